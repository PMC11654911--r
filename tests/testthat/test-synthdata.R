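test_that("scene generation is byte-deterministic and honors the priors", {
  p <- scene_params(size = 64, seed = 21)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1, s2)
  expect_true(all(s1$mask %in% 0:3))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_equal(sum(s1$class_fractions), 1)
  # quantile thresholding pins per-scene fractions to the priors
  expect_lt(max(abs(s1$class_fractions - p$class_prior)), 0.02)
  # different seeds give different scenes
  expect_false(identical(generate_scene(scene_params(size = 64, seed = 22)),
                         s1))
})

test_that("extreme priors produce near-single-class masks", {
  p <- scene_params(size = 64, class_prior = c(0.97, 0.01, 0.01, 0.01),
                    seed = 5)
  s <- generate_scene(p)
  expect_gt(s$class_fractions["BG"], 0.9)
  expect_error(scene_params(class_prior = c(1, 0, 0, 0)), "positive")
})

test_that("the lodged-class fraction concentrates at its prior over many scenes", {
  scn <- generate_scenes(60, scene_params(size = 64, seed = 1000))
  lfrac <- vapply(scn, function(s) s$class_fractions[["L"]], numeric(1))
  expect_lt(abs(mean(lfrac) - 0.10), 0.05)
})

test_that("half-lodged pixels lie along upright/lodged interfaces", {
  s <- generate_scene(scene_params(size = 96, seed = 9))
  # every L region boundary pixel should touch HL, not NL/BG directly
  m <- s$mask
  H <- nrow(m); W <- ncol(m)
  lpix <- which(m == 3, arr.ind = TRUE)
  touching <- 0L; total <- 0L
  for (r in seq_len(nrow(lpix))) {
    i <- lpix[r, 1]; j <- lpix[r, 2]
    nb <- c(if (i > 1) m[i - 1, j], if (i < H) m[i + 1, j],
            if (j > 1) m[i, j - 1], if (j < W) m[i, j + 1])
    if (any(nb != 3)) {  # boundary pixel of an L region
      total <- total + 1L
      if (any(nb == 2)) touching <- touching + 1L
    }
  }
  expect_gt(total, 0L)
  expect_gt(touching / total, 0.9)
})

test_that("datasets round-trip through PNG exactly and split 75/25", {
  dir <- withr::local_tempdir()
  man <- generate_dataset(8, scene_params(size = 64, seed = 50), dir)
  expect_identical(sum(man$scenes$split == "train"), 6L)
  expect_identical(sum(man$scenes$split == "val"), 2L)
  expect_true(all(file.exists(file.path(dir, man$scenes$image))))
  expect_true(all(file.exists(file.path(dir, man$scenes$mask))))
  ds <- load_dataset(dir)
  expect_length(ds$train, 6)
  expect_length(ds$val, 2)
  # written mask equals the in-memory mask bit for bit
  i <- 3
  mem <- generate_scene(scene_params(size = 64, seed = 50 + i))
  disk <- read_scene(file.path(dir, man$scenes$image[i]),
                     file.path(dir, man$scenes$mask[i]))
  expect_identical(disk$mask, mem$mask)
  # image quantized to 8 bits on write
  expect_lt(max(abs(disk$image - mem$image)), 1 / 255)
  expect_error(generate_dataset(2, scene_params(size = 64), dir), "at least 4")
})

test_that("tiling cuts non-overlapping tiles and rescaling invents no labels", {
  s <- generate_scene(scene_params(size = 128, seed = 60))
  tiles <- tile_and_rescale(s$image, s$mask, tile_sizes = c(128, 64),
                            out_size = 64)
  expect_length(tiles, 1 + 4)
  for (t in tiles) {
    expect_identical(dim(t$mask), c(64L, 64L))
    expect_identical(dim(t$image), c(64L, 64L, 3L))
    expect_true(all(t$mask %in% 0:3))
    expect_true(all(unique(as.vector(t$mask)) %in% unique(as.vector(s$mask))))
  }
  # the unscaled 64-tiles partition the mask exactly
  expect_identical(tiles[[2]]$mask, s$mask[1:64, 1:64])
  # constant-label image yields single-label tiles
  tiles1 <- tile_and_rescale(s$image, matrix(2L, 128, 128),
                             tile_sizes = c(128), out_size = 64)
  expect_true(all(tiles1[[1]]$mask == 2L))
  expect_warning(tile_and_rescale(s$image, s$mask, tile_sizes = c(256),
                                  out_size = 64), "skipped")
})

test_that("Labelme polygons rasterize with overwrite semantics", {
  empty <- rasterize_labelme(list(shapes = list()), c(32, 32))
  expect_true(all(empty == 0L))
  full <- list(shapes = list(list(
    label = "NL",
    points = list(c(-1, -1), c(40, -1), c(40, 40), c(-1, 40)))))
  expect_true(all(rasterize_labelme(full, c(32, 32)) == 1L))
  two <- list(shapes = list(
    list(label = "NL",
         points = list(c(-1, -1), c(40, -1), c(40, 40), c(-1, 40))),
    list(label = "L",
         points = list(c(0, 0), c(16, 0), c(16, 16), c(0, 16)))))
  m <- rasterize_labelme(two, c(32, 32))
  expect_true(all(m[1:16, 1:16] == 3L))   # later polygon wins the overlap
  expect_true(all(m[17:32, ] == 1L))
  bad <- list(shapes = list(list(label = "XX", points = full$shapes[[1]]$points)))
  expect_error(rasterize_labelme(bad, c(32, 32)), "XX")
  # round trip through a JSON file
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(two, f, auto_unbox = TRUE, digits = NA)
  expect_identical(rasterize_labelme(f, c(32, 32)), m)
})

test_that("scenes are separable by a simple pixel classifier (task is learnable)", {
  scn <- cached_scenes(3, size = 64, seed = 100)
  local_var <- function(img) {
    g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    m <- EBImage::filter2(g, matrix(1 / 9, 3, 3))
    m2 <- EBImage::filter2(g^2, matrix(1 / 9, 3, 3))
    pmax(m2 - m^2, 0)
  }
  feat <- function(s) cbind(as.vector(s$image[, , 1]),
                            as.vector(s$image[, , 2]),
                            as.vector(s$image[, , 3]),
                            sqrt(as.vector(local_var(s$image))) * 4)
  xtr <- rbind(feat(scn[[1]]), feat(scn[[2]]))
  ytr <- c(as.vector(scn[[1]]$mask), as.vector(scn[[2]]$mask))
  xte <- feat(scn[[3]])
  yte <- as.vector(scn[[3]]$mask)
  set.seed(1)
  tr_idx <- sample(nrow(xtr), 3000)
  te_idx <- sample(nrow(xte), 2000)
  pred <- class::knn(xtr[tr_idx, ], xte[te_idx, ],
                     factor(ytr[tr_idx]), k = 5)
  acc <- mean(as.integer(as.character(pred)) == yte[te_idx])
  expect_gt(acc, 0.7)
})
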