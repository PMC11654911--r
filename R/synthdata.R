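# Synthetic four-class crop-lodging scenes: spatially contiguous canopy
# regions (smoothed random field thresholded at prior quantiles) rendered
# with class-specific color and texture, plus dataset writing/splitting,
# tiling, and Labelme-style polygon rasterization.

CLASS_NAMES <- c("BG", "NL", "HL", "L")

#' Scene generation parameters
#'
#' Defaults encode the intended statistical structure of aerial
#' rice-lodging imagery: background and upright canopy dominate, lodged
#' canopy is rare, and half-lodged canopy forms bands between upright and
#' lodged regions.
#'
#' @param size Scene size `c(H, W)`; default `c(128, 128)` (desk scale;
#'   use 512 to mirror full-resolution tiles).
#' @param class_prior Expected fractions for (BG, NL, HL, L); positive,
#'   summing to 1. Default `c(0.25, 0.45, 0.20, 0.10)` — lodging rarest.
#' @param blob_scale Spatial correlation length (Gaussian smoothing sigma,
#'   pixels) of the region field; default `size/8`.
#' @param noise_sd Additive pixel noise standard deviation; default 0.02.
#' @param seed Integer seed; every byte of the scene is a function of
#'   `(seed, params)`.
#' @return Object of class `"scene_params"`.
#' @export
scene_params <- function(size = c(128, 128),
                         class_prior = c(BG = 0.25, NL = 0.45,
                                         HL = 0.20, L = 0.10),
                         blob_scale = NULL, noise_sd = 0.02, seed = 1L) {
  size <- rep_len(as.integer(size), 2)
  if (any(size < 32)) stop("scene size must be at least 32 pixels")
  if (length(class_prior) != 4 || any(class_prior <= 0))
    stop("class_prior must be 4 positive fractions")
  class_prior <- class_prior / sum(class_prior)
  if (is.null(blob_scale)) blob_scale <- min(size) / 8
  structure(list(size = size, class_prior = class_prior,
                 blob_scale = blob_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# directional sinusoidal texture with jitter, in [-1, 1]
streak_texture <- function(H, W, period, angle, jitter = 0.2) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  phase <- (i * sin(angle) + j * cos(angle)) / period
  sin(2 * pi * (phase + jitter * matrix(stats::runif(1), H, W)))
}

#' Generate one synthetic lodging scene
#'
#' The label mask is built by thresholding a Gaussian-smoothed random
#' field at the empirical quantiles of the class priors, in value order
#' BG < NL < HL < L — a smooth field then yields contiguous regions whose
#' per-scene class fractions match the priors (up to ties) and in which HL
#' bands sit between NL and L regions, mimicking half-lodged canopy at
#' lodging fronts. Each class is rendered with its own base color and
#' texture: upright canopy (NL) dark green with high-frequency speckle,
#' half-lodged (HL) yellow-green with oblique streaks, lodged (L) smooth
#' yellowish directional straw streaks, background (BG) low-texture brown.
#'
#' @param params A [scene_params()].
#' @return Object of class `"lodging_scene"`: list with `image`
#'   (`H x W x 3` in `[0, 1]`), `mask` (`H x W` integer labels 0..3), and
#'   `class_fractions` (empirical, summing to 1).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  H <- params$size[1]; W <- params$size[2]
  field <- EBImage::gblur(matrix(stats::rnorm(H * W), H, W),
                          sigma = params$blob_scale)
  cuts <- stats::quantile(field, cumsum(params$class_prior)[1:3],
                          names = FALSE)
  mask <- matrix(0L, H, W)
  mask[field > cuts[1]] <- 1L
  mask[field > cuts[2]] <- 2L
  mask[field > cuts[3]] <- 3L

  base_col <- rbind(BG = c(0.45, 0.32, 0.18),
                    NL = c(0.15, 0.42, 0.12),
                    HL = c(0.42, 0.50, 0.20),
                    L  = c(0.62, 0.55, 0.25))
  speckle <- matrix(stats::rnorm(H * W), H, W)               # NL texture
  oblique <- streak_texture(H, W, period = 6, angle = pi / 4)  # HL
  straw <- EBImage::gblur(streak_texture(H, W, period = 12, angle = 0) +
                          0.5 * matrix(stats::rnorm(H * W), H, W),
                          sigma = 1.5)                        # L
  bgtex <- EBImage::gblur(matrix(stats::rnorm(H * W), H, W), sigma = 3)
  tex <- list(`0` = 0.03 * bgtex, `1` = 0.10 * speckle,
              `2` = 0.06 * oblique, `3` = 0.08 * straw)
  img <- array(0, c(H, W, 3))
  for (k in 0:3) {
    sel <- mask == k
    t_k <- tex[[as.character(k)]]
    for (ch in 1:3)
      img[, , ch][sel] <- base_col[k + 1, ch] + t_k[sel]
  }
  img <- img + array(stats::rnorm(H * W * 3, 0, params$noise_sd),
                     c(H, W, 3))
  img <- pmin(pmax(img, 0), 1)
  fr <- tabulate(mask + 1L, 4) / (H * W)
  names(fr) <- CLASS_NAMES
  structure(list(image = img, mask = mask, class_fractions = fr),
            class = "lodging_scene")
}

#' Generate a list of scenes with derived seeds
#'
#' @param n Number of scenes.
#' @param params Template [scene_params()]; scene `i` uses seed
#'   `params$seed + i`.
#' @return List of [generate_scene()] results.
#' @export
generate_scenes <- function(n, params = scene_params()) {
  lapply(seq_len(n), function(i) {
    p <- params; p$seed <- params$seed + i
    generate_scene(p)
  })
}

write_scene <- function(scene, image_path, mask_path) {
  png::writePNG(scene$image, image_path)
  png::writePNG(scene$mask / 255, mask_path)
}

#' Read a scene written by [generate_dataset()]
#'
#' Masks are stored as 8-bit single-channel PNGs whose gray level is the
#' class label (0..3); reading back is exact.
#'
#' @param image_path,mask_path PNG file paths.
#' @return A `"lodging_scene"`.
#' @export
read_scene <- function(image_path, mask_path) {
  img <- png::readPNG(image_path)
  m <- png::readPNG(mask_path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  mask <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  fr <- tabulate(mask + 1L, 4) / length(mask)
  names(fr) <- CLASS_NAMES
  structure(list(image = img, mask = mask, class_fractions = fr),
            class = "lodging_scene")
}

#' Generate and write a dataset of scenes with a train/validation split
#'
#' Writes image and mask PNGs plus a JSON manifest recording the
#' per-scene split (train fraction `round(split * n)`, assignment by a
#' seeded shuffle) and the generator parameters.
#'
#' @param n_scenes Number of scenes, at least 4.
#' @param params Template [scene_params()].
#' @param out_dir Output directory (created if missing).
#' @param split Train fraction; default 0.75.
#' @return The manifest (invisibly also written to
#'   `out_dir/manifest.json`): list with `scenes` (data frame `image`,
#'   `mask`, `split`, `seed`) and `params`.
#' @export
generate_dataset <- function(n_scenes, params = scene_params(), out_dir,
                             split = 0.75) {
  if (n_scenes < 4) stop("need at least 4 scenes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  scenes <- generate_scenes(n_scenes, params)
  set.seed(params$seed)
  n_train <- round(split * n_scenes)
  train_idx <- sample(n_scenes, n_train)
  files <- data.frame(
    image = sprintf("scene_%03d.png", seq_len(n_scenes)),
    mask = sprintf("mask_%03d.png", seq_len(n_scenes)),
    split = ifelse(seq_len(n_scenes) %in% train_idx, "train", "val"),
    seed = params$seed + seq_len(n_scenes),
    stringsAsFactors = FALSE)
  for (i in seq_len(n_scenes))
    write_scene(scenes[[i]], file.path(out_dir, files$image[i]),
                file.path(out_dir, files$mask[i]))
  manifest <- list(scenes = files,
                   params = list(size = params$size,
                                 class_prior = as.numeric(params$class_prior),
                                 blob_scale = params$blob_scale,
                                 noise_sd = params$noise_sd,
                                 seed = params$seed),
                   split = split)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a written dataset
#'
#' @param dir Directory holding `manifest.json` and the PNGs.
#' @return List with `train` and `val` lists of scenes.
#' @export
load_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  sc <- man$scenes
  scenes <- lapply(seq_len(nrow(sc)), function(i)
    read_scene(file.path(dir, sc$image[i]), file.path(dir, sc$mask[i])))
  list(train = scenes[sc$split == "train"],
       val = scenes[sc$split == "val"],
       manifest = man)
}

resize_bilinear <- function(m, h, w) EBImage::resize(m, w = h, h = w)

#' Tile a large annotated image at several scales
#'
#' Cuts non-overlapping tiles at each requested size and rescales every
#' tile to `out_size` (bilinear for the image, nearest-neighbor for the
#' mask so no new label values appear). Tile sizes larger than the image
#' are skipped with a warning.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask `H x W` integer label matrix.
#' @param tile_sizes Vector of square tile sizes; default
#'   `c(2048, 1024, 512)`.
#' @param out_size Output resolution; default 512.
#' @return List of `"lodging_scene"` tiles.
#' @export
tile_and_rescale <- function(image, mask, tile_sizes = c(2048, 1024, 512),
                             out_size = 512) {
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- list()
  for (ts in tile_sizes) {
    if (ts > H || ts > W) {
      warning("tile size ", ts, " exceeds image size; skipped")
      next
    }
    for (ti in seq_len(H %/% ts)) for (tj in seq_len(W %/% ts)) {
      ri <- (ti - 1) * ts + seq_len(ts)
      rj <- (tj - 1) * ts + seq_len(ts)
      sub_img <- image[ri, rj, , drop = FALSE]
      sub_mask <- mask[ri, rj, drop = FALSE]
      if (ts != out_size) {
        res <- array(0, c(out_size, out_size, 3))
        for (ch in 1:3)
          res[, , ch] <- resize_bilinear(sub_img[, , ch], out_size,
                                         out_size)
        res <- pmin(pmax(res, 0), 1)
        nn <- floor((seq_len(out_size) - 0.5) * ts / out_size) + 1L
        sub_mask <- sub_mask[nn, nn, drop = FALSE]
        sub_img <- res
      }
      fr <- tabulate(sub_mask + 1L, 4) / length(sub_mask)
      names(fr) <- CLASS_NAMES
      out[[length(out) + 1L]] <-
        structure(list(image = sub_img,
                       mask = matrix(as.integer(sub_mask),
                                     nrow(sub_mask), ncol(sub_mask)),
                       class_fractions = fr),
                  class = "lodging_scene")
    }
  }
  out
}

#' Rasterize Labelme-style polygon annotations to a label mask
#'
#' Polygons (fields `shapes[].label`, `shapes[].points` with `(x, y)`
#' vertices, x rightward and y downward from the top-left corner) are
#' filled in order, later polygons overwriting earlier ones; pixels
#' covered by no polygon are background.
#'
#' @param annotation Path to a Labelme JSON file, or an equivalent list.
#' @param size Mask size `c(H, W)`.
#' @return Integer `H x W` label matrix (0..3).
#' @export
rasterize_labelme <- function(annotation, size) {
  if (is.character(annotation))
    annotation <- jsonlite::read_json(annotation, simplifyVector = FALSE)
  H <- size[1]; W <- size[2]
  mask <- matrix(0L, H, W)
  shapes <- annotation$shapes
  if (length(shapes) == 0) return(mask)
  # pixel centers in Labelme coordinates
  px <- cbind(x = rep(seq_len(W) - 0.5, each = H),
              y = rep(seq_len(H) - 0.5, times = W))
  for (sh in shapes) {
    lab <- match(sh$label, CLASS_NAMES) - 1L
    if (is.na(lab))
      stop("unknown class label in annotation: '", sh$label, "'")
    pts <- do.call(rbind, lapply(sh$points, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    if (nrow(pts) < 3) next
    inside <- mgcv::in.out(rbind(pts, pts[1, ]), px)
    mask[matrix(inside, H, W)] <- lab
  }
  mask
}
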