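ns <- asNamespace("lodgeopt")

test_that("convolution primitives match numeric gradients", {
  set.seed(1)
  H <- 8; W <- 8; B <- 2; C <- 3
  x0 <- array(rnorm(H * W * B * C), c(H, W, B, C))
  tgt <- array(rnorm(H * W * B * 5), c(H, W, B, 5))
  Wc <- matrix(rnorm(49 * C * 5, 0, 0.2), 49 * C, 5)
  bc <- rnorm(5)
  f <- ns$conv_fwd(x0, Wc, bc, 7L, 1L, 3L)
  bwd <- ns$conv_bwd(2 * (f$y - tgt), Wc, 7L, 1L, 3L, f$cache)
  loss_x <- function(x) {
    sum((ns$conv_fwd(x, Wc, bc, 7L, 1L, 3L)$y - tgt)^2)
  }
  idx <- sample(length(x0), 8)
  expect_lt(max(rel_err(num_grad(loss_x, x0, idx), bwd$dx[idx])), 1e-5)
  loss_w <- function(w) {
    sum((ns$conv_fwd(x0, matrix(w, 49 * C, 5), bc, 7L, 1L, 3L)$y - tgt)^2)
  }
  idx <- sample(length(Wc), 8)
  expect_lt(max(rel_err(num_grad(loss_w, as.numeric(Wc), idx),
                        bwd$dW[idx])), 1e-5)
  # strided 2x2 conv halves the spatial size
  W2 <- matrix(rnorm(4 * C * 5, 0, 0.2), 4 * C, 5)
  y2 <- ns$conv_fwd(x0, W2, bc, 2L, 2L, 0L)$y
  expect_identical(dim(y2), c(4L, 4L, 2L, 5L))
})

test_that("depthwise convolution, layer norm and GELU match numeric gradients", {
  set.seed(2)
  H <- 6; W <- 6; B <- 2; C <- 4
  x0 <- array(rnorm(H * W * B * C), c(H, W, B, C))
  tgt <- array(rnorm(H * W * B * C), c(H, W, B, C))
  Wd <- matrix(rnorm(49 * C, 0, 0.2), 49, C); bd <- rnorm(C)
  fd <- ns$dwconv_fwd(x0, Wd, bd)
  bd_ <- ns$dwconv_bwd(2 * (fd$y - tgt), Wd, fd$cache)
  idx <- sample(length(x0), 6)
  g <- num_grad(function(x) sum((ns$dwconv_fwd(x, Wd, bd)$y - tgt)^2),
                x0, idx)
  expect_lt(max(rel_err(g, bd_$dx[idx])), 1e-5)

  gam <- runif(C, 0.5, 1.5); bet <- rnorm(C)
  fl <- ns$ln_fwd(x0, gam, bet)
  bl <- ns$ln_bwd(2 * (fl$y - tgt), gam, fl$cache)
  g <- num_grad(function(x) sum((ns$ln_fwd(x, gam, bet)$y - tgt)^2),
                x0, idx)
  expect_lt(max(rel_err(g, bl$dx[idx])), 1e-4)
  # layer norm output rows are standardized before the affine map
  xh <- fl$cache$xhat
  expect_lt(max(abs(rowMeans(xh))), 1e-8)

  g <- num_grad(function(x) sum((ns$gelu_fwd(x) - tgt)^2), x0, idx)
  ga <- ns$gelu_bwd(2 * (ns$gelu_fwd(x0) - tgt), x0)
  expect_lt(max(rel_err(g, ga[idx])), 1e-5)
})

test_that("bilinear upsampling doubles resolution, preserves constants, and is adjoint-consistent", {
  set.seed(3)
  x <- array(rnorm(4 * 6 * 2 * 3), c(4, 6, 2, 3))
  y <- ns$up2_fwd(x)
  expect_identical(dim(y), c(8L, 12L, 2L, 3L))
  const <- array(2.5, c(4, 4, 1, 1))
  expect_equal(ns$up2_fwd(const), array(2.5, c(8, 8, 1, 1)))
  # backward is the exact adjoint: <Ux, y> = <x, U'y>
  dy <- array(rnorm(length(y)), dim(y))
  expect_equal(sum(y * dy), sum(x * ns$up2_bwd(dy, dim(x))),
               tolerance = 1e-10)
})

test_that("the full network matches numeric gradients through every layer kind", {
  plan <- tiny_plan(42)
  spec <- reference_spec(plan, input_size = c(64, 64))
  net <- build_network(spec, seed = 7)
  set.seed(4)
  x <- array(runif(64 * 64 * 1 * 3), c(64, 64, 1, 3))
  tgt <- array(rnorm(64 * 64 * 1 * 4), c(64, 64, 1, 4))
  fwd <- net_forward(net, x, keep_cache = TRUE)
  grads <- net_backward(net, fwd, 2 * (fwd$logits - tgt))
  loss_at <- function(params) {
    n2 <- net; n2$params <- params
    sum((net_forward(n2, x)$logits - tgt)^2)
  }
  set.seed(5)
  worst <- 0
  for (nm in sample(names(net$params), 12)) {
    j <- sample(length(net$params[[nm]]), 1)
    pp <- net$params; pp[[nm]][j] <- pp[[nm]][j] + 1e-5
    pm <- net$params; pm[[nm]][j] <- pm[[nm]][j] - 1e-5
    num <- (loss_at(pp) - loss_at(pm)) / 2e-5
    worst <- max(worst, rel_err(num, grads[[nm]][j]))
  }
  expect_lt(worst, 1e-4)
})

test_that("forward contract: shapes, per-pixel normalization, determinism", {
  spec <- reference_spec(tiny_plan(1), input_size = c(64, 64))
  net <- build_network(spec, seed = 2)
  set.seed(6)
  x1 <- array(runif(64 * 64 * 3), c(64, 64, 1, 3))
  x2 <- array(0, c(64, 64, 2, 3))          # same image twice
  x2[, , 1, ] <- x1[, , 1, ]
  x2[, , 2, ] <- x1[, , 1, ]
  out <- net_forward(net, x2)$logits
  expect_identical(dim(out), c(64L, 64L, 2L, 4L))
  expect_true(all(is.finite(out)))
  expect_equal(out[, , 1, ], out[, , 2, ])   # batch determinism
  expect_equal(net_forward(net, x2)$logits, out)  # call determinism
  pm <- ns$softmax_rows(matrix(out, ncol = 4))
  expect_equal(rowSums(pm), rep(1, 64 * 64 * 2), tolerance = 1e-5)
  expect_error(net_forward(net, array(0, c(60, 60, 1, 3))), "divisible")
})

test_that("the composite loss gradient matches numeric differentiation", {
  set.seed(8)
  z <- array(rnorm(8 * 8 * 2 * 4), c(8, 8, 2, 4))
  lab <- array(sample(0:3, 128, TRUE), c(8, 8, 2))
  lg <- loss_and_grad(z, lab)
  expect_equal(lg$loss, lg$focal + lg$dice)
  idx <- sample(length(z), 10)
  g <- num_grad(function(zz) loss_and_grad(zz, lab)$loss, z, idx)
  expect_lt(max(rel_err(g, lg$dlogits[idx])), 1e-4)
  # perfect logits give (near) zero loss
  zp <- array(-20, dim(z))
  for (b in 1:2) for (i in 1:8) for (j in 1:8)
    zp[i, j, b, lab[i, j, b] + 1] <- 20
  expect_lt(loss_and_grad(zp, lab)$loss, 1e-4)
})

test_that("a short training step reduces the loss and keeps gradients finite", {
  spec <- reference_spec(tiny_plan(3), input_size = c(64, 64))
  net <- build_network(spec, seed = 4)
  scenes <- cached_scenes(4, size = 64, seed = 300)
  tr <- train_network(net, scenes, epochs = 3, seed = 5)
  expect_true(all(is.finite(tr$loss_history)))
  expect_lt(mean(tail(tr$loss_history, 2)), mean(head(tr$loss_history, 2)))
  # determinism of training under a fixed seed
  net2 <- build_network(spec, seed = 4)
  tr2 <- train_network(net2, scenes, epochs = 3, seed = 5)
  expect_identical(tr$loss_history, tr2$loss_history)
  preds <- predict_network(tr$net, scenes[1])
  expect_identical(dim(preds[[1]]), c(64L, 64L))
  expect_true(all(preds[[1]] %in% 0:3))
})

test_that("the network can overfit a single scene (capacity check)", {
  scene <- cached_scenes(1, size = 64, seed = 400)
  spec <- reference_spec(base_channel_plan(), input_size = c(64, 64))
  net <- build_network(spec, seed = 1)
  tr <- train_network(net, scene, epochs = 200, batch_size = 1, seed = 1)
  expect_lt(min(tr$loss_history), 0.1)
})
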