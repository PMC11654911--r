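# Network engine: builds trainable weights from an architecture_spec and
# runs forward, backward and AdamW updates. Feature maps are numeric arrays
# with layout (H, W, B, C); flattening the first three dimensions gives the
# (H*W*B) x C matrix view used for all pointwise convolutions and layer
# normalization, so the heavy lifting is BLAS GEMM. Spatial convolutions go
# through im2col; depthwise 7x7 convolutions are evaluated as 49 shifted
# elementwise multiply-accumulates.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

as_tensor <- function(m, H, W, B) {
  dim(m) <- c(H, W, B, ncol(m))
  m
}

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

im2col <- function(x, k, s, p) {
  xp <- pad_hw(x, p)
  d <- dim(xp)
  Ho <- (d[1] - k) %/% s + 1L
  Wo <- (d[2] - k) %/% s + 1L
  B <- d[3]; C <- d[4]
  cols <- matrix(0, Ho * Wo * B, k * k * C)
  hi <- seq.int(1L, by = s, length.out = Ho)
  wi <- seq.int(1L, by = s, length.out = Wo)
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    o <- o + 1L
    blk <- xp[hi + di, wi + dj, , , drop = FALSE]
    cols[, ((o - 1L) * C + 1L):(o * C)] <- blk
    # dim(blk) = (Ho, Wo, B, C); assignment flattens in matching order
  }
  list(cols = cols, Ho = Ho, Wo = Wo, B = B, C = C)
}

col2im <- function(dcols, H, W, B, C, k, s, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L
  Wo <- (Wp - k) %/% s + 1L
  dxp <- array(0, c(Hp, Wp, B, C))
  hi <- seq.int(1L, by = s, length.out = Ho)
  wi <- seq.int(1L, by = s, length.out = Wo)
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    o <- o + 1L
    blk <- dcols[, ((o - 1L) * C + 1L):(o * C)]
    dim(blk) <- c(Ho, Wo, B, C)
    dxp[hi + di, wi + dj, , ] <- dxp[hi + di, wi + dj, , , drop = FALSE] + blk
  }
  if (p > 0) dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE] else dxp
}

conv_fwd <- function(x, W, b, k, s, p) {
  if (k == 1L && s == 1L) {
    xm <- as_mat(x)
    y <- xm %*% W + rep(b, each = nrow(xm))
    d <- dim(x)
    list(y = as_tensor(y, d[1], d[2], d[3]), cache = list(xm = xm))
  } else {
    ic <- im2col(x, k, s, p)
    y <- ic$cols %*% W + rep(b, each = nrow(ic$cols))
    list(y = as_tensor(y, ic$Ho, ic$Wo, ic$B),
         cache = list(cols = ic$cols, in_dim = dim(x)))
  }
}

conv_bwd <- function(dy, W, k, s, p, cache) {
  dym <- as_mat(dy)
  if (k == 1L && s == 1L) {
    dW <- crossprod(cache$xm, dym)
    db <- colSums(dym)
    dx <- dym %*% t(W)
    d <- dim(dy)
    list(dx = as_tensor(dx, d[1], d[2], d[3]), dW = dW, db = db)
  } else {
    dW <- crossprod(cache$cols, dym)
    db <- colSums(dym)
    dcols <- dym %*% t(W)
    id <- cache$in_dim
    list(dx = col2im(dcols, id[1], id[2], id[3], id[4], k, s, p),
         dW = dW, db = db)
  }
}

dwconv_fwd <- function(x, Wd, b, k = 7L, p = 3L) {
  xp <- pad_hw(x, p)
  d <- dim(x); C <- d[4]; n <- d[1] * d[2] * d[3]
  y <- array(0, d)
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    o <- o + 1L
    y <- y + xp[di + seq_len(d[1]), dj + seq_len(d[2]), , , drop = FALSE] *
      rep(Wd[o, ], each = n)
  }
  y <- y + rep(b, each = n)
  list(y = y, cache = list(xp = xp, dims = d))
}

dwconv_bwd <- function(dy, Wd, cache, k = 7L, p = 3L) {
  d <- cache$dims; C <- d[4]; n <- d[1] * d[2] * d[3]
  dxp <- array(0, dim(cache$xp))
  dW <- matrix(0, k * k, C)
  dym <- as_mat(dy)
  o <- 0L
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    o <- o + 1L
    blk <- cache$xp[di + seq_len(d[1]), dj + seq_len(d[2]), , , drop = FALSE]
    dim(blk) <- c(n, C)
    dW[o, ] <- colSums(blk * dym)
    dxp[di + seq_len(d[1]), dj + seq_len(d[2]), , ] <-
      dxp[di + seq_len(d[1]), dj + seq_len(d[2]), , , drop = FALSE] +
      dy * rep(Wd[o, ], each = n)
  }
  db <- colSums(dym)
  dx <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

LN_EPS <- 1e-6

ln_fwd <- function(x, gamma, beta) {
  xm <- as_mat(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + LN_EPS)
  xhat <- xc * istd
  y <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  d <- dim(x)
  list(y = as_tensor(y, d[1], d[2], d[3]),
       cache = list(xhat = xhat, istd = istd, dims = d))
}

ln_bwd <- function(dy, gamma, cache) {
  dym <- as_mat(dy)
  xhat <- cache$xhat
  C <- ncol(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = nrow(dym))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$istd
  d <- cache$dims
  list(dx = as_tensor(dx, d[1], d[2], d[3]), dgamma = dgamma,
       dbeta = dbeta)
}

gelu_fwd <- function(x) x * stats::pnorm(x)

gelu_bwd <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

# dense 2x bilinear interpolation matrix (align_corners = FALSE sampling)
bilinear_matrix <- function(n) {
  U <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    s <- i / 2 + 0.25
    l <- floor(s); f <- s - l
    if (l < 1) { l <- 1; f <- 0 }
    if (l >= n) { l <- n; f <- 0 }
    U[i, l] <- U[i, l] + (1 - f)
    if (f > 0) U[i, l + 1L] <- U[i, l + 1L] + f
  }
  U
}

up2_fwd <- function(x) {
  d <- dim(x)
  Uh <- bilinear_matrix(d[1]); Uw <- bilinear_matrix(d[2])
  m <- x; dim(m) <- c(d[1], d[2] * d[3] * d[4])
  y <- Uh %*% m
  dim(y) <- c(2L * d[1], d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  dim(y) <- c(d[2], 2L * d[1] * d[3] * d[4])
  y <- Uw %*% y
  dim(y) <- c(2L * d[2], 2L * d[1], d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

up2_bwd <- function(dy, in_dim) {
  d <- in_dim
  Uh <- bilinear_matrix(d[1]); Uw <- bilinear_matrix(d[2])
  m <- aperm(dy, c(2, 1, 3, 4))
  dim(m) <- c(2L * d[2], 2L * d[1] * d[3] * d[4])
  m <- crossprod(Uw, m)
  dim(m) <- c(d[2], 2L * d[1], d[3], d[4])
  m <- aperm(m, c(2, 1, 3, 4))
  dim(m) <- c(2L * d[1], d[2] * d[3] * d[4])
  m <- crossprod(Uh, m)
  dim(m) <- d
  m
}

#' Build a trainable network from an architecture spec
#'
#' Allocates weight tensors for every parameterized layer (He-initialized
#' convolutions, unit-scale layer norms) under a fixed seed.
#'
#' @param spec An [reference_spec()] result.
#' @param seed Integer seed for the weight draws.
#' @return Object of class `"lodge_net"`: list with `spec` and `params`
#'   (named list of weight matrices/vectors, keyed by layer row).
#' @export
build_network <- function(spec, seed = 1L) {
  set.seed(seed)
  l <- spec$layers
  params <- list()
  for (i in seq_len(nrow(l))) {
    kind <- l$kind[i]
    if (kind %in% conv_kinds) {
      fan_in <- l$kernel[i]^2 * l$in_ch[i]
      sd <- sqrt(2 / fan_in)
      # damp residual branches and the head so initial blocks are
      # near-identity and initial logits are O(1) (unsaturated softmax)
      if (kind == "pw_project") sd <- sd * 0.1
      if (kind == "head_conv") sd <- sd * 0.1
      params[[paste0("L", i, "_W")]] <-
        matrix(stats::rnorm(fan_in * l$out_ch[i], 0, sd),
               fan_in, l$out_ch[i])
      params[[paste0("L", i, "_b")]] <- numeric(l$out_ch[i])
    } else if (kind == "dw_conv7") {
      C <- l$out_ch[i]
      params[[paste0("L", i, "_W")]] <-
        matrix(stats::rnorm(49 * C, 0, sqrt(2 / 49)), 49, C)
      params[[paste0("L", i, "_b")]] <- numeric(C)
    } else if (kind == "layer_norm") {
      C <- l$out_ch[i]
      params[[paste0("L", i, "_g")]] <- rep(1, C)
      params[[paste0("L", i, "_be")]] <- numeric(C)
    }
  }
  structure(list(spec = spec, params = params), class = "lodge_net")
}

#' Forward pass
#'
#' Runs a batch through the network. Inputs are RGB tensors in `[0, 1]`
#' with layout `(H, W, B, 3)`; they are shifted to `[-1, 1]` internally.
#' Deterministic (the network has no stochastic layers).
#'
#' @param net A [build_network()] result.
#' @param x Input array `(H, W, B, 3)` with `H`, `W` divisible by 16.
#' @param keep_cache Keep per-layer activations for [net_backward()].
#' @return List with `logits` (array `(H, W, B, K)`) and, if requested,
#'   `cache`.
#' @export
net_forward <- function(net, x, keep_cache = FALSE) {
  l <- net$spec$layers
  p <- net$params
  if (any(dim(x)[1:2] %% net$spec$down_factor != 0))
    stop("input spatial size must be divisible by ", net$spec$down_factor)
  cur <- x * 2 - 1
  caches <- if (keep_cache) vector("list", nrow(l)) else NULL
  skips <- list()
  block_in <- list()   # block id -> input tensor (for residual)
  ds_seen <- 0L
  for (i in seq_len(nrow(l))) {
    kind <- l$kind[i]
    if (kind %in% c("stem_conv7", "downsample", "pw_reduce", "head_conv",
                    "pw_expand", "pw_project", "shortcut_proj")) {
      if (kind == "downsample") {
        ds_seen <- ds_seen + 1L
        if (ds_seen <= 4L) skips[[paste0("s", ds_seen)]] <- cur
      }
      xin <- if (kind == "shortcut_proj") block_in[[l$block[i]]] else cur
      cf <- conv_fwd(xin, p[[paste0("L", i, "_W")]],
                     p[[paste0("L", i, "_b")]],
                     l$kernel[i], l$stride[i], l$padding[i])
      if (kind == "pw_expand") {
        z <- cf$y
        cur <- gelu_fwd(z)
        if (keep_cache) caches[[i]] <- c(cf["cache"], list(z = z))
      } else if (kind == "pw_project") {
        # identity residual when widths match (no shortcut row follows)
        has_proj <- i < nrow(l) && l$kind[i + 1L] == "shortcut_proj" &&
          identical(l$block[i + 1L], l$block[i])
        cur <- if (has_proj) cf$y else cf$y + block_in[[l$block[i]]]
        if (keep_cache) caches[[i]] <- c(cf["cache"],
                                         list(has_proj = has_proj))
      } else if (kind == "shortcut_proj") {
        cur <- cur + cf$y
        if (keep_cache) caches[[i]] <- cf["cache"]
      } else {
        cur <- cf$y
        if (keep_cache) caches[[i]] <- cf["cache"]
      }
    } else if (kind == "dw_conv7") {
      block_in[[l$block[i]]] <- cur
      df <- dwconv_fwd(cur, p[[paste0("L", i, "_W")]],
                       p[[paste0("L", i, "_b")]])
      cur <- df$y
      if (keep_cache) caches[[i]] <- df["cache"]
    } else if (kind == "layer_norm") {
      lf <- ln_fwd(cur, p[[paste0("L", i, "_g")]],
                   p[[paste0("L", i, "_be")]])
      cur <- lf$y
      if (keep_cache) caches[[i]] <- lf["cache"]
    } else if (kind == "upsample_bilinear") {
      if (keep_cache) caches[[i]] <- list(in_dim = dim(cur))
      cur <- up2_fwd(cur)
    } else if (kind == "concat_skip") {
      sk <- skips[[l$skip[i]]]
      d <- dim(cur)
      if (keep_cache) caches[[i]] <- list(c_main = d[4], skip = l$skip[i])
      cur <- array(c(cur, sk), c(d[1], d[2], d[3], d[4] + dim(sk)[4]))
    } else stop("unknown layer kind: ", kind)
    if (any(!is.finite(cur)))
      stop("non-finite activation after layer ", i, " (", kind, ")")
  }
  out <- list(logits = cur)
  if (keep_cache) out$cache <- list(caches = caches, block_in = block_in)
  out
}

#' Backward pass
#'
#' Backpropagates a gradient on the logits through the cached forward pass
#' and returns per-parameter gradients.
#'
#' @param net A [build_network()] result.
#' @param fwd Result of `net_forward(net, x, keep_cache = TRUE)`.
#' @param dlogits Gradient array matching `fwd$logits`.
#' @return Named list of gradients, same names as `net$params`.
#' @export
net_backward <- function(net, fwd, dlogits) {
  l <- net$spec$layers
  p <- net$params
  caches <- fwd$cache$caches
  grads <- list()
  dcur <- dlogits
  dskips <- list()
  dblock <- list()   # block id -> residual gradient for the block input
  ds_total <- sum(l$kind == "downsample")
  ds_seen <- ds_total
  for (i in rev(seq_len(nrow(l)))) {
    kind <- l$kind[i]
    if (kind %in% c("stem_conv7", "downsample", "pw_reduce", "head_conv",
                    "pw_expand", "pw_project", "shortcut_proj")) {
      dy <- dcur
      if (kind == "pw_expand") dy <- gelu_bwd(dcur, caches[[i]]$z)
      if (kind == "pw_project" && !caches[[i]]$has_proj)
        dblock[[l$block[i]]] <- dcur  # identity residual branch
      cb <- conv_bwd(dy, p[[paste0("L", i, "_W")]], l$kernel[i],
                     l$stride[i], l$padding[i], caches[[i]]$cache)
      grads[[paste0("L", i, "_W")]] <- cb$dW
      grads[[paste0("L", i, "_b")]] <- cb$db
      if (kind == "shortcut_proj") {
        dblock[[l$block[i]]] <- cb$dx  # projected residual branch
        # dcur continues unchanged into pw_project
      } else {
        dcur <- cb$dx
        if (kind == "downsample") {
          sk <- paste0("s", ds_seen)
          if (!is.null(dskips[[sk]])) dcur <- dcur + dskips[[sk]]
          ds_seen <- ds_seen - 1L
        }
      }
    } else if (kind == "dw_conv7") {
      db <- dwconv_bwd(dcur, p[[paste0("L", i, "_W")]], caches[[i]]$cache)
      grads[[paste0("L", i, "_W")]] <- db$dW
      grads[[paste0("L", i, "_b")]] <- db$db
      dcur <- db$dx
      res <- dblock[[l$block[i]]]
      if (!is.null(res)) dcur <- dcur + res
    } else if (kind == "layer_norm") {
      lb <- ln_bwd(dcur, p[[paste0("L", i, "_g")]], caches[[i]]$cache)
      grads[[paste0("L", i, "_g")]] <- lb$dgamma
      grads[[paste0("L", i, "_be")]] <- lb$dbeta
      dcur <- lb$dx
    } else if (kind == "upsample_bilinear") {
      dcur <- up2_bwd(dcur, caches[[i]]$in_dim)
    } else if (kind == "concat_skip") {
      cm <- caches[[i]]$c_main
      d <- dim(dcur)
      dsk <- dcur[, , , (cm + 1L):d[4], drop = FALSE]
      sk <- caches[[i]]$skip
      dskips[[sk]] <- if (is.null(dskips[[sk]])) dsk else dskips[[sk]] + dsk
      dcur <- dcur[, , , seq_len(cm), drop = FALSE]
    }
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Combined focal + dice loss with logit gradients
#'
#' Computes the training loss of a logits batch against integer label maps
#' and the exact gradient with respect to the logits (softmax chained
#' through both components).
#'
#' @param logits Array `(H, W, B, K)`.
#' @param labels Integer array `(H, W, B)` with values `0..K-1`.
#' @param w_focal,w_dice Component weights (default 1 and 1).
#' @param gamma Focal focusing parameter (default 2).
#' @return List with `loss`, `focal`, `dice`, `dlogits`.
#' @export
loss_and_grad <- function(logits, labels, w_focal = 1, w_dice = 1,
                          gamma = 2) {
  d <- dim(logits)
  K <- d[4]
  N <- d[1] * d[2] * d[3]
  Z <- logits; dim(Z) <- c(N, K)
  y <- as.integer(labels) + 1L
  P <- softmax_rows(Z)
  Y <- matrix(0, N, K)
  Y[cbind(seq_len(N), y)] <- 1
  pt <- P[cbind(seq_len(N), y)]
  ptc <- pmax(pt, FOCAL_EPS)
  focal <- mean(-(1 - ptc)^gamma * log(ptc))
  dldpt <- (gamma * (1 - ptc)^(gamma - 1) * log(ptc) -
            (1 - ptc)^gamma / ptc) / N
  dzF <- (dldpt * pt) * (Y - P)
  num <- 2 * colSums(P * Y) + DICE_EPS
  den <- colSums(P) + colSums(Y) + DICE_EPS
  dice <- 1 - mean(num / den)
  G <- -(2 * Y * rep(den, each = N) - rep(num, each = N)) /
    rep(den^2, each = N) / K
  dzD <- P * (G - rowSums(G * P))
  dlog <- w_focal * dzF + w_dice * dzD
  dim(dlog) <- d
  list(loss = w_focal * focal + w_dice * dice, focal = focal, dice = dice,
       dlogits = dlog)
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr = 0.0015,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 5e-5) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * step -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

scenes_to_batch <- function(scenes, idx) {
  H <- dim(scenes[[idx[1]]]$image)[1]
  W <- dim(scenes[[idx[1]]]$image)[2]
  B <- length(idx)
  x <- array(0, c(H, W, B, 3))
  yl <- array(0L, c(H, W, B))
  for (b in seq_len(B)) {
    x[, , b, ] <- scenes[[idx[b]]]$image
    yl[, , b] <- scenes[[idx[b]]]$mask
  }
  list(x = x, labels = yl)
}

#' Train a network on labeled scenes
#'
#' Minimizes the combined focal + dice loss with AdamW (learning rate
#' 0.0015, weight decay 5e-5 by default) over shuffled mini-batches.
#' Deterministic given `seed`. A non-finite loss aborts with an error
#' identifying the batch.
#'
#' @param net A [build_network()] result (weights are updated functionally;
#'   the trained network is returned).
#' @param scenes List of scenes, each `list(image = (H,W,3) in [0,1],
#'   mask = (H,W) labels 0..K-1)`.
#' @param epochs Number of passes over the scenes.
#' @param batch_size Mini-batch size (default 4).
#' @param lr,weight_decay AdamW hyperparameters.
#' @param warmup Number of linear learning-rate warmup steps (stabilizes
#'   AdamW's early second-moment estimates); default 10.
#' @param seed Seed for shuffling.
#' @param w_focal,w_dice,gamma Loss configuration.
#' @return List with `net` (trained) and `loss_history` (per-batch).
#' @export
train_network <- function(net, scenes, epochs = 1, batch_size = 4,
                          lr = 0.0015, weight_decay = 5e-5, warmup = 10,
                          seed = 1L, w_focal = 1, w_dice = 1, gamma = 2) {
  set.seed(seed)
  opt <- adamw_init(net$params)
  hist <- numeric(0)
  step <- 0L
  for (e in seq_len(epochs)) {
    ord <- sample(length(scenes))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (bi in seq_along(batches)) {
      bt <- scenes_to_batch(scenes, batches[[bi]])
      fwd <- net_forward(net, bt$x, keep_cache = TRUE)
      lg <- loss_and_grad(fwd$logits, bt$labels, w_focal, w_dice, gamma)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", e,
             " batch ", bi)
      grads <- net_backward(net, fwd, lg$dlogits)
      step <- step + 1L
      lr_t <- lr * min(1, step / max(1, warmup))
      upd <- adamw_step(net$params, grads, opt, lr = lr_t,
                        weight_decay = weight_decay)
      net$params <- upd$params
      opt <- upd$state
      hist <- c(hist, lg$loss)
    }
  }
  list(net = net, loss_history = hist)
}

#' Predict label maps
#'
#' Argmax over the class logits in eval mode (deterministic).
#'
#' @param net A trained network.
#' @param scenes List of scenes (only `$image` is used).
#' @param batch_size Scenes per forward pass.
#' @return List of integer `(H, W)` label maps (`0..K-1`).
#' @export
predict_network <- function(net, scenes, batch_size = 4) {
  out <- vector("list", length(scenes))
  idxs <- split(seq_along(scenes),
                ceiling(seq_along(scenes) / batch_size))
  for (ix in idxs) {
    bt <- scenes_to_batch(scenes, ix)
    lg <- net_forward(net, bt$x)$logits
    d <- dim(lg)
    for (b in seq_along(ix)) {
      sl <- lg[, , b, , drop = FALSE]
      dim(sl) <- c(d[1] * d[2], d[4])
      out[[ix[b]]] <- matrix(max.col(sl, ties.method = "first") - 1L,
                             d[1], d[2])
    }
  }
  out
}

#' Evaluate a network's segmentation metrics
#'
#' @param net A trained network.
#' @param scenes Scenes with `$image` and `$mask`.
#' @return A `"metrics_report"` over all pixels of all scenes.
#' @export
evaluate_network <- function(net, scenes) {
  preds <- predict_network(net, scenes)
  cm <- Reduce(`+`, lapply(seq_along(scenes), function(i)
    unclass(confusion(preds[[i]], scenes[[i]]$mask, K = 4))))
  metrics_from_confusion(cm)
}
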