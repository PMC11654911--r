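# shared fixtures: tiny channel plans, cached scene sets, numeric gradients

tiny_plan <- function(seed = 42, lo = 3L, hi = 7L) {
  set.seed(seed)
  ids <- base_channel_plan()$layer_id
  channel_plan(ids, base = rep(6L, 43),
               optimized = sample(lo:hi, 43, replace = TRUE))
}

# scenes are expensive enough to share across tests
scene_cache <- new.env(parent = emptyenv())
cached_scenes <- function(n, size = 64, seed = 100) {
  key <- paste(n, size, seed, sep = "_")
  if (is.null(scene_cache[[key]]))
    scene_cache[[key]] <- generate_scenes(n, scene_params(size = size,
                                                          seed = seed))
  scene_cache[[key]]
}

num_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(j) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))
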