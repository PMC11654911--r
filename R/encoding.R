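# Channel-plan encoding: decision vectors in [-0.5, 0.5]^43 <-> per-layer
# channel counts of the 43 tunable convolution layers (31 down-sampling
# "DSCL" slots + 12 up-sampling "USCL" slots; depthwise layers are not
# slot-bound).

#' Construct a channel plan
#'
#' A channel plan is an ordered table of the 43 tunable convolution layers
#' with their base and optimized channel counts.
#'
#' @param layer_id Character vector of layer labels (e.g. `"DSCL 01"`).
#' @param base Positive integer base channel counts.
#' @param optimized Positive integer optimized counts (defaults to `base`).
#' @return A data frame of class `"channel_plan"`.
#' @export
channel_plan <- function(layer_id, base, optimized = base) {
  stopifnot(length(layer_id) == length(base),
            length(base) == length(optimized),
            all(base >= 1), all(optimized >= 1))
  structure(data.frame(layer_id = as.character(layer_id),
                       base = as.integer(base),
                       optimized = as.integer(optimized),
                       stringsAsFactors = FALSE),
            class = c("channel_plan", "data.frame"))
}

#' Reference channel plans of the segmentation network
#'
#' Loads the packaged channel table of the published UConvNeXt /
#' AAUConvNeXt models: 31 down-sampling and 12 up-sampling tunable
#' convolution layers with base and optimized channel counts and the
#' printed reduction ratios.
#'
#' @return Data frame with columns `layer_id`, `base`, `optimized`,
#'   `printed_reduction_pct`.
#' @export
reference_channel_table <- function() {
  path <- system.file("extdata", "uconvnext_channel_plan.csv",
                      package = "lodgeopt", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Baseline (identity) channel plan
#'
#' The UConvNeXt base channel counts with `optimized = base`.
#' @return A [channel_plan()].
#' @export
base_channel_plan <- function() {
  tab <- reference_channel_table()
  channel_plan(tab$layer_id, tab$base)
}

#' Published optimized channel plan
#'
#' The AAUConvNeXt channel counts found by the published search.
#' @return A [channel_plan()].
#' @export
published_channel_plan <- function() {
  tab <- reference_channel_table()
  channel_plan(tab$layer_id, tab$base, tab$optimized)
}

#' Published ablation metrics table
#'
#' Metrics (PA, MPA, mIoU in percent; parameters in millions; FLOPs in
#' billions) of the baseline, AFOA-optimized and AFOA-APOM-optimized models
#' on the real rice-lodging dataset, as published.
#'
#' @return Data frame with one row per model.
#' @export
reference_ablation_table <- function() {
  path <- system.file("extdata", "ablation_metrics.csv",
                      package = "lodgeopt", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Decode a decision vector into channel counts
#'
#' Each coordinate `x_v` in `[-0.5, 0.5]` changes layer `v`'s channel count
#' as `optimized_v = base_v - floor(base_v * x_v)` (floor toward minus
#' infinity, so negative coordinates increase channels: base 64 at
#' `x = -0.5` gives `64 - floor(-32) = 96`). Decoded counts are clamped to
#' at least 1.
#'
#' @param x Numeric vector with one coordinate per plan row, inside
#'   `[-0.5, 0.5]`.
#' @param base_plan A [channel_plan()] supplying the base counts.
#' @return A [channel_plan()] with the decoded `optimized` column.
#' @export
decode_channels <- function(x, base_plan = base_channel_plan()) {
  stopifnot(inherits(base_plan, "channel_plan"))
  if (length(x) != nrow(base_plan))
    stop("decision vector length ", length(x), " != plan length ",
         nrow(base_plan))
  if (any(x < -0.5 - 1e-12) || any(x > 0.5 + 1e-12))
    stop("decision coordinates must lie in [-0.5, 0.5]; clip before decoding")
  opt <- pmax(1L, as.integer(base_plan$base - floor(base_plan$base * x)))
  channel_plan(base_plan$layer_id, base_plan$base, opt)
}

#' Per-layer channel reduction ratio
#'
#' `100 * (base - optimized) / base`, rounded half-up to two decimals;
#' negative values denote channel increases.
#'
#' @param base,optimized Integer vectors of channel counts (`base >= 1`).
#' @return Numeric vector of percentages.
#' @examples
#' reduction_ratio(1024, 1469)  # -43.46
#' reduction_ratio(1024, 540)   #  47.27
#' @export
reduction_ratio <- function(base, optimized) {
  if (any(base < 1)) stop("base channel count must be >= 1")
  round_half_up(100 * (base - optimized) / base, 2)
}

# round half away from zero at `digits` decimals (print convention of the
# reference channel table; base R round() is half-to-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a channel plan as a reduction report
#'
#' Computes the per-layer reduction ratios and tallies how many layers
#' increased, decreased, or kept their channel count.
#'
#' @param plan A [channel_plan()].
#' @return An object of class `"reduction_report"`: list with `rows`
#'   (data frame `layer_id`, `base`, `optimized`,
#'   `reduction_ratio_percent`) and `summary` (`n_increased`,
#'   `n_decreased`, `n_unchanged`).
#' @export
summarize_plan <- function(plan) {
  stopifnot(inherits(plan, "channel_plan"))
  rows <- data.frame(
    layer_id = plan$layer_id,
    base = plan$base,
    optimized = plan$optimized,
    reduction_ratio_percent = reduction_ratio(plan$base, plan$optimized),
    stringsAsFactors = FALSE)
  structure(list(rows = rows,
                 summary = list(
                   n_increased = sum(plan$optimized > plan$base),
                   n_decreased = sum(plan$optimized < plan$base),
                   n_unchanged = sum(plan$optimized == plan$base))),
            class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(format_reduction_report(x), sep = "\n")
  invisible(x)
}

#' Format a reduction report as aligned text
#'
#' @param report A `"reduction_report"`.
#' @return Character vector of lines.
#' @export
format_reduction_report <- function(report) {
  r <- report$rows
  lines <- sprintf("%-8s %6d %6d %9.2f%%", r$layer_id, r$base, r$optimized,
                   r$reduction_ratio_percent)
  header <- sprintf("%-8s %6s %6s %10s", "layer", "base", "opt", "reduction")
  s <- report$summary
  c(header, lines,
    sprintf("increased %d  decreased %d  unchanged %d",
            s$n_increased, s$n_decreased, s$n_unchanged))
}
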