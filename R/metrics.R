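# Composite focal + dice training loss and the confusion-matrix metric
# suite (pixel accuracy, mean pixel accuracy, IoU / mIoU, precision,
# recall, F1).

FOCAL_EPS <- 1e-12   # probability clamp inside log
DICE_EPS <- 1e-6     # smoothing against 0/0 on absent classes

#' Focal loss from true-class probabilities
#'
#' Mean over pixels of `-(1 - pt)^gamma * log(pt)` where `pt` is the
#' predicted probability of each pixel's true class. `gamma = 0` reduces to
#' cross-entropy; the default `gamma = 2` down-weights easy pixels, which
#' counteracts class imbalance (lodged canopy is rare relative to
#' background and upright canopy).
#'
#' @param pt Numeric vector/array of true-class probabilities in `[0, 1]`.
#' @param gamma Focusing parameter, default 2.
#' @return Scalar loss.
#' @examples
#' focal_loss(1)            # 0
#' focal_loss(0.5)          # -0.25 * log(0.5) ~= 0.17329
#' @export
focal_loss <- function(pt, gamma = 2) {
  if (any(pt < 0) || any(pt > 1)) stop("pt must lie in [0, 1]")
  ptc <- pmax(pt, FOCAL_EPS)
  mean(-(1 - ptc)^gamma * log(ptc))
}

#' Dice loss between predicted probabilities and one-hot labels
#'
#' `1 - mean_k [ 2 * sum_i y_ik p_ik / (sum_i p_ik + sum_i y_ik) ]`
#' averaged over classes, with a small smoothing term in numerator and
#' denominator so classes absent from both prediction and truth contribute
#' a perfect overlap instead of 0/0.
#'
#' @param pred Numeric matrix `n_pixels x K` of class probabilities (or a
#'   vector for `K = 1` binary overlap).
#' @param target Same shape, one-hot (or probabilistic) labels.
#' @param eps Smoothing constant, default `1e-6`.
#' @return Scalar loss in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(pred, target, eps = DICE_EPS) {
  if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1)
  if (is.null(dim(target))) target <- matrix(target, ncol = 1)
  if (!all(dim(pred) == dim(target)))
    stop("pred and target shapes differ")
  num <- 2 * colSums(pred * target) + eps
  den <- colSums(pred) + colSums(target) + eps
  1 - mean(num / den)
}

#' Combined focal + dice loss
#'
#' Weighted sum `w_focal * focal + w_dice * dice`; both weights default to
#' 1 so the two components contribute equally.
#'
#' @param pred `n_pixels x K` probability matrix.
#' @param target `n_pixels x K` one-hot label matrix.
#' @param w_focal,w_dice Nonnegative component weights.
#' @param gamma Focal focusing parameter.
#' @return Scalar loss.
#' @export
combined_loss <- function(pred, target, w_focal = 1, w_dice = 1,
                          gamma = 2) {
  if (w_focal < 0 || w_dice < 0) stop("loss weights must be nonnegative")
  pt <- rowSums(pred * target)
  w_focal * focal_loss(pt, gamma) + w_dice * dice_loss(pred, target)
}

#' Pixel confusion matrix
#'
#' `counts[i, j]` is the number of pixels with true class `i` predicted as
#' class `j` (labels `0..K-1`).
#'
#' @param pred,true Integer label vectors/arrays in `{0, ..., K-1}`.
#' @param K Number of classes.
#' @param class_names Optional length-`K` labels; defaults to
#'   `BG, NL, HL, L` when `K = 4`.
#' @return Object of class `"confusion_matrix"`: integer `K x K` matrix
#'   with dimnames `true` x `predicted`.
#' @export
confusion <- function(pred, true, K = 4, class_names = NULL) {
  pred <- as.integer(pred); true <- as.integer(true)
  if (length(pred) != length(true)) stop("length mismatch")
  if (any(pred < 0 | pred >= K) || any(true < 0 | true >= K))
    stop("labels must lie in {0..K-1}")
  if (is.null(class_names))
    class_names <- if (K == 4) c("BG", "NL", "HL", "L")
                   else paste0("C", seq_len(K) - 1)
  counts <- matrix(tabulate(true * K + pred + 1L, nbins = K * K),
                   nrow = K, byrow = TRUE,
                   dimnames = list(true = class_names,
                                   predicted = class_names))
  structure(counts, class = c("confusion_matrix", class(counts)))
}

#' Row-normalize a confusion matrix
#'
#' Divides each row by its sum so rows sum to 1; the diagonal then equals
#' per-class recall. Zero rows (classes absent from the truth) are emitted
#' as zeros with a warning.
#'
#' @param cm A confusion matrix (counts).
#' @return Numeric `K x K` matrix of row proportions.
#' @export
normalize_rows <- function(cm) {
  cm <- unclass(cm)
  rs <- rowSums(cm)
  if (any(rs == 0))
    warning("confusion matrix has empty true-class rows; emitted as zeros")
  out <- cm / ifelse(rs == 0, 1, rs)
  out[rs == 0, ] <- 0
  out
}

#' Segmentation metrics from a confusion matrix
#'
#' Computes pixel accuracy `PA = trace/total`, per-class pixel accuracy
#' (recall), their mean `MPA`, per-class `IoU = TP/(TP+FP+FN)` and `mIoU`,
#' and per-class precision, recall and `F1 = 2PR/(P+R)`. Classes absent
#' from both prediction and truth (`TP+FP+FN = 0`) are excluded from the
#' MPA and mIoU means.
#'
#' @param cm A [confusion()] matrix.
#' @return Object of class `"metrics_report"`: list with `pa`, `mpa`,
#'   `miou`, and per-class vectors `iou`, `precision`, `recall`, `f1`,
#'   `pa_class`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  present <- (tp + fp + fn) > 0
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  iou <- ifelse(present, tp / (tp + fp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(present, 0, NA_real_))
  structure(list(
    pa = sum(tp) / total,
    pa_class = recall,
    mpa = mean(recall[present], na.rm = TRUE),
    iou = iou,
    miou = mean(iou[present]),
    precision = precision,
    recall = recall,
    f1 = f1), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PA   %.4f\nMPA  %.4f\nmIoU %.4f\n", x$pa, x$mpa, x$miou))
  tab <- rbind(IoU = x$iou, P = x$precision, R = x$recall, F1 = x$f1)
  print(round(tab, 4))
  invisible(x)
}

#' Segmentation metrics from label maps
#'
#' Convenience wrapper: tallies the confusion matrix of `pred` vs `true`
#' and returns [metrics_from_confusion()].
#'
#' @inheritParams confusion
#' @return A `"metrics_report"`.
#' @export
segmentation_metrics <- function(pred, true, K = 4) {
  metrics_from_confusion(confusion(pred, true, K))
}
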