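#' Pixel-level segmentation metrics
#'
#' Exact confusion counts between a predicted and a reference binary mask,
#' with accuracy, precision, recall and F1. Precision/recall are defined
#' as 0 (and flagged via the `undefined` attribute) when their denominator
#' is 0.
#'
#' @param pred,truth Binary masks (logical or 0/1) of equal shape.
#' @return A `pixel_metrics` list: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
pixel_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  undef <- character()
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undef <- c(undef, "precision"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undef <- c(undef, "recall"); 0 }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              accuracy = (tp + tn) / (tp + fp + fn + tn),
              precision = precision, recall = recall, f1 = f1)
  if (length(undef)) attr(out, "undefined") <- undef
  class(out) <- "pixel_metrics"
  out
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf(
    "<pixel_metrics> acc %.4f  prec %.4f  rec %.4f  F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Object-level instance segmentation metrics
#'
#' One-to-one greedy matching of predicted to reference instances by
#' descending IoU; pairs with IoU at or above the threshold are true
#' positives, unmatched predictions are false positives and unmatched
#' reference objects false negatives.
#'
#' @param pred,truth Integer instance maps (0 = background) of equal
#'   shape.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return An `instance_metrics` list with `precision`, `recall`, `f1`,
#'   counts, and the matched pair table (`pred`, `truth`, `iou`).
#' @export
instance_metrics <- function(pred, truth, iou_threshold = 0.5) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  pl <- sort(setdiff(unique(as.integer(pred)), 0L))
  tl <- sort(setdiff(unique(as.integer(truth)), 0L))
  n_pred <- length(pl); n_truth <- length(tl)
  pairs <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  if (n_pred && n_truth) {
    keep <- pred > 0 & truth > 0
    if (any(keep)) {
      ct <- table(factor(pred[keep], levels = pl),
                  factor(truth[keep], levels = tl))
      pa <- tabulate(factor(pred[pred > 0], levels = pl), n_pred)
      ta <- tabulate(factor(truth[truth > 0], levels = tl), n_truth)
      iou <- as.matrix(ct) / (outer(pa, ta, `+`) - as.matrix(ct))
      cand <- which(iou >= iou_threshold, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(-iou[cand], cand[, 1], cand[, 2])
        used_p <- logical(n_pred); used_t <- logical(n_truth)
        for (q in ord) {
          i <- cand[q, 1]; j <- cand[q, 2]
          if (!used_p[i] && !used_t[j]) {
            used_p[i] <- TRUE; used_t[j] <- TRUE
            pairs <- rbind(pairs, data.frame(pred = pl[i], truth = tl[j],
                                             iou = iou[i, j]))
          }
        }
      }
    }
  }
  tp <- nrow(pairs)
  precision <- if (n_pred > 0) tp / n_pred else 0
  recall <- if (n_truth > 0) tp / n_truth else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, n_pred = n_pred, n_truth = n_truth,
                 iou_threshold = iou_threshold, pairs = pairs,
                 mean_matched_iou = if (tp) mean(pairs$iou) else NA_real_),
            class = "instance_metrics")
}

#' @export
print.instance_metrics <- function(x, ...) {
  cat(sprintf(
    "<instance_metrics> prec %.4f rec %.4f F1 %.4f (%d/%d pred, %d truth, IoU>=%.2f)\n",
    x$precision, x$recall, x$f1, x$tp, x$n_pred, x$n_truth,
    x$iou_threshold))
  invisible(x)
}

#' Agreement error metrics
#'
#' Mean absolute error, mean squared error and root mean squared error
#' between predictions and reference values.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return List with `mae`, `mse`, `rmse`.
#' @export
error_metrics <- function(pred, truth) {
  if (length(pred) != length(truth) || !length(pred))
    stop("pred and truth must have equal positive length")
  d <- pred - truth
  list(mae = mean(abs(d)), mse = mean(d^2), rmse = sqrt(mean(d^2)))
}

#' Simple linear regression with R-squared
#'
#' Ordinary least squares of `y` on `x` with intercept;
#' `r_squared = 1 - SSres / SStot` (0 for a constant response).
#'
#' @param x,y Numeric vectors (length >= 3, `x` not constant).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}
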