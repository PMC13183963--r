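# Exhaustive one-to-one matching oracle for instance metrics: maximize
# matched pairs at the IoU threshold (then total IoU) over all
# assignments. Only feasible for small toys.
brute_instance_metrics <- function(pred, truth, thr) {
  pl <- sort(setdiff(unique(as.integer(pred)), 0L))
  tl <- sort(setdiff(unique(as.integer(truth)), 0L))
  iou <- matrix(0, length(pl), length(tl))
  for (i in seq_along(pl)) for (j in seq_along(tl)) {
    a <- pred == pl[i]; b <- truth == tl[j]
    iou[i, j] <- sum(a & b) / sum(a | b)
  }
  best_tp <- 0; best_sum <- 0
  k <- min(length(pl), length(tl))
  if (k > 0) {
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (subset_p in utils::combn(seq_along(pl), k, simplify = FALSE))
      for (pt in perms(seq_along(tl))) {
        pairs <- cbind(subset_p, pt[seq_len(k)])
        ious <- iou[pairs]
        tp <- sum(ious >= thr)
        s <- sum(ious[ious >= thr])
        if (tp > best_tp || (tp == best_tp && s > best_sum)) {
          best_tp <- tp; best_sum <- s
        }
      }
  }
  list(tp = best_tp,
       precision = if (length(pl)) best_tp / length(pl) else 0,
       recall = if (length(tl)) best_tp / length(tl) else 0)
}
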