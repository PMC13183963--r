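# Instance segmentation by flow tracking: the count network predicts a
# cell-probability map plus horizontal/vertical unit-gradient (flow) maps;
# post-processing advects thresholded pixels along the flows and clusters
# the converged positions into instances.

#' Post-processing parameters for flow-based instance segmentation
#'
#' @param prob_threshold Minimum cell probability for a pixel to enter
#'   flow tracking.
#' @param max_flow_error Instances whose re-derived flows disagree with
#'   the predicted flows by more than this mean squared vector error are
#'   discarded (quality-control filter).
#' @param min_object_px Minimum instance size in pixels.
#' @param n_integration_steps Euler steps of flow following.
#' @param step_size Step length in pixels.
#' @param seed_min_count Minimum number of converged trajectories for a
#'   histogram cell to seed an instance.
#' @param expand_iters Seed-region growth iterations over the landing
#'   histogram.
#' @return A `seg_params` list.
#' @export
seg_params <- function(prob_threshold = 0.5, max_flow_error = 0.9,
                       min_object_px = 9, n_integration_steps = 200,
                       step_size = 1, seed_min_count = 3,
                       expand_iters = 5) {
  stopifnot(prob_threshold > 0, max_flow_error > 0, min_object_px > 0,
            n_integration_steps > 0, step_size > 0)
  structure(list(prob_threshold = prob_threshold,
                 max_flow_error = max_flow_error,
                 min_object_px = as.integer(min_object_px),
                 n_integration_steps = as.integer(n_integration_steps),
                 step_size = step_size,
                 seed_min_count = as.integer(seed_min_count),
                 expand_iters = as.integer(expand_iters)),
            class = "seg_params")
}

#' Construct a flow field
#' @param prob Cell-probability map in \[0,1\].
#' @param dy,dx Vertical/horizontal flow components; the vector norm must
#'   not exceed 1 (+1e-6).
#' @return A `flow_field` object.
#' @export
flow_field <- function(prob, dy, dx) {
  stopifnot(identical(dim(prob), dim(dy)), identical(dim(prob), dim(dx)))
  if (max(sqrt(dy^2 + dx^2)) > 1 + 1e-6)
    stop("flow vector norms must not exceed 1")
  structure(list(prob = prob, dy = dy, dx = dx), class = "flow_field")
}

#' Ground-truth flows from an instance map
#'
#' For each object, heat is diffused from the object's median-centre pixel
#' within the object; the flow is the normalized spatial gradient of the
#' diffused field, so every interior vector points toward the object
#' centre. `prob` is 1 inside objects and 0 outside.
#'
#' @param instances Integer instance map (0 = background).
#' @return A [flow_field()].
#' @export
masks_to_flows <- function(instances) {
  m <- matrix(as.integer(instances), nrow(instances), ncol(instances))
  r <- cq_masks_to_flows(m)
  flow_field(r$prob, r$dy, r$dx)
}

#' Cluster a flow field into instances
#'
#' Pixels with probability at or above the threshold are advected along
#' the flow field (fixed-step bilinear Euler integration); converged
#' positions are histogrammed, local maxima seed instances, and each pixel
#' receives the label of the seed region its trajectory lands in (lowest
#' label id wins ties). Instances are then hole-filled, small objects
#' removed, and instances failing the flow-consistency check discarded.
#'
#' @param field A [flow_field()].
#' @param params A [seg_params()].
#' @return Integer instance map with contiguous labels `1..K` (possibly
#'   `K = 0`).
#' @export
follow_flows <- function(field, params = seg_params()) {
  stopifnot(inherits(field, "flow_field"))
  lab <- cq_follow_flows(field$prob, field$dy, field$dx,
                         params$prob_threshold,
                         params$n_integration_steps, params$step_size,
                         params$seed_min_count, params$expand_iters)
  if (max(lab) == 0) return(lab)
  lab <- matrix(as.integer(EBImage::fillHull(lab)), nrow(lab), ncol(lab))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(sizes > 0 & sizes < params$min_object_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (max(lab) > 0 && is.finite(params$max_flow_error)) {
    ref <- masks_to_flows(lab)
    for (l in setdiff(unique(as.integer(lab)), 0L)) {
      px <- lab == l
      err <- mean((field$dy[px] - ref$dy[px])^2 +
                    (field$dx[px] - ref$dx[px])^2)
      if (err > params$max_flow_error) lab[px] <- 0L
    }
  }
  relabel_contiguous(lab)
}

relabel_contiguous <- function(lab) {
  ids <- unique(as.integer(t(lab)))   # row-major first-occurrence order
  ids <- ids[ids != 0L]
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- lut[lab[lab > 0]]
  out
}

#' Count objects in an ROI with the hemocytometer boundary rule
#'
#' Objects whose centroid lies inside the ROI are counted; objects
#' crossing the top or left ROI edge are also counted, while objects
#' touching or crossing the bottom or right edge are excluded — the
#' standard counting-chamber convention that makes tiled counts unbiased.
#'
#' @param instances Integer instance map.
#' @param roi `NULL` (full frame) or `c(x0, y0, x1, y1)` in 0-based
#'   half-open pixel coordinates.
#' @return Integer count.
#' @export
count_cells <- function(instances, roi = NULL) {
  H <- nrow(instances); W <- ncol(instances)
  if (is.null(roi)) roi <- c(0, 0, W, H)
  stopifnot(length(roi) == 4, roi[2] < roi[4], roi[1] < roi[3])
  if (roi[3] <= 0 || roi[4] <= 0 || roi[1] >= W || roi[2] >= H)
    stop("empty roi")
  labs <- setdiff(unique(as.integer(instances)), 0L)
  n <- 0L
  for (l in labs) {
    idx <- which(instances == l)
    y <- (idx - 1L) %% H
    x <- (idx - 1L) %/% H
    inside <- x >= roi[1] & x < roi[3] & y >= roi[2] & y < roi[4]
    if (!any(inside)) next
    if (any(x >= roi[3]) || any(y >= roi[4])) next        # bottom/right
    if (any(x < roi[1]) || any(y < roi[2])) { n <- n + 1L; next }  # top/left
    cy <- mean(y); cx <- mean(x)
    if (cx >= roi[1] && cx < roi[3] && cy >= roi[2] && cy < roi[4])
      n <- n + 1L
  }
  n
}

#' Concentration from per-square counts
#'
#' `mean(counts) / (square_side_mm^2 x depth_mm x 1e-3 mL/mm^3) x
#' dilution_factor` — the standard hemocytometer formula.
#'
#' @param counts_per_square Integer counts, one per counted square.
#' @param geometry A [chamber_geometry()].
#' @return A `count_result` with `count` (total), `counts_per_square`,
#'   `concentration` in cells/mL and the geometry.
#' @export
concentration <- function(counts_per_square, geometry) {
  stopifnot(length(counts_per_square) >= 1,
            inherits(geometry, "chamber_geometry"))
  conc <- mean(counts_per_square) / square_volume_ml(geometry) *
    geometry$dilution_factor
  structure(list(count = sum(counts_per_square),
                 counts_per_square = counts_per_square,
                 concentration = conc, geometry = geometry),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> %d objects over %d square(s): %.3g cells/mL\n",
              x$count, length(x$counts_per_square), x$concentration))
  invisible(x)
}

# Instance map with debris labels removed, for training targets and
# counting ground truth.
countable_instances <- function(sample) {
  stopifnot(inherits(sample, "rendered_sample"))
  inst <- sample$instance_map
  drop <- sample$objects$label_id[sample$objects$class == "debris"]
  if (length(drop)) inst[inst %in% drop] <- 0L
  inst
}
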