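# Synthetic brightfield rendering. Objects are irregular ellipses whose
# boundary radius is perturbed by low-order Fourier modes, with a bright or
# dark rim depending on scene type. Coordinates are pixel-centred, 0-based,
# x rightward / y downward; reported tables use the same convention.

# Rasterize one blob. Returns linear (1-based) pixel indices into an HxW
# matrix for the interior and the rim, plus the normalised radius of each
# interior pixel (0 at centre, 1 at boundary).
rasterize_blob <- function(H, W, cy, cx, a, b, theta, amps, phases,
                           rim_frac = 0.18) {
  k_modes <- seq_along(amps) + 1
  rmax <- max(a, b) * (1 + sum(abs(amps))) * (1 + rim_frac) + 1.5
  y0 <- max(0, floor(cy - rmax)); y1 <- min(H - 1, ceiling(cy + rmax))
  x0 <- max(0, floor(cx - rmax)); x1 <- min(W - 1, ceiling(cx + rmax))
  if (y0 > y1 || x0 > x1)
    return(list(idx_in = integer(), idx_rim = integer(), rad = numeric()))
  ys <- y0:y1; xs <- x0:x1
  ny <- length(ys); nx <- length(xs)
  dyg <- matrix(ys - cy, ny, nx)
  dxg <- matrix(xs - cx, ny, nx, byrow = TRUE)
  u <- (cos(theta) * dxg + sin(theta) * dyg) / a
  v <- (-sin(theta) * dxg + cos(theta) * dyg) / b
  rho <- sqrt(u * u + v * v)
  rb <- 1
  if (length(amps) && any(amps != 0)) {
    phi <- atan2(v, u)
    for (k in seq_along(amps))
      rb <- rb + amps[k] * cos(k_modes[k] * phi + phases[k])
  }
  inside <- rho <= rb
  rim <- !inside & rho <= rb * (1 + rim_frac)
  lin <- outer(ys + 1L, xs * H + 1L, `+`) - 1L  # row + H*col, 1-based
  rad <- if (length(rb) > 1) rho[inside] / rb[inside] else rho[inside] / rb
  list(idx_in = lin[inside], idx_rim = lin[rim], rad = pmin(rad, 1))
}

scene_background <- function(spec, level, noise_sd = 0.02) {
  H <- spec$height_px; W <- spec$width_px
  gx <- stats::runif(1, -0.05, 0.05); gy <- stats::runif(1, -0.05, 0.05)
  plane <- outer((seq_len(H) - H / 2) / H, rep(1, W)) * gy +
           outer(rep(1, H), (seq_len(W) - W / 2) / W) * gx
  level + plane + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
}

new_rendered_sample <- function(image, semantic_mask, instance_map, objects,
                                spec, roi = NULL) {
  structure(list(image = image, semantic_mask = semantic_mask,
                 instance_map = instance_map, objects = objects,
                 coverage_pct = 100 * sum(semantic_mask) /
                   length(semantic_mask),
                 roi = roi, spec = spec),
            class = "rendered_sample")
}

#' @export
print.rendered_sample <- function(x, ...) {
  cat("<rendered_sample>", paste(dim(x$semantic_mask), collapse = "x"),
      "px,", nrow(x$objects), "objects, coverage",
      sprintf("%.1f%%", x$coverage_pct), "\n")
  invisible(x)
}

empty_objects <- function() {
  data.frame(label_id = integer(), class = character(), cy = numeric(),
             cx = numeric(), diameter_px = numeric(),
             diameter_um = numeric(), viability = character(),
             stringsAsFactors = FALSE)
}

#' Render a synthetic adherent-culture brightfield field
#'
#' Places irregular cells (ellipses with Fourier-perturbed boundaries,
#' textured interior, bright 1-2 px halo) on a noisy background with an
#' illumination gradient until pixel coverage reaches the spec's target
#' confluency. Coverage lands within about +/-2 percentage points of the
#' target except near geometric saturation, where it is at least 98%.
#' Identical specs (including seed) produce bit-identical samples.
#'
#' @param spec A [scene_spec()] with `scene_kind = "adherent_field"`.
#' @return A `rendered_sample`: `image` in \[0,1\], binary `semantic_mask`,
#'   integer `instance_map`, per-object table, and `coverage_pct` computed
#'   by pixel counting of the emitted mask.
#' @export
render_adherent_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$scene_kind == "adherent_field")
  H <- spec$height_px; W <- spec$width_px
  target <- spec$target_confluency_pct
  min_diam_px <- min(spec$object_mix$diameter_um) / spec$microns_per_px
  if (min(H, W) < min_diam_px)
    stop("image smaller than one cell diameter")
  set.seed(obj_seed(spec$seed, 0L))
  img <- scene_background(spec, level = 0.62)
  mask <- matrix(FALSE, H, W)
  inst <- matrix(0L, H, W)
  objects <- list()
  mix <- spec$object_mix
  cell_rows <- which(mix$class == "cell")
  if (!length(cell_rows)) stop("adherent fields need cells in object_mix")
  stop_at <- if (target > 99) 98.5 else max(target - 0.5, 0)
  cov <- 0; i <- 0L; rejects <- 0L
  max_objects <- ceiling(40 * H * W /
                           (pi * (min_diam_px / 2)^2 + 1)) + 50L
  while (target > 0 && cov < stop_at && i < max_objects && rejects < 400L) {
    i <- i + 1L
    set.seed(obj_seed(spec$seed, i))
    row <- mix[sample(cell_rows, 1, prob = mix$fraction[cell_rows]), ]
    d_px <- max(3, stats::rnorm(1, row$diameter_um, row$diameter_sd_um) /
                  spec$microns_per_px)
    ratio <- stats::runif(1, 1.0, 1.8)
    a <- d_px / 2 * sqrt(ratio); b <- d_px / 2 / sqrt(ratio)
    blob <- rasterize_blob(H, W, stats::runif(1, 0, H - 1),
                           stats::runif(1, 0, W - 1), a, b,
                           stats::runif(1, 0, pi),
                           stats::runif(3, 0, 0.10),
                           stats::runif(3, 0, 2 * pi))
    if (!length(blob$idx_in)) { rejects <- rejects + 1L; next }
    new_px <- blob$idx_in[!mask[blob$idx_in]]
    cov_after <- cov + 100 * length(new_px) / (H * W)
    if (cov_after > target + 1.5 &&
        (cov_after - target) >= (target - cov)) {
      rejects <- rejects + 1L
      next
    }
    rejects <- 0L
    lab <- length(objects) + 1L
    mask[blob$idx_in] <- TRUE
    claim <- blob$idx_in[inst[blob$idx_in] == 0L]
    inst[claim] <- lab
    img[blob$idx_in] <- 0.46 + 0.10 * blob$rad^2 +
      stats::rnorm(length(blob$idx_in), sd = 0.04)
    img[blob$idx_rim] <- 0.88 + stats::rnorm(length(blob$idx_rim), sd = 0.02)
    objects[[lab]] <- data.frame(
      label_id = lab, class = "cell",
      cy = mean((blob$idx_in - 1L) %% H), cx = mean((blob$idx_in - 1L) %/% H),
      diameter_px = 2 * sqrt(length(blob$idx_in) / pi),
      diameter_um = 2 * sqrt(length(blob$idx_in) / pi) * spec$microns_per_px,
      viability = "n/a", stringsAsFactors = FALSE)
    cov <- cov_after
  }
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(spec$defocus))
    img <- apply_defocus(img, spec$defocus[1], spec$defocus[2])
  new_rendered_sample(img, mask * 1L, inst,
                      if (length(objects)) do.call(rbind, objects)
                      else empty_objects(), spec)
}

# per-row object counts by largest remainder, exact for rational fractions
mix_counts <- function(fractions, n) {
  raw <- fractions * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  as.integer(cnt)
}

#' Render a synthetic counting-chamber scene
#'
#' Renders a hemocytometer/KOVA-style scene: etched grid lines at the
#' chamber's pitch, live cells with bright interiors and dark membranes,
#' dead cells with dye-filled interiors (dark blue for Trypan Blue,
#' red-pink for Erythrosin B; stained scenes are RGB), reference beads
#' (dark ring, bright centre) and dark high-eccentricity debris specks.
#' Debris is recorded in the object table and instance map but excluded
#' from the semantic ground truth. Pairwise object IoU is capped at the
#' spec's `overlap_cap` via bounded rejection sampling.
#'
#' @param spec A [scene_spec()] with `scene_kind = "chamber"`.
#' @return A `rendered_sample`. The number of cells rendered dead is
#'   exactly `round(n_cells * dead_fraction)`.
#' @export
render_chamber_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$scene_kind == "chamber")
  H <- spec$height_px; W <- spec$width_px
  n <- spec$n_objects
  set.seed(obj_seed(spec$seed, 0L))
  img <- scene_background(spec, level = 0.80)
  # grid lines
  if (!is.null(spec$grid)) {
    pitch_px <- spec$grid$grid_pitch_mm * 1000 / spec$microns_per_px
    off <- if (!is.null(spec$placement_rect)) spec$placement_rect[1] %% pitch_px
           else stats::runif(1, 0, pitch_px)
    vx <- round(seq(off, W - 1, by = pitch_px))
    hy <- round(seq(off, H - 1, by = pitch_px))
    for (x in vx) {
      cols <- intersect(seq(x, x + 1) + 1L, seq_len(W))
      img[, cols] <- 0.42 + stats::rnorm(H * length(cols), sd = 0.015)
    }
    for (y in hy) {
      rows <- intersect(seq(y, y + 1) + 1L, seq_len(H))
      img[rows, ] <- 0.42 + stats::rnorm(length(rows) * W, sd = 0.015)
    }
  }

  mix <- spec$object_mix
  counts <- mix_counts(mix$fraction, n)
  row_of <- rep(seq_len(nrow(mix)), counts)
  set.seed(obj_seed(spec$seed, 1999999L))
  row_of <- if (length(row_of)) sample(row_of) else integer()
  cls <- mix$class[row_of]
  cell_idx <- which(cls == "cell")
  n_dead <- round(length(cell_idx) * spec$dead_fraction)
  dead <- rep(FALSE, n)
  if (n_dead > 0) dead[sample(cell_idx)[seq_len(n_dead)]] <- TRUE

  color <- spec$stain != "none"
  inst <- matrix(0L, H, W)
  pix <- vector("list", n)
  shade <- matrix(0, H, W)   # interior intensity, gray channel
  shade_rim <- matrix(NA_real_, H, W)
  objects <- list()
  pr <- spec$placement_rect
  cx_rng <- if (is.null(pr)) c(4, W - 5) else c(pr[1], pr[3] - 1e-9)
  cy_rng <- if (is.null(pr)) c(4, H - 5) else c(pr[2], pr[4] - 1e-9)

  placed <- 0L
  for (i in seq_len(n)) {
    set.seed(obj_seed(spec$seed, i))
    row <- mix[row_of[i], ]
    d_px <- max(2.5, stats::rnorm(1, row$diameter_um, row$diameter_sd_um) /
                  spec$microns_per_px)
    shp <- switch(row$class,
      cell = list(ratio = stats::runif(1, 1.0, 1.3),
                  amps = stats::runif(3, 0, 0.06)),
      bead = list(ratio = 1, amps = rep(0, 3)),
      debris = list(ratio = stats::runif(1, 2.5, 4),
                    amps = stats::runif(3, 0, 0.2)))
    a <- d_px / 2 * sqrt(shp$ratio); b <- d_px / 2 / sqrt(shp$ratio)
    theta <- stats::runif(1, 0, pi)
    phases <- stats::runif(3, 0, 2 * pi)
    ok <- FALSE
    for (try in 1:40) {
      cy <- stats::runif(1, cy_rng[1], cy_rng[2])
      cx <- stats::runif(1, cx_rng[1], cx_rng[2])
      blob <- rasterize_blob(H, W, cy, cx, a, b, theta, shp$amps, phases)
      if (!length(blob$idx_in)) next
      if (spec$overlap_cap == 0) {
        # strict mode: a 1.6 px guard ring around the blob must be free,
        # guaranteeing a gap (connected components then equal objects)
        guard <- rasterize_blob(H, W, cy, cx, a + 1.6, b + 1.6, theta,
                                shp$amps, phases)
        if (!any(inst[guard$idx_in] > 0L)) ok <- TRUE
        if (ok) break else next
      }
      labs <- setdiff(unique(inst[blob$idx_in]), 0L)
      bad <- FALSE
      for (l in labs) {
        inter <- sum(!is.na(match(blob$idx_in, pix[[l]])))
        iou <- inter / (length(blob$idx_in) + length(pix[[l]]) - inter)
        if (iou > spec$overlap_cap) { bad <- TRUE; break }
      }
      if (!bad) { ok <- TRUE; break }
    }
    if (!ok) stop("object placement failed after bounded retries; ",
                  "scene too dense for overlap_cap")
    placed <- placed + 1L
    lab <- placed
    pix[[lab]] <- blob$idx_in
    claim <- blob$idx_in[inst[blob$idx_in] == 0L]
    inst[claim] <- lab
    objects[[lab]] <- data.frame(
      label_id = lab, class = row$class,
      cy = mean((blob$idx_in - 1L) %% H), cx = mean((blob$idx_in - 1L) %/% H),
      diameter_px = 2 * sqrt(length(blob$idx_in) / pi),
      diameter_um = d_px * spec$microns_per_px,
      viability = if (row$class == "cell") {
        if (dead[i]) "dead" else "live"
      } else "n/a",
      stringsAsFactors = FALSE)
    nin <- length(blob$idx_in)
    base_val <- switch(row$class,
      cell = if (dead[i] && !color)
        0.60 + stats::rnorm(nin, sd = 0.05)
      else 0.86 - 0.10 * blob$rad^2 + stats::rnorm(nin, sd = 0.03),
      bead = 0.92 - 0.06 * blob$rad^2 + stats::rnorm(nin, sd = 0.02),
      debris = 0.30 + stats::rnorm(nin, sd = 0.05))
    shade[blob$idx_in] <- base_val
    shade_rim[blob$idx_rim] <- switch(row$class, cell = 0.40,
                                      bead = 0.28, debris = 0.32)
  }
  objects <- if (length(objects)) do.call(rbind, objects)
             else empty_objects()

  if (!color) {
    out <- img
    drawn <- shade != 0
    out[drawn] <- shade[drawn]
    out[!is.na(shade_rim)] <- shade_rim[!is.na(shade_rim)] +
      stats::rnorm(sum(!is.na(shade_rim)), sd = 0.02)
    out <- pmin(pmax(out, 0), 1)
  } else {
    out <- array(rep(img, 3), c(H, W, 3))
    dye <- if (spec$stain == "trypan_blue") c(0.16, 0.20, 0.54)
           else c(0.88, 0.36, 0.48)
    tint_live <- c(1.0, 1.0, 0.96)
    for (l in seq_len(placed)) {
      ob <- objects[l, ]
      idx <- pix[[l]]
      vals <- shade[idx]
      set.seed(obj_seed(spec$seed, 3999999L + l))
      for (ch in 1:3) {
        off <- (ch - 1L) * H * W
        if (ob$class == "cell" && ob$viability == "dead")
          out[idx + off] <- dye[ch] + stats::rnorm(length(idx), sd = 0.03)
        else if (ob$class == "cell")
          out[idx + off] <- vals * tint_live[ch]
        else out[idx + off] <- vals
      }
    }
    rimi <- which(!is.na(shade_rim))
    for (ch in 1:3) {
      off <- (ch - 1L) * H * W
      out[rimi + off] <- shade_rim[rimi]
    }
    out <- pmin(pmax(out, 0), 1)
  }
  if (!is.null(spec$defocus))
    out <- apply_defocus(out, spec$defocus[1], spec$defocus[2])
  sem <- matrix(0L, H, W)
  keep <- objects$label_id[objects$class %in% c("cell", "bead")]
  if (length(keep)) sem[inst %in% keep] <- 1L
  new_rendered_sample(out, sem, inst, objects, spec, roi = spec$placement_rect)
}

#' Gaussian defocus blur with explicit kernel support
#'
#' Convolves the image with a normalised Gaussian kernel of the given odd
#' support; `sigma = 0` returns the input unchanged. Matches the defocus
#' augmentation grid used during training (kernel sizes 5/9/13/15, sigmas
#' 0 to 2).
#'
#' @param image Matrix or H x W x C array in \[0,1\].
#' @param kernel_size Odd kernel support in pixels.
#' @param sigma Gaussian standard deviation in pixels (>= 0).
#' @return Blurred image of the same shape.
#' @export
apply_defocus <- function(image, kernel_size, sigma) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1 || kernel_size %% 2 == 0)
    stop("kernel_size must be an odd integer >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0 || kernel_size == 1) return(image)
  off <- seq(-(kernel_size - 1) / 2, (kernel_size - 1) / 2)
  w <- exp(-off^2 / (2 * sigma^2))
  K <- outer(w, w); K <- K / sum(K)
  blur1 <- function(m) EBImage::filter2(m, K, boundary = "replicate")
  if (length(dim(image)) == 3) {
    out <- image
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- blur1(image[, , ch])
    out
  } else blur1(image)
}
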