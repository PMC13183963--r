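# Confluency: semantic cell/background segmentation of adherent-culture
# images and conversion of masks to percent coverage of an ROI.

#' Convert an RGB image to luma
#' @param image Matrix or H x W x 3 array in \[0,1\].
#' @return Grayscale matrix (Rec. 601 luma for RGB input).
#' @export
as_gray <- function(image) {
  if (length(dim(image)) == 3) {
    if (dim(image)[3] == 1) return(image[, , 1])
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else image
}

roi_to_logical <- function(roi, dm) {
  if (is.null(roi)) return(matrix(TRUE, dm[1], dm[2]))
  if (is.matrix(roi)) {
    stopifnot(identical(dim(roi), dm))
    return(roi > 0)
  }
  stopifnot(length(roi) == 4)  # c(x0, y0, x1, y1), 0-based, half-open
  y0 <- max(roi[2], 0) + 1; y1 <- min(roi[4], dm[1])
  x0 <- max(roi[1], 0) + 1; x1 <- min(roi[3], dm[2])
  if (y0 > y1 || x0 > x1) stop("empty roi")
  m <- matrix(FALSE, dm[1], dm[2])
  m[y0:y1, x0:x1] <- TRUE
  m
}

#' Percent coverage of a binary mask within an ROI
#'
#' `100 * |mask AND roi| / |roi|`, computed exactly; with a full-frame ROI
#' the coverages of a mask and its complement sum to exactly 100.
#'
#' @param mask Binary mask.
#' @param roi `NULL` (full frame), a logical matrix, or `c(x0, y0, x1,
#'   y1)` in 0-based half-open pixel coordinates.
#' @return Confluency percentage in \[0, 100\].
#' @export
confluency_from_mask <- function(mask, roi = NULL) {
  r <- roi_to_logical(roi, dim(mask))
  n <- sum(r)
  if (n == 0) stop("empty roi")
  100 * sum(as.logical(mask) & r) / n
}

resize_im <- function(m, h, w, filter = "bilinear") {
  out <- EBImage::resize(m, w = h, h = w, filter = filter)
  as.matrix(out)
}

# anti-aliased downscale: Gaussian prefilter matched to the scale factor
downscale_aa <- function(m, h, w) {
  scale <- nrow(m) / h
  if (scale > 1.2) {
    sigma <- 0.5 * scale
    k <- 2 * ceiling(2 * sigma) + 1
    m <- apply_defocus(m, k, sigma)
  }
  resize_im(m, h, w)
}

# Letterbox an image to the model's square input: pad to square with the
# median intensity (padding is excluded from the ROI downstream), then
# resize. Downscaling applies a Gaussian anti-aliasing prefilter matched
# to the scale factor, so images entering at different native resolutions
# produce consistent model inputs. Returns the resized image plus the
# geometry needed to map masks back.
letterbox <- function(image, hw) {
  H <- dim(image)[1]; W <- dim(image)[2]
  side <- max(H, W)
  pad_val <- stats::median(image)
  sq <- matrix(pad_val, side, side)
  y0 <- (side - H) %/% 2; x0 <- (side - W) %/% 2
  sq[y0 + seq_len(H), x0 + seq_len(W)] <- image
  list(img = downscale_aa(sq, hw[1], hw[2]), side = side, y0 = y0,
       x0 = x0, H = H, W = W)
}

unletterbox_mask <- function(mask, lb) {
  big <- resize_im(mask, lb$side, lb$side, filter = "none")
  big[lb$y0 + seq_len(lb$H), lb$x0 + seq_len(lb$W)] > 0.5
}

#' Train the confluency network
#'
#' Minimizes binary cross-entropy with Adam (learning rate from the spec)
#' over (image, mask) pairs, with flip/rotation augmentation plus the
#' defocus-blur grid (kernel sizes 5/9/13/15, sigmas 0-2). The checkpoint
#' with the best validation F1 is retained. Fully deterministic given
#' `seed`.
#'
#' @param model A [build_confluency_net()] handle.
#' @param train_set,val_set Lists of `rendered_sample`s or
#'   `list(image, mask)` pairs sized to the model input.
#' @param epochs Training epochs.
#' @param seed RNG seed covering shuffling, augmentation and dropout.
#' @param augment Apply flips/rotations and defocus blur.
#' @param verbose Print per-epoch progress.
#' @return The trained model with a per-epoch `history` data frame
#'   (loss plus validation pixel metrics).
#' @export
train_confluency <- function(model, train_set, val_set = NULL, epochs = 10,
                             seed = 1L, augment = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "confluency_net"))
  if (!length(train_set)) stop("empty dataset")
  pairs <- lapply(train_set, as_pair, hw = model$spec$input_size[1:2])
  vpairs <- lapply(val_set, as_pair, hw = model$spec$input_size[1:2])
  set.seed(seed)
  lr <- model$spec$learning_rate
  hist <- vector("list", epochs)
  best_f1 <- -1; best_params <- NULL
  for (ep in seq_len(epochs)) {
    ord <- sample(length(pairs))
    tot <- 0
    for (q in ord) {
      p <- pairs[[q]]
      x <- p$image; y <- p$mask
      if (augment) {
        a <- augment_pair(x, y)
        x <- a$x; y <- a$y
      }
      x <- canon_input(model, x)
      fwd <- nn_forward(model$net, array(x, c(dim(x), 1L)), train = TRUE)
      z <- fwd$vals[[model$head]][, , 1]
      l <- bce_with_logits(z, y)
      tot <- tot + l$loss
      pg <- nn_backward(model$net, fwd,
                        stats::setNames(list(array(l$grad,
                                                   c(dim(z), 1L))),
                                        model$head))
      model$net <- nn_adam_step(model$net, pg, lr)
    }
    vm <- if (length(vpairs)) eval_confluency(model, vpairs) else NULL
    hist[[ep]] <- data.frame(
      epoch = ep, loss = tot / length(pairs),
      val_accuracy = if (is.null(vm)) NA else vm$accuracy,
      val_precision = if (is.null(vm)) NA else vm$precision,
      val_recall = if (is.null(vm)) NA else vm$recall,
      val_f1 = if (is.null(vm)) NA else vm$f1)
    if (!is.null(vm) && vm$f1 > best_f1) {
      best_f1 <- vm$f1
      best_params <- model$net$params
    }
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val F1 %s", ep,
                      tot / length(pairs),
                      if (is.null(vm)) "-" else sprintf("%.4f", vm$f1)))
  }
  if (!is.null(best_params)) model$net$params <- best_params
  # calibrate the binarization threshold on the validation set: pick the
  # candidate minimizing the mean absolute coverage error
  if (length(vpairs)) {
    probs <- lapply(vpairs, function(p) forward_prob(model, p$image))
    cand <- seq(0.30, 0.70, by = 0.02)
    err <- vapply(cand, function(th)
      mean(vapply(seq_along(vpairs), function(i)
        abs(100 * mean(probs[[i]] >= th) -
              100 * mean(vpairs[[i]]$mask > 0)), 0)), 0)
    model$threshold <- cand[which.min(err)]
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

as_pair <- function(s, hw) {
  if (inherits(s, "rendered_sample"))
    s <- list(image = s$image, mask = s$semantic_mask)
  img <- as_gray(s$image)
  msk <- (s$mask > 0) * 1
  if (!identical(dim(img), as.integer(hw))) {
    img <- downscale_aa(img, hw[1], hw[2])
    msk <- resize_im(msk, hw[1], hw[2], filter = "none")
  }
  list(image = img, mask = msk)
}

augment_pair <- function(x, y) {
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k)) {
    x <- t(x)[, rev(seq_len(nrow(x))), drop = FALSE]  # rotate 90 deg
    y <- t(y)[, rev(seq_len(nrow(y))), drop = FALSE]
  }
  if (stats::runif(1) < 0.5) { x <- x[, rev(seq_len(ncol(x)))]
                               y <- y[, rev(seq_len(ncol(y)))] }
  if (stats::runif(1) < 0.3) {
    ks <- sample(c(5, 9, 13, 15), 1)
    sg <- sample(c(0, 0.5, 1, 1.5, 2), 1)
    x <- apply_defocus(x, ks, sg)
  }
  if (stats::runif(1) < 0.5) {
    # resolution degradation: downscale and back, mask stays sharp
    f <- stats::runif(1, 0.25, 1)
    hs <- max(8, round(nrow(x) * f)); ws <- max(8, round(ncol(x) * f))
    x <- resize_im(resize_im(x, hs, ws), nrow(y), ncol(y))
  }
  list(x = x, y = y)
}

eval_confluency <- function(model, vpairs) {
  tp <- fp <- fn <- tn <- 0
  for (p in vpairs) {
    prob <- forward_prob(model, p$image)
    pm <- pixel_metrics(prob >= model$threshold, p$mask > 0)
    tp <- tp + pm$tp; fp <- fp + pm$fp; fn <- fn + pm$fn; tn <- tn + pm$tn
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(accuracy = (tp + tn) / (tp + fp + fn + tn), precision = prec,
       recall = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

canon_input <- function(model, x) {
  sg <- model$spec$input_smoothing_sigma
  if (is.null(sg) || sg <= 0) return(x)
  apply_defocus(x, 2 * ceiling(2 * sg) + 1, sg)
}

forward_prob <- function(model, image) {
  fwd <- nn_forward(model$net,
                    array(canon_input(model, image),
                          c(dim(image), 1L)), train = FALSE)
  sigmoid(fwd$vals[[model$head]][, , 1])
}

#' Segment an image and compute its confluency
#'
#' Letterbox-resizes the image (aspect-preserving pad-to-square with the
#' median intensity) to the model input, thresholds the sigmoid
#' probability map at the model's threshold, maps the mask back to native
#' resolution with nearest-neighbour resizing, and computes percent
#' coverage inside the ROI. Colour images are converted to luma.
#'
#' @param model A trained `confluency_net`.
#' @param image Image matrix or RGB array, any size.
#' @param roi `NULL`, logical matrix, or `c(x0, y0, x1, y1)` (0-based,
#'   half-open).
#' @return A `confluency_result`: `mask` (native resolution),
#'   `confluency_pct`, `roi`.
#' @export
predict_mask <- function(model, image, roi = NULL) {
  stopifnot(inherits(model, "confluency_net"))
  img <- as_gray(image)
  lb <- letterbox(img, model$spec$input_size[1:2])
  prob <- forward_prob(model, lb$img)
  mask <- unletterbox_mask((prob >= model$threshold) * 1, lb)
  structure(list(mask = mask * 1L,
                 confluency_pct = confluency_from_mask(mask, roi),
                 roi = roi),
            class = "confluency_result")
}

#' @export
print.confluency_result <- function(x, ...) {
  cat(sprintf("<confluency_result> %.2f%% of ROI covered\n",
              x$confluency_pct))
  invisible(x)
}
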