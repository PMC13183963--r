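# Two-pass cell-size estimation: the count network's pooled style vector
# feeds a linear regression on log-diameter; the image is rescaled to the
# predicted diameter, re-segmented, and the median object diameter of the
# final masks is the size estimate.

#' Style vector of an image
#'
#' Globally pooled feature summary of the count network, L2-normalized.
#' The default `"multiscale"` pooling concatenates the per-channel mean
#' and standard deviation of every encoder and bottleneck activation
#' map, which carries the spatial-frequency information that object size
#' regression needs; `"deepest"` is plain global average pooling of the
#' deepest (bottleneck) features — 256 values at the default scale.
#' Identical images give identical vectors; the pooled representation is
#' invariant to whole-stride translations.
#'
#' @param model A trained `count_net`.
#' @param image Image matrix.
#' @param pool `"multiscale"` (default) or `"deepest"`.
#' @return Numeric style vector.
#' @export
style_vector <- function(model, image,
                         pool = c("multiscale", "deepest")) {
  stopifnot(inherits(model, "count_net"))
  pool <- match.arg(pool)
  if (!model$trained) stop("untrained model")
  img <- as_gray(image)
  pd <- pad_to_divisor(img, model$divisor)
  fwd <- nn_forward(model$net, array(pd$img, c(dim(pd$img), 1L)),
                    train = FALSE)
  s <- if (pool == "deepest") {
    apply(fwd$vals[[model$style]], 3, mean)
  } else {
    unlist(lapply(model$enc_relus, function(id) {
      a <- fwd$vals[[id]]
      c(apply(a, 3, mean), apply(a, 3, stats::sd))
    }), use.names = FALSE)
  }
  n <- sqrt(sum(s^2))
  if (n > 0) s / n else s
}

#' Fit the style-to-size linear regression
#'
#' Ordinary least squares of log-diameter on the style vector. When there
#' are fewer training pairs than style dimensions (+1), plain OLS is
#' degenerate, so a ridge penalty is applied unless disabled.
#'
#' @param styles Matrix (n x style_dim) of style vectors.
#' @param diameters_px Positive true diameters in pixels.
#' @param ridge Ridge penalty; `NULL` selects 0 when `n > dim + 1` and
#'   1e-3 otherwise. Set `ridge = 0` to force OLS (errors on degenerate
#'   designs).
#' @return A `size_model` with `weights`, `intercept`, `train_mse` (on
#'   log-diameter).
#' @export
fit_size_model <- function(styles, diameters_px, ridge = NULL) {
  styles <- as.matrix(styles)
  stopifnot(nrow(styles) == length(diameters_px), all(diameters_px > 0))
  y <- log(diameters_px)
  d <- ncol(styles)
  if (is.null(ridge)) ridge <- if (nrow(styles) > d + 1) 0 else 1e-3
  X <- cbind(1, styles)
  if (ridge == 0) {
    if (nrow(styles) < d + 1 || qr(X)$rank < d + 1)
      stop("degenerate design matrix; supply a ridge penalty")
    beta <- qr.solve(X, y)
  } else {
    P <- diag(c(0, rep(ridge, d)))          # intercept unpenalized
    beta <- solve(crossprod(X) + P, crossprod(X, y))
  }
  pred <- as.numeric(X %*% beta)
  structure(list(weights = as.numeric(beta[-1]), intercept = beta[1],
                 train_mse = mean((pred - y)^2), ridge = ridge),
            class = "size_model")
}

#' Predict a diameter from a style vector
#' @param size_model A [fit_size_model()] result.
#' @param style Style vector.
#' @return Predicted diameter in pixels.
#' @export
predict_size <- function(size_model, style) {
  stopifnot(inherits(size_model, "size_model"))
  exp(size_model$intercept + sum(size_model$weights * style))
}

#' Two-pass cell-size estimation
#'
#' Pass 1: the image is rescaled as if its objects had the default
#' diameter, the style vector is computed and the size regression predicts
#' the true diameter. Pass 2: the image is rescaled by the predicted
#' diameter, re-segmented, masks are mapped back to native resolution, and
#' the median object equivalent diameter `2*sqrt(area/pi)` is the final
#' estimate.
#'
#' @param model A trained `count_net`.
#' @param size_model A [fit_size_model()] result.
#' @param image Image matrix.
#' @param default_diameter_px Assumed diameter for pass 1. Defaults to the
#'   diameter the model was trained at (the conventional default of 30 px
#'   corresponds to models trained on 30 px objects).
#' @param params A [seg_params()].
#' @return List with `diameter_px` (NA with `flag = "no-objects"` if pass
#'   2 finds nothing), `style_diameter_px` (the pass-1 regression
#'   prediction), `instances` (native resolution) and `n_objects`.
#' @export
estimate_size <- function(model, size_model, image,
                          default_diameter_px = model$train_diameter_px,
                          params = seg_params()) {
  stopifnot(inherits(model, "count_net"), inherits(size_model, "size_model"))
  img <- as_gray(image)
  f1 <- model$train_diameter_px / default_diameter_px
  img1 <- rescale_image(img, f1)
  d_hat_scaled <- predict_size(size_model, style_vector(model, img1))
  d_hat <- d_hat_scaled / f1                   # native-pixel prediction
  f2 <- model$train_diameter_px / d_hat
  img2 <- rescale_image(img, f2)
  lab2 <- segment_image(model, img2, params)
  lab <- resize_im(lab2, nrow(img), ncol(img), filter = "none")
  lab <- relabel_contiguous(matrix(as.integer(round(lab)), nrow(img)))
  sizes <- tabulate(lab[lab > 0])
  sizes <- sizes[sizes > 0]
  if (!length(sizes))
    return(list(diameter_px = NA_real_, style_diameter_px = d_hat,
                instances = lab, n_objects = 0L, flag = "no-objects"))
  list(diameter_px = stats::median(2 * sqrt(sizes / pi)),
       style_diameter_px = d_hat, instances = lab,
       n_objects = length(sizes), flag = NULL)
}

rescale_image <- function(img, factor) {
  if (abs(factor - 1) < 1e-3) return(img)
  h <- max(8, round(nrow(img) * factor))
  w <- max(8, round(ncol(img) * factor))
  resize_im(img, h, w)
}

#' Median object diameter of an instance map
#' @param instances Integer instance map.
#' @return Median of per-object equivalent diameters `2*sqrt(area/pi)`,
#'   NA when empty.
#' @export
median_object_diameter <- function(instances) {
  sizes <- tabulate(instances[instances > 0])
  sizes <- sizes[sizes > 0]
  if (!length(sizes)) return(NA_real_)
  stats::median(2 * sqrt(sizes / pi))
}
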