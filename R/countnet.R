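# The count model: a U-Net backbone with a 3-channel head (vertical flow,
# horizontal flow, cell-probability logits) and a global style
# representation pooled from the bottleneck, used downstream for size
# regression.

#' Build the cell-count (flow prediction) network
#'
#' U-Net backbone whose head emits three maps: vertical and horizontal
#' flow components (trained against 5x the unit flows, L2 loss) and
#' cell-probability logits (binary cross-entropy). The style vector is the
#' global average pooling of the deepest encoder features — 256 values at
#' the default scale — later used by the size-estimation regression. The
#' network is fully convolutional: any input whose sides are divisible by
#' `2^length(encoder_filters)` works.
#'
#' @param in_channels Input channels (1 for grayscale).
#' @param encoder_filters Encoder filter counts (default 32/64/128/256).
#' @param base_scale Multiplier on all filter counts (rounded up).
#' @param learning_rate Adam learning rate for training.
#' @param seed Seed for weight initialization.
#' @return A `count_net` handle.
#' @export
build_count_net <- function(in_channels = 1,
                            encoder_filters = c(32, 64, 128, 256),
                            base_scale = 1, learning_rate = 1e-3,
                            seed = 1L) {
  enc <- as.integer(ceiling(encoder_filters * base_scale))
  set.seed(seed)
  gb <- graph_builder()
  bk <- unet_backbone(gb, in_channels, enc, enc[length(enc)], rev(enc),
                      dropout_rate = 0)
  head <- gb$conv(bk$out, "head", 1, enc[1], 3)
  structure(list(net = gb$net(), head = head, style = bk$style,
                 enc_relus = bk$enc_relus,
                 in_channels = in_channels, encoder_filters = enc,
                 style_dim = enc[length(enc)],
                 learning_rate = learning_rate,
                 divisor = 2^length(enc),
                 train_diameter_px = NA_real_, trained = FALSE,
                 history = NULL),
            class = "count_net")
}

#' @export
print.count_net <- function(x, ...) {
  cat("<count_net> encoder", paste(x$encoder_filters, collapse = "/"),
      "; style dim", x$style_dim, ";",
      if (x$trained) sprintf("trained (diameter %.1f px)",
                             x$train_diameter_px) else "untrained", "\n")
  invisible(x)
}

count_target <- function(sample) {
  inst <- if (inherits(sample, "rendered_sample"))
    countable_instances(sample) else sample$instances
  ff <- masks_to_flows(inst)
  list(prob = ff$prob, dy = ff$dy, dx = ff$dx)
}

#' Train the count model
#'
#' Derives ground-truth flows from each training instance map (debris
#' excluded), then minimizes BCE on the probability map plus L2 on the
#' flow maps with Adam. Flip augmentation negates the corresponding flow
#' component. Deterministic given `seed`.
#'
#' @param model A [build_count_net()] handle.
#' @param train_set List of `rendered_sample`s (or `list(image,
#'   instances)`).
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param augment Random horizontal/vertical flips.
#' @param flow_weight Weight of the flow L2 loss relative to BCE.
#' @param verbose Print per-epoch loss.
#' @return The trained model; `train_diameter_px` records the median
#'   object diameter of the training set.
#' @export
train_count_model <- function(model, train_set, epochs = 10, seed = 1L,
                              augment = TRUE, flow_weight = 1,
                              verbose = FALSE) {
  stopifnot(inherits(model, "count_net"))
  if (!length(train_set)) stop("empty dataset")
  data <- lapply(train_set, function(s) {
    img <- as_gray(if (inherits(s, "rendered_sample")) s$image else s$image)
    tg <- count_target(s)
    diams <- if (inherits(s, "rendered_sample"))
      s$objects$diameter_px[s$objects$class != "debris"] else {
        sz <- tabulate(s$instances[s$instances > 0])
        2 * sqrt(sz[sz > 0] / pi)
      }
    list(x = img, tg = tg, diams = diams)
  })
  model$train_diameter_px <-
    stats::median(unlist(lapply(data, `[[`, "diams")))
  set.seed(seed)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(data))
    tot <- 0
    for (q in ord) {
      d <- data[[q]]
      x <- d$x; dy <- 5 * d$tg$dy; dx <- 5 * d$tg$dx; pr <- d$tg$prob
      if (augment) {
        if (stats::runif(1) < 0.5) {           # horizontal flip
          rev_c <- rev(seq_len(ncol(x)))
          x <- x[, rev_c]; pr <- pr[, rev_c]
          dy <- dy[, rev_c]; dx <- -dx[, rev_c]
        }
        if (stats::runif(1) < 0.5) {           # vertical flip
          rev_r <- rev(seq_len(nrow(x)))
          x <- x[rev_r, ]; pr <- pr[rev_r, ]
          dy <- -dy[rev_r, ]; dx <- dx[rev_r, ]
        }
      }
      fwd <- nn_forward(model$net, array(x, c(dim(x), 1L)), train = TRUE)
      out <- fwd$vals[[model$head]]
      lf1 <- l2_loss(out[, , 1], dy)
      lf2 <- l2_loss(out[, , 2], dx)
      lp <- bce_with_logits(out[, , 3], pr)
      tot <- tot + flow_weight * (lf1$loss + lf2$loss) + lp$loss
      g <- array(0, dim(out))
      g[, , 1] <- flow_weight * lf1$grad
      g[, , 2] <- flow_weight * lf2$grad
      g[, , 3] <- lp$grad
      pg <- nn_backward(model$net, fwd,
                        stats::setNames(list(g), model$head))
      model$net <- nn_adam_step(model$net, pg, model$learning_rate)
    }
    hist[ep] <- tot / length(data)
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, hist[ep]))
  }
  model$history <- data.frame(epoch = seq_len(epochs), loss = hist)
  model$trained <- TRUE
  model
}

pad_to_divisor <- function(img, div) {
  H <- nrow(img); W <- ncol(img)
  Hp <- ceiling(H / div) * div; Wp <- ceiling(W / div) * div
  if (Hp == H && Wp == W) return(list(img = img, H = H, W = W))
  out <- matrix(stats::median(img), Hp, Wp)
  out[seq_len(H), seq_len(W)] <- img
  list(img = out, H = H, W = W)
}

#' Predict a flow field for an image
#'
#' Runs the count network and returns the cell-probability map and flow
#' components (predictions are rescaled from the 5x training encoding and
#' renormalized so vector norms do not exceed 1).
#'
#' @param model A trained `count_net`.
#' @param image Image matrix (RGB converted to luma).
#' @return A [flow_field()].
#' @export
predict_flow_field <- function(model, image) {
  stopifnot(inherits(model, "count_net"))
  img <- as_gray(image)
  pd <- pad_to_divisor(img, model$divisor)
  fwd <- nn_forward(model$net, array(pd$img, c(dim(pd$img), 1L)),
                    train = FALSE)
  out <- fwd$vals[[model$head]]
  sel_r <- seq_len(pd$H); sel_c <- seq_len(pd$W)
  dy <- out[sel_r, sel_c, 1] / 5
  dx <- out[sel_r, sel_c, 2] / 5
  nrm <- pmax(sqrt(dy^2 + dx^2), 1)
  flow_field(sigmoid(out[sel_r, sel_c, 3]), dy / nrm, dx / nrm)
}

#' Segment an image into cell instances
#'
#' Flow-field prediction followed by [follow_flows()].
#'
#' @param model A trained `count_net`.
#' @param image Image matrix or RGB array.
#' @param params A [seg_params()].
#' @return Integer instance map.
#' @export
segment_image <- function(model, image, params = seg_params()) {
  follow_flows(predict_flow_field(model, image), params)
}
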