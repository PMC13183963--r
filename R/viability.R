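# Per-object live/dead classification of dye-stained chamber images,
# applied strictly after instance segmentation. The classifier is a small
# encoder-decoder that emits a single-channel viability map in [-1, 1]
# (tanh head); objects are called dead when their mean map score exceeds
# the decision threshold (default 0).

#' Build the viability network
#'
#' Four 3x3 convolutions (ReLU), the first two each followed by 2x2 max
#' pooling; three 2x2 transposed convolutions for spatial reconstruction
#' (two with stride 2 restoring the input size, one stride-1); a final 1x1
#' convolution with tanh produces the single-channel viability map, the
#' same size as the input.
#'
#' @param in_channels Input channels (3 for stained RGB scenes).
#' @param conv_filters Four filter counts for the convolutional layers.
#' @param learning_rate Adam learning rate.
#' @param seed Seed for weight initialization.
#' @return A `viability_net` handle.
#' @export
build_viability_net <- function(in_channels = 3,
                                conv_filters = c(16, 32, 64, 64),
                                learning_rate = 1e-3, seed = 1L) {
  stopifnot(length(conv_filters) == 4)
  f <- as.integer(conv_filters)
  set.seed(seed)
  gb <- graph_builder()
  x <- gb$input()
  x <- gb$relu(gb$conv(x, "c1", 3, in_channels, f[1]))
  x <- gb$pool(x)
  x <- gb$relu(gb$conv(x, "c2", 3, f[1], f[2]))
  x <- gb$pool(x)
  x <- gb$relu(gb$conv(x, "c3", 3, f[2], f[3]))
  x <- gb$relu(gb$conv(x, "c4", 3, f[3], f[4]))
  x <- gb$relu(gb$tconv(x, "t1", f[4], f[3]))     # x2 up
  x <- gb$relu(gb$tconv(x, "t2", f[3], f[2]))     # x2 up
  x <- gb$relu(gb$conv(x, "t3", 2, f[2], f[1], pad = c(0, 0, 1, 1)))
  head <- gb$conv(x, "head", 1, f[1], 1)          # tanh applied at use
  net <- gb$net()
  structure(list(net = net, head = head, in_channels = in_channels,
                 conv_filters = f, learning_rate = learning_rate,
                 threshold = 0, n_params = nn_n_params(net),
                 trained = FALSE),
            class = "viability_net")
}

#' @export
print.viability_net <- function(x, ...) {
  cat("<viability_net>", x$in_channels, "-channel input; filters",
      paste(x$conv_filters, collapse = "/"), ";",
      format(x$n_params, big.mark = ","), "parameters;",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

viability_map <- function(model, image) {
  x <- image
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] != model$in_channels) {
    if (model$in_channels == 3 && dim(x)[3] == 1)
      x <- array(rep(x, 3), c(dim(x)[1:2], 3))
    else stop("channel mismatch")
  }
  H <- dim(x)[1]; W <- dim(x)[2]
  Hp <- ceiling(H / 4) * 4; Wp <- ceiling(W / 4) * 4
  if (Hp != H || Wp != W) {
    xp <- array(stats::median(x), c(Hp, Wp, dim(x)[3]))
    xp[seq_len(H), seq_len(W), ] <- x
    x <- xp
  }
  fwd <- nn_forward(model$net, x, train = FALSE)
  tanh(fwd$vals[[model$head]][seq_len(H), seq_len(W), 1])
}

#' Train the viability classifier
#'
#' The target map is +1 on dead-object pixels, -1 on live-object pixels
#' and 0 elsewhere; training minimizes L2 between the tanh output and the
#' target. Scenes must be stained; a dataset with no dead examples
#' triggers a class-imbalance warning.
#'
#' @param model A [build_viability_net()] handle.
#' @param train_set List of `rendered_sample`s from stained chamber
#'   scenes (or `list(image, instances, viability)` with a per-label
#'   `"live"`/`"dead"` character vector named by label id).
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @param verbose Print per-epoch loss.
#' @return The trained model with a `history` data frame.
#' @export
train_viability <- function(model, train_set, epochs = 10, seed = 1L,
                            verbose = FALSE) {
  stopifnot(inherits(model, "viability_net"))
  if (!length(train_set)) stop("empty dataset")
  data <- lapply(train_set, function(s) {
    if (inherits(s, "rendered_sample")) {
      ob <- s$objects[s$objects$class == "cell", ]
      list(image = s$image, instances = s$instance_map,
           viability = stats::setNames(ob$viability,
                                       as.character(ob$label_id)))
    } else s
  })
  n_dead <- sum(vapply(data, function(d) sum(d$viability == "dead"), 0))
  if (n_dead == 0)
    warning("dataset contains no dead examples; class imbalance")
  targets <- lapply(data, function(d) {
    tg <- matrix(0, nrow(d$instances), ncol(d$instances))
    for (l in names(d$viability)) {
      v <- if (d$viability[[l]] == "dead") 1 else -1
      tg[d$instances == as.integer(l)] <- v
    }
    tg
  })
  set.seed(seed)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(data))
    tot <- 0
    for (q in ord) {
      x <- data[[q]]$image
      if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1L))
      fwd <- nn_forward(model$net, x, train = TRUE)
      z <- fwd$vals[[model$head]][, , 1]
      yhat <- tanh(z)
      l <- l2_loss(yhat, targets[[q]])
      tot <- tot + l$loss
      gz <- l$grad * (1 - yhat^2)             # d tanh
      pg <- nn_backward(model$net, fwd,
                        stats::setNames(list(array(gz, c(dim(gz), 1L))),
                                        model$head))
      model$net <- nn_adam_step(model$net, pg, model$learning_rate)
    }
    hist[ep] <- tot / length(data)
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, hist[ep]))
  }
  model$history <- data.frame(epoch = seq_len(epochs), loss = hist)
  model$trained <- TRUE
  model
}

#' Classify segmented objects as live or dead
#'
#' Scores each object as the mean of the viability map over its pixels;
#' the call is `dead` when the score exceeds the model's decision
#' threshold. Calls depend only on object geometry, not label order.
#'
#' @param model A trained `viability_net`.
#' @param image Stained scene (RGB array).
#' @param instances Integer instance map from the count model.
#' @param dye Dye annotation carried through to the calls
#'   (`"trypan_blue"` or `"erythrosin_b"`).
#' @return A `viability_calls` data frame: `label_id`, `score` in
#'   \[-1, 1\], `call`, `dye`. Empty instance map gives zero rows.
#' @export
classify_objects <- function(model, image, instances,
                             dye = c("trypan_blue", "erythrosin_b")) {
  stopifnot(inherits(model, "viability_net"))
  if (!model$trained) stop("untrained model")
  dye <- match.arg(dye)
  labs <- sort(setdiff(unique(as.integer(instances)), 0L))
  if (!length(labs))
    return(structure(data.frame(label_id = integer(), score = numeric(),
                                call = character(), dye = character(),
                                stringsAsFactors = FALSE),
                     class = c("viability_calls", "data.frame")))
  vm <- viability_map(model, image)
  score <- vapply(labs, function(l) mean(vm[instances == l]), 0)
  structure(data.frame(label_id = labs, score = score,
                       call = ifelse(score > model$threshold, "dead",
                                     "live"),
                       dye = dye, stringsAsFactors = FALSE),
            class = c("viability_calls", "data.frame"))
}

#' Percent viable cells from viability calls
#' @param calls A `viability_calls` data frame (>= 1 call), or any data
#'   frame with a `call` column.
#' @return `100 * live / (live + dead)`.
#' @export
viability_percent <- function(calls) {
  if (!nrow(calls)) stop("no viability calls")
  100 * sum(calls$call == "live") / nrow(calls)
}
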