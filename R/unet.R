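# Graph assembly for the U-Net family. A small mutable builder wraps the
# nn_* primitives; node ids are returned so heads, skips and the style
# (bottleneck) node can be referenced later.

graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$net <- nn_new()
  add <- function(op, inputs = integer(), param = NULL, pad = NULL,
                  rate = NULL) {
    env$net <- nn_add_node(env$net, op, inputs, param, pad, rate)
    length(env$net$nodes)
  }
  list(
    input = function() add("input"),
    conv = function(src, name, k, cin, cout, pad = same_pad(k)) {
      env$net <- nn_add_param(env$net, name, k, k, cin, cout)
      add("conv", src, param = name, pad = pad)
    },
    tconv = function(src, name, cin, cout) {
      env$net <- nn_add_param(env$net, name, 2, 2, cin, cout)
      add("tconv", src, param = name)
    },
    relu = function(src) add("relu", src),
    pool = function(src) add("pool", src),
    up = function(src) add("up", src),
    concat = function(a, b) add("concat", c(a, b)),
    dropout = function(src, rate) add("dropout", src, rate = rate),
    net = function() env$net
  )
}

# Shared encoder-decoder backbone: per level two 3x3 convs (ReLU) then 2x2
# max pooling; dropout after the deepest encoder block and in the
# bottleneck; decoder levels upsample 2x, apply a 2x2 conv, concatenate
# the skip and run two 3x3 convs. Returns builder, last decoder node and
# the bottleneck (style) node.
unet_backbone <- function(gb, in_ch, enc, bottleneck, dec, dropout_rate) {
  x <- gb$input()
  cin <- in_ch
  skips <- integer(length(enc))
  enc_relus <- integer()
  for (i in seq_along(enc)) {
    f <- enc[i]
    x <- gb$relu(gb$conv(x, sprintf("enc%da", i), 3, cin, f))
    enc_relus <- c(enc_relus, x)
    x <- gb$relu(gb$conv(x, sprintf("enc%db", i), 3, f, f))
    enc_relus <- c(enc_relus, x)
    skips[i] <- x
    x <- gb$pool(x)
    cin <- f
  }
  if (dropout_rate > 0) x <- gb$dropout(x, dropout_rate)
  x <- gb$relu(gb$conv(x, "bna", 3, cin, bottleneck))
  enc_relus <- c(enc_relus, x)
  x <- gb$relu(gb$conv(x, "bnb", 3, bottleneck, bottleneck))
  enc_relus <- c(enc_relus, x)
  style <- x
  if (dropout_rate > 0) x <- gb$dropout(x, dropout_rate)
  cin <- bottleneck
  for (i in rev(seq_along(enc))) {
    f <- dec[length(enc) - i + 1]
    x <- gb$up(x)
    x <- gb$relu(gb$conv(x, sprintf("upc%d", i), 2, cin, f,
                         pad = c(0, 0, 1, 1)))
    x <- gb$concat(x, skips[i])
    x <- gb$relu(gb$conv(x, sprintf("dec%da", i), 3, f + enc[i], f))
    x <- gb$relu(gb$conv(x, sprintf("dec%db", i), 3, f, f))
    cin <- f
  }
  list(gb = gb, out = x, style = style, enc_relus = enc_relus)
}

#' U-Net architecture specification for the confluency model
#'
#' Defaults follow the full-scale architecture: 1024 x 1024 x 1 input,
#' encoder blocks of two 3x3 convolutions with 64/128/256/512 filters each
#' followed by 2x2 max pooling, a 1024-filter bottleneck, 0.5 dropout
#' after the fourth block and in the bottleneck, a symmetric decoder
#' (2x upsampling, 2x2 convolution with 512/256/128/64 filters, skip
#' concatenation, two 3x3 convolutions), and a final 3x3 convolution with
#' two filters (ReLU) followed by a 1x1 sigmoid convolution. `base_scale`
#' scales every filter count (rounded up) for desk-scale training.
#'
#' @param input_size `c(H, W, channels)`; H and W must be divisible by
#'   `2 ^ length(encoder_filters)`.
#' @param encoder_filters,bottleneck_filters,decoder_filters Filter counts.
#' @param dropout_rate Dropout after the deepest block and bottleneck.
#' @param learning_rate Adam learning rate.
#' @param base_scale Multiplier applied to all filter counts (ceiling).
#' @param input_smoothing_sigma Gaussian sigma (in model-input pixels) of
#'   a canonical smoothing applied identically during training and
#'   prediction. A small value (~1) trades a little sharpness for
#'   markedly more consistent confluency estimates across input
#'   resolutions; 0 disables it.
#' @return A `unet_spec` object.
#' @export
unet_spec <- function(input_size = c(1024, 1024, 1),
                      encoder_filters = c(64, 128, 256, 512),
                      bottleneck_filters = 1024,
                      decoder_filters = rev(encoder_filters),
                      dropout_rate = 0.5, learning_rate = 1e-4,
                      base_scale = 1, input_smoothing_sigma = 0) {
  stopifnot(length(input_size) == 3,
            length(encoder_filters) == length(decoder_filters),
            base_scale > 0, dropout_rate >= 0, dropout_rate < 1)
  div <- 2^length(encoder_filters)
  if (input_size[1] %% div != 0 || input_size[2] %% div != 0)
    stop("input H and W must be divisible by ", div)
  structure(list(
    input_size = as.integer(input_size),
    encoder_filters = as.integer(ceiling(encoder_filters * base_scale)),
    bottleneck_filters = as.integer(ceiling(bottleneck_filters *
                                              base_scale)),
    decoder_filters = as.integer(ceiling(decoder_filters * base_scale)),
    dropout_rate = dropout_rate, final_activation = "sigmoid",
    learning_rate = learning_rate, loss = "binary_cross_entropy",
    base_scale = base_scale,
    input_smoothing_sigma = input_smoothing_sigma), class = "unet_spec")
}

#' Build the confluency segmentation network
#'
#' Instantiates the U-Net described by a [unet_spec()] with He-normal
#' initial weights. The returned handle carries the graph, the probability
#' threshold used to binarize the sigmoid output (default 0.5,
#' configurable) and the parameter count.
#'
#' @param spec A [unet_spec()].
#' @param seed Seed for weight initialization.
#' @return A `confluency_net` handle.
#' @export
build_confluency_net <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  set.seed(seed)
  gb <- graph_builder()
  bk <- unet_backbone(gb, spec$input_size[3], spec$encoder_filters,
                      spec$bottleneck_filters, spec$decoder_filters,
                      spec$dropout_rate)
  pen <- gb$relu(gb$conv(bk$out, "head_pre", 3,
                         spec$decoder_filters[length(spec$decoder_filters)],
                         2))
  head <- gb$conv(pen, "head", 1, 2, 1)
  structure(list(net = gb$net(), spec = spec, head = head,
                 style = bk$style, threshold = 0.5,
                 n_params = nn_n_params(gb$net()),
                 history = NULL, trained = FALSE),
            class = "confluency_net")
}

#' @export
print.confluency_net <- function(x, ...) {
  cat("<confluency_net>", paste(x$spec$input_size, collapse = "x"),
      "input; encoder", paste(x$spec$encoder_filters, collapse = "/"),
      "; bottleneck", x$spec$bottleneck_filters, ";",
      format(x$n_params, big.mark = ","), "parameters;",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}
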