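# Compact CNN engine: static computation graphs over (H, W, C) arrays with
# manual reverse-mode differentiation and an Adam optimizer. Heavy kernels
# (convolution, pooling, upsampling) live in src/nn_ops.cpp. All randomness
# (weight init, dropout, shuffling) goes through R's RNG so that training is
# reproducible under set.seed().

as_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  storage.mode(x) <- "double"
  x
}

nn_new <- function() {
  list(params = list(), nodes = list(), opt = list(t = 0L))
}

nn_add_param <- function(net, name, kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  W <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  net$params[[name]] <- list(W = W, b = rep(0, cout),
                             kh = kh, kw = kw, cin = cin, cout = cout)
  net
}

# pad = c(top, left, bottom, right); "same" padding for odd kernels,
# bottom/right-heavy for even kernels so output size equals input size.
same_pad <- function(k) {
  tot <- k - 1L
  a <- tot %/% 2L
  c(a, a, tot - a, tot - a)
}

nn_add_node <- function(net, op, inputs = integer(), param = NULL,
                        pad = NULL, rate = NULL) {
  net$nodes[[length(net$nodes) + 1L]] <-
    list(op = op, inputs = as.integer(inputs), param = param,
         pad = pad, rate = rate)
  net
}

nn_forward <- function(net, x, train = FALSE) {
  n <- length(net$nodes)
  vals <- vector("list", n)
  caches <- vector("list", n)
  for (id in seq_len(n)) {
    nd <- net$nodes[[id]]
    ins <- lapply(nd$inputs, function(i) vals[[i]])
    vals[[id]] <- switch(nd$op,
      input = as_tensor(x),
      conv = {
        p <- net$params[[nd$param]]
        cq_conv_fwd(ins[[1]], p$W, p$b, p$kh, p$kw,
                    nd$pad[1], nd$pad[2], nd$pad[3], nd$pad[4])
      },
      tconv = {
        p <- net$params[[nd$param]]
        cq_tconv_fwd(ins[[1]], p$W, p$b)
      },
      relu = pmax(ins[[1]], 0),
      pool = {
        r <- cq_pool_fwd(ins[[1]])
        caches[[id]] <- list(idx = r$idx, H = dim(ins[[1]])[1],
                             W = dim(ins[[1]])[2])
        r$y
      },
      up = cq_up_fwd(ins[[1]]),
      concat = {
        a <- ins[[1]]; b <- ins[[2]]
        caches[[id]] <- dim(a)[3]
        y <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
        y[, , seq_len(dim(a)[3])] <- a
        y[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
        y
      },
      dropout = {
        if (train && nd$rate > 0) {
          m <- array(
            (stats::runif(length(ins[[1]])) >= nd$rate) / (1 - nd$rate),
            dim(ins[[1]]))
          caches[[id]] <- m
          ins[[1]] * m
        } else ins[[1]]
      },
      stop("unknown op: ", nd$op)
    )
  }
  list(vals = vals, caches = caches)
}

# grads_at: named list mapping node index (as character) to the gradient of
# the loss w.r.t. that node's output. Returns per-parameter gradients.
nn_backward <- function(net, fwd, grads_at) {
  n <- length(net$nodes)
  g <- vector("list", n)
  for (k in names(grads_at)) g[[as.integer(k)]] <- grads_at[[k]]
  pg <- list()
  for (id in rev(seq_len(n))) {
    if (is.null(g[[id]])) next
    nd <- net$nodes[[id]]
    gy <- g[[id]]
    gins <- switch(nd$op,
      input = list(),
      conv = {
        p <- net$params[[nd$param]]
        r <- cq_conv_bwd(fwd$vals[[nd$inputs[1]]], p$W, gy, p$kh, p$kw,
                         nd$pad[1], nd$pad[2], nd$pad[3], nd$pad[4])
        pg <- acc_pgrad(pg, nd$param, r$gW, r$gb)
        list(r$gx)
      },
      tconv = {
        p <- net$params[[nd$param]]
        r <- cq_tconv_bwd(fwd$vals[[nd$inputs[1]]], p$W, gy)
        pg <- acc_pgrad(pg, nd$param, r$gW, r$gb)
        list(r$gx)
      },
      relu = list(gy * (fwd$vals[[id]] > 0)),
      pool = {
        cc <- fwd$caches[[id]]
        list(cq_pool_bwd(gy, cc$idx, cc$H, cc$W))
      },
      up = list(cq_up_bwd(gy)),
      concat = {
        ca <- fwd$caches[[id]]
        list(gy[, , seq_len(ca), drop = FALSE],
             gy[, , -seq_len(ca), drop = FALSE])
      },
      dropout = {
        m <- fwd$caches[[id]]
        if (is.null(m)) list(gy) else list(gy * m)
      }
    )
    for (k in seq_along(gins)) {
      src <- nd$inputs[k]
      g[[src]] <- if (is.null(g[[src]])) gins[[k]] else g[[src]] + gins[[k]]
    }
    g[id] <- list(NULL)  # free without shrinking the list
  }
  pg
}

acc_pgrad <- function(pg, name, gW, gb) {
  if (is.null(pg[[name]])) pg[[name]] <- list(gW = gW, gb = gb)
  else {
    pg[[name]]$gW <- pg[[name]]$gW + gW
    pg[[name]]$gb <- pg[[name]]$gb + gb
  }
  pg
}

nn_adam_step <- function(net, pg, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  net$opt$t <- net$opt$t + 1L
  t <- net$opt$t
  for (name in names(pg)) {
    p <- net$params[[name]]
    st <- net$opt[[name]]
    if (is.null(st))
      st <- list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
    st$mW <- beta1 * st$mW + (1 - beta1) * pg[[name]]$gW
    st$vW <- beta2 * st$vW + (1 - beta2) * pg[[name]]$gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * pg[[name]]$gb
    st$vb <- beta2 * st$vb + (1 - beta2) * pg[[name]]$gb^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    p$W <- p$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    p$b <- p$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    net$params[[name]] <- p
    net$opt[[name]] <- st
  }
  net
}

nn_n_params <- function(net) {
  sum(vapply(net$params, function(p) length(p$W) + length(p$b), 0))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable binary cross-entropy on logits; returns the mean loss
# and its gradient w.r.t. the logits.
bce_with_logits <- function(z, y) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  list(loss = loss, grad = (sigmoid(z) - y) / n)
}

l2_loss <- function(pred, target) {
  n <- length(pred)
  d <- pred - target
  list(loss = sum(d^2) / n, grad = 2 * d / n)
}
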