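# Metric implementations against independent brute-force oracles.

brute_pixel_metrics <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    p <- pred[i] > 0; t <- truth[i] > 0
    if (p && t) tp <- tp + 1 else if (p) fp <- fp + 1
    else if (t) fn <- fn + 1 else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

test_that("pixel metrics equal a per-pixel confusion tally on random masks", {
  set.seed(11)
  for (rep in 1:100) {
    pred <- matrix(stats::runif(64) > stats::runif(1, 0.2, 0.8), 8, 8)
    truth <- matrix(stats::runif(64) > stats::runif(1, 0.2, 0.8), 8, 8)
    got <- pixel_metrics(pred, truth)
    want <- brute_pixel_metrics(pred, truth)
    expect_equal(got[c("tp", "fp", "fn", "tn")], want,
                 ignore_attr = TRUE)
    expect_equal(got$accuracy, (want$tp + want$tn) / 64, tolerance = 1e-12)
    if (want$tp + want$fp > 0)
      expect_equal(got$precision, want$tp / (want$tp + want$fp),
                   tolerance = 1e-12)
    if (got$precision + got$recall > 0)
      expect_equal(got$f1, 2 * got$precision * got$recall /
                     (got$precision + got$recall), tolerance = 1e-12)
  }
})

test_that("pixel metrics handle perfect, empty and mismatched masks", {
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  pm <- pixel_metrics(m, m)
  expect_equal(c(pm$accuracy, pm$precision, pm$recall, pm$f1),
               rep(1, 4))
  half <- matrix(c(1, 1, 0, 0), 2, 2)
  pm0 <- pixel_metrics(matrix(0, 2, 2), half)
  expect_equal(pm0$recall, 0)
  expect_equal(pm0$accuracy, 0.5)
  expect_true("precision" %in% attr(pm0, "undefined"))
  expect_error(pixel_metrics(matrix(0, 2, 2), matrix(0, 3, 2)),
               "shape")
})

test_that("adding foreground pixels to the prediction never lowers recall", {
  set.seed(12)
  for (rep in 1:25) {
    truth <- matrix(stats::runif(64) > 0.5, 8, 8)
    pred <- matrix(stats::runif(64) > 0.7, 8, 8)
    r0 <- pixel_metrics(pred, truth)$recall
    off <- which(!pred)
    pred[sample(off, 1)] <- TRUE
    expect_gte(pixel_metrics(pred, truth)$recall, r0)
  }
})

test_that("instance matching equals the exhaustive-assignment oracle", {
  set.seed(13)
  for (rep in 1:100) {
    n_t <- sample(1:3, 1)
    truth <- disc_map(16, 16,
                      cbind(stats::runif(n_t, 3, 12),
                            stats::runif(n_t, 3, 12)), 3)
    # perturb: shift labels, occasionally split one object
    pred <- truth
    if (stats::runif(1) < 0.5 && max(truth) >= 1) {
      px <- which(truth == 1)
      pred[px[seq_len(length(px) %/% 2)]] <- max(truth) + 1L
    }
    sh <- sample(0:2, 1)
    if (sh > 0) pred <- rbind(matrix(0L, sh, 16), pred)[1:16, ]
    got <- instance_metrics(pred, truth, 0.5)
    want <- brute_instance_metrics(pred, truth, 0.5)
    expect_equal(got$tp, want$tp)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
  }
})

test_that("instance metrics boundary cases", {
  truth <- disc_map(16, 16, cbind(c(5, 11), c(5, 11)), 3)
  expect_equal(instance_metrics(truth, truth)$f1, 1)
  empty <- matrix(0L, 16, 16)
  expect_equal(instance_metrics(empty, truth)$recall, 0)
  expect_error(instance_metrics(truth, matrix(0L, 8, 8)), "shape")
})

test_that("error metrics match hand computation and the rmse >= mae bound", {
  em <- error_metrics(c(0, 4), c(0, 0))
  expect_equal(em$mae, 2)
  expect_equal(em$mse, 8)
  expect_equal(em$rmse, sqrt(8))
  em1 <- error_metrics(3, 1)
  expect_equal(em1$mae, 2)
  expect_equal(em1$rmse, 2)
  expect_equal(error_metrics(1:4, 1:4), list(mae = 0, mse = 0, rmse = 0))
  set.seed(14)
  for (rep in 1:100) {
    a <- stats::rnorm(7); b <- stats::rnorm(7)
    em <- error_metrics(a, b)
    expect_equal(em$mae, mean(abs(a - b)), tolerance = 1e-12)
    expect_equal(em$rmse, sqrt(em$mse), tolerance = 1e-12)
    expect_gte(em$rmse + 1e-12, em$mae)
  }
  expect_gte(error_metrics(c(1, 3), c(0, 0))$rmse,
             error_metrics(c(1, 3), c(0, 0))$mae)
  em_eq <- error_metrics(c(2, -2), c(0, 0))   # equal |errors|
  expect_equal(em_eq$rmse, em_eq$mae)
})

test_that("linear_fit matches the normal equations", {
  lf <- linear_fit(1:5, 2 * (1:5) + 1)
  expect_equal(lf$slope, 2, tolerance = 1e-12)
  expect_equal(lf$intercept, 1, tolerance = 1e-12)
  expect_equal(lf$r_squared, 1, tolerance = 1e-12)
  expect_equal(linear_fit(1:5, rep(3, 5))$r_squared, 0)
  expect_error(linear_fit(rep(2, 5), 1:5), "constant")
  set.seed(15)
  for (rep in 1:100) {
    x <- stats::rnorm(5); y <- stats::rnorm(5)
    lf <- linear_fit(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(lf$intercept, beta[1], tolerance = 1e-10)
    expect_equal(lf$slope, beta[2], tolerance = 1e-10)
    res <- y - X %*% beta
    expect_equal(lf$r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
})

test_that("confluency of a mask and its complement sum to exactly 100", {
  set.seed(16)
  for (rep in 1:20) {
    m <- matrix(stats::runif(100) > stats::runif(1), 10, 10)
    expect_identical(confluency_from_mask(m) + confluency_from_mask(!m),
                     100)
  }
  m <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(confluency_from_mask(m, c(0, 0, 1, 1)), 100)
  expect_error(confluency_from_mask(m, c(5, 5, 6, 6)), "roi")
})
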