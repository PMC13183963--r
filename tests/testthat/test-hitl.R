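# Human-in-the-loop scaffold: split integrity, correction ingestion,
# stop decisions.

mock_pair <- function(seed, size = 12) {
  set.seed(seed)
  img <- matrix(stats::runif(size^2), size, size)
  list(image = img, mask = (img > 0.5) * 1)
}

# "training" fits a single intensity threshold; evaluation reports pixel
# metrics of the thresholded prediction on the frozen test set
mock_train <- function(pool, seed) {
  vals <- unlist(lapply(pool, function(p) p$image[p$mask == 1]))
  bg <- unlist(lapply(pool, function(p) p$image[p$mask == 0]))
  list(threshold = (min(vals) + max(bg)) / 2)
}
mock_eval <- function(model, test) {
  agg <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (p in test) {
    pm <- pixel_metrics(p$image > model$threshold, p$mask)
    agg <- agg + c(pm$tp, pm$fp, pm$fn, pm$tn)
  }
  prec <- agg[["tp"]] / max(agg[["tp"]] + agg[["fp"]], 1)
  rec <- agg[["tp"]] / max(agg[["tp"]] + agg[["fn"]], 1)
  list(accuracy = (agg[["tp"]] + agg[["tn"]]) / sum(agg),
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

test_that("test-set leakage is refused at construction and ingestion", {
  train <- list(a = mock_pair(1), b = mock_pair(2))
  val <- list(v = mock_pair(3))
  test <- list(t1 = mock_pair(4), t2 = mock_pair(5))
  expect_error(hitl_state(c(train, list(x = mock_pair(4))), val, test,
                          mock_train, mock_eval), "leak")
  st <- hitl_state(train, val, test, mock_train, mock_eval)
  expect_error(run_cycle(st, list(new = mock_pair(5))), "held-out")
  bad <- mock_pair(6); bad$mask <- bad$mask[1:6, ]
  expect_error(run_cycle(st, list(new = bad)), "mismatch")
})

test_that("cycles retrain, report, audit, and metrics persist with no input", {
  st <- hitl_state(list(a = mock_pair(1), b = mock_pair(2)),
                   list(v = mock_pair(3)),
                   list(t1 = mock_pair(4), t2 = mock_pair(5)),
                   mock_train, mock_eval)
  st <- run_cycle(st, list(c1 = mock_pair(10)))
  expect_equal(st$cycle, 1L)
  expect_equal(st$history[[1]]$n_train, 3)
  m1 <- st$history[[1]]$metrics
  # a cycle with no new pairs leaves metrics unchanged
  st <- run_cycle(st)
  expect_equal(st$history[[2]]$metrics, m1, tolerance = 1e-12)
  expect_equal(st$history[[2]]$cycle_index,
               st$history[[1]]$cycle_index + 1L)
  # replacing an existing id is audited
  st <- run_cycle(st, list(a = mock_pair(20)))
  acts <- vapply(st$audit, `[[`, "", "action")
  expect_true("replaced" %in% acts && "added" %in% acts)
})

test_that("corrected annotations improve metrics across cycles", {
  set.seed(71)
  clean <- lapply(1:6, function(i) mock_pair(100 + i))
  noisy <- lapply(clean[1:4], function(p) {
    flip <- sample(length(p$mask), 30)
    p$mask[flip] <- 1 - p$mask[flip]
    p
  })
  names(noisy) <- paste0("n", 1:4)
  st <- hitl_state(noisy, clean[5], clean[6], mock_train, mock_eval)
  st <- run_cycle(st)
  f <- st$history[[1]]$metrics$f1
  for (k in 1:3) {       # correct one annotation per cycle
    fix <- clean[[k]]
    st <- run_cycle(st, stats::setNames(list(fix), paste0("n", k)))
  }
  f1s <- vapply(st$history, function(h) h$metrics$f1, 0)
  expect_true(all(diff(f1s) >= -1e-9))
})

test_that("stop decisions follow thresholds, including the 0.94/0.91 case", {
  hist <- list(list(metrics = list(accuracy = 1, f1 = 1)))
  expect_true(check_stop(hist))
  hist2 <- list(list(metrics = list(accuracy = 0.95, f1 = 0.89)))
  expect_false(check_stop(hist2))
  # a trajectory ending at accuracy 0.94 / F1 0.91 passes 0.90 thresholds
  traj <- list(list(metrics = list(accuracy = 0.71, f1 = 0.62)),
               list(metrics = list(accuracy = 0.88, f1 = 0.85)),
               list(metrics = list(accuracy = 0.94, f1 = 0.91)))
  expect_true(check_stop(traj, c(accuracy = 0.90, f1 = 0.90)))
  expect_false(check_stop(traj[1:2], c(accuracy = 0.90, f1 = 0.90)))
  expect_error(check_stop(traj, c(recall = 0.9)), "missing")
})
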