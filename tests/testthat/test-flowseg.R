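# Flow construction, flow following, counting rules and concentration.

test_that("empty instance map gives zero flows and zero instances", {
  empty <- matrix(0L, 32, 32)
  ff <- masks_to_flows(empty)
  expect_true(all(ff$prob == 0) && all(ff$dy == 0) && all(ff$dx == 0))
  expect_equal(max(follow_flows(ff)), 0)
})

test_that("disc flows point toward the centre for >=95% of interior pixels", {
  m <- disc_map(33, 33, cbind(16, 16), 10)
  ff <- masks_to_flows(m)
  idx <- which(m == 1L)
  y <- (idx - 1) %% 33; x <- (idx - 1) %/% 33
  dotp <- ff$dy[idx] * (16 - y) + ff$dx[idx] * (16 - x)
  interior <- (y - 16)^2 + (x - 16)^2 > 1   # skip the source pixel itself
  expect_gte(mean(dotp[interior] > 0), 0.95)
  expect_lte(max(sqrt(ff$dy^2 + ff$dx^2)), 1 + 1e-6)
})

test_that("touching discs get opposing flows and resolve to two instances", {
  m <- disc_map(40, 60, cbind(c(20, 20), c(22, 37)), 8)
  expect_equal(max(EBImage::bwlabel(m > 0)), 1)  # genuinely touching
  ff <- masks_to_flows(m)
  # just left / right of the contact line, the x-flows point apart
  ff_left <- ff$dx[21, 27]; ff_right <- ff$dx[21, 32]
  expect_true(ff_left < 0 && ff_right > 0)
  lab <- follow_flows(ff)
  expect_equal(max(lab), 2)
  im <- instance_metrics(lab, m, 0.5)
  expect_equal(im$tp, 2)
})

test_that("probabilities below threshold produce no instances", {
  ff <- flow_field(matrix(0.4, 16, 16), matrix(0, 16, 16),
                   matrix(0, 16, 16))
  expect_equal(max(follow_flows(ff, seg_params(prob_threshold = 0.5))), 0)
})

test_that("flow round trip on generated chamber scenes preserves objects", {
  set.seed(41)
  total_err <- 0; total_n <- 0; ious <- c()
  for (i in 1:10) {
    s <- gen_chamber_scene(500 + i, n = sample(4:20, 1),
                           mix = default_object_mix(16, 2))
    ff <- masks_to_flows(s$instance_map)
    lab <- follow_flows(ff)
    im <- instance_metrics(lab, s$instance_map, 0.5)
    total_err <- total_err + abs(im$n_pred - im$n_truth)
    total_n <- total_n + im$n_truth
    ious <- c(ious, im$mean_matched_iou)
  }
  expect_lte(total_err / total_n, 0.02)
  expect_gte(mean(ious), 0.9)
})

test_that("counting applies the top/left-include bottom/right-exclude rule", {
  expect_equal(count_cells(matrix(0L, 20, 20)), 0)
  inside <- disc_map(40, 40, cbind(rep(c(10, 20, 30), c(3, 3, 4))[1:10],
                                   rep(c(10, 20, 30, 35), 3)[1:10] - 2), 2)
  expect_equal(count_cells(inside), max(inside))
  # object centred exactly on the right roi edge -> excluded
  m <- disc_map(30, 30, cbind(15, 20), 3)
  expect_equal(count_cells(m, roi = c(5, 5, 20, 25)), 0)
  # crossing the left edge -> counted
  m2 <- disc_map(30, 30, cbind(15, 5), 3)
  expect_equal(count_cells(m2, roi = c(5, 5, 20, 25)), 1)
  # crossing the top edge -> counted; bottom edge -> excluded
  m3 <- disc_map(30, 30, cbind(5, 12), 3)
  expect_equal(count_cells(m3, roi = c(5, 5, 25, 25)), 1)
  m4 <- disc_map(30, 30, cbind(25, 12), 3)
  expect_equal(count_cells(m4, roi = c(5, 5, 25, 25)), 0)
  expect_error(count_cells(m, roi = c(40, 40, 50, 50)), "roi")
})

test_that("counting is invariant to joint translation of scene and roi", {
  set.seed(42)
  m <- disc_map(60, 60, cbind(stats::runif(6, 10, 30),
                              stats::runif(6, 10, 30)), 3)
  roi <- c(5, 5, 35, 35)
  n0 <- count_cells(m, roi)
  sh <- 12
  m2 <- matrix(0L, 60, 60)
  m2[seq_len(48) + sh, seq_len(48) + sh] <- m[1:48, 1:48]
  expect_equal(count_cells(m2, roi + sh), n0)
})

test_that("concentration implements the hemocytometer formula exactly", {
  g2 <- chamber_geometry(1, 0.1, dilution_factor = 2)
  expect_equal(concentration(c(25, 25, 25, 25), g2)$concentration, 5e5)
  g1 <- chamber_geometry(1, 0.1, dilution_factor = 1)
  expect_equal(concentration(100, g1)$concentration, 1e6)
  expect_equal(concentration(c(0, 0, 0, 0), g1)$concentration, 0)
  expect_equal(square_volume_ml(g1), 1e-4)
})

test_that("dilution series exposes Poisson means and monotone counts", {
  ch <- chamber_geometry(1, 0.1)
  # conc 2.5e5 in a 1 mm^2 x 0.1 mm square -> mean 25 objects
  sim_small <- simulate_dilution_series(2.5e5, 1, ch, fields_per_sample = 1,
                                        microns_per_px = 10, seed = 5)
  expect_equal(sim_small$samples[[1]]$lambda, 25)
  ch2 <- chamber_geometry(0.2, 0.1)
  sim0 <- simulate_dilution_series(0, c(1, 2), ch2, fields_per_sample = 2,
                                   microns_per_px = 4, seed = 6)
  expect_true(all(sim0$summary$mean_true_count == 0))
  sim <- simulate_dilution_series(5e6, c(1, 2, 4, 8, 16, 32, 64, 128), ch2,
                                  fields_per_sample = 2,
                                  microns_per_px = 4, seed = 7)
  expect_true(all(diff(sim$summary$lambda) < 0))
  expect_true(all(diff(sim$summary$expected_conc) < 0))
})
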