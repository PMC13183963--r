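# Architecture contracts: filter schedules, scaling, shape preservation,
# parameter counts, determinism of training.

test_that("confluency U-Net follows the published filter schedule", {
  sp <- unet_spec()
  expect_equal(sp$encoder_filters, c(64L, 128L, 256L, 512L))
  expect_equal(sp$bottleneck_filters, 1024L)
  expect_equal(sp$decoder_filters, c(512L, 256L, 128L, 64L))
  expect_equal(sp$dropout_rate, 0.5)
  expect_equal(sp$learning_rate, 1e-4)
  expect_identical(sp$loss, "binary_cross_entropy")
  sp4 <- unet_spec(base_scale = 0.25)
  expect_equal(sp4$encoder_filters, c(16L, 32L, 64L, 128L))
  expect_equal(sp4$bottleneck_filters, 256L)
  expect_error(unet_spec(input_size = c(100, 100, 1)), "divisible")
})

test_that("built confluency net reports parameters and segments an image", {
  sp <- unet_spec(input_size = c(32, 32, 1), base_scale = 1 / 32,
                  dropout_rate = 0)
  m <- build_confluency_net(sp, seed = 3)
  expect_gt(m$n_params, 0)
  img <- matrix(stats::runif(48 * 40), 48, 40)  # non-square, any size
  r <- predict_mask(m, img)
  expect_s3_class(r, "confluency_result")
  expect_identical(dim(r$mask), dim(img))
  expect_gte(r$confluency_pct, 0); expect_lte(r$confluency_pct, 100)
  # all-background probability: an untrained-but-biased map thresholds low
  expect_equal(confluency_from_mask(matrix(0, 8, 8)), 0)
})

test_that("viability net preserves spatial size and obeys closed-form count", {
  f <- c(4L, 8L, 16L, 16L)
  m <- build_viability_net(in_channels = 3, conv_filters = f, seed = 2)
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  vm <- cellquant:::viability_map(m, img)
  expect_identical(dim(vm), c(64L, 64L))
  expect_true(all(vm >= -1 & vm <= 1))
  # parameter count: four 3x3 convs, two 2x2 tconvs, one 2x2 conv, 1x1 head
  want <- (9 * 3 * f[1] + f[1]) + (9 * f[1] * f[2] + f[2]) +
    (9 * f[2] * f[3] + f[3]) + (9 * f[3] * f[4] + f[4]) +
    (4 * f[4] * f[3] + f[3]) + (4 * f[3] * f[2] + f[2]) +
    (4 * f[2] * f[1] + f[1]) + (f[1] + 1)
  expect_equal(m$n_params, want)
  # zero weights -> output is tanh(bias) everywhere
  m0 <- m
  for (nm in names(m0$net$params)) {
    m0$net$params[[nm]]$W[] <- 0
    m0$net$params[[nm]]$b[] <- 0
  }
  m0$net$params$head$b[] <- 0.7
  vm0 <- cellquant:::viability_map(m0, img)
  expect_equal(unique(round(as.numeric(vm0), 10)), round(tanh(0.7), 10))
})

test_that("odd-sized inputs are padded transparently", {
  m <- build_count_net(base_scale = 1 / 16, seed = 5)
  img <- matrix(stats::runif(50 * 70), 50, 70)
  ff <- predict_flow_field(m, img)
  expect_identical(dim(ff$prob), c(50L, 70L))
  expect_lte(max(sqrt(ff$dy^2 + ff$dx^2)), 1 + 1e-6)
})

test_that("one-epoch training is finite and seed-deterministic", {
  train <- lapply(1:2, function(i) gen_field(700 + i, size = 32))
  sp <- unet_spec(input_size = c(32, 32, 1), base_scale = 1 / 32,
                  dropout_rate = 0.2, learning_rate = 1e-3)
  m1 <- train_confluency(build_confluency_net(sp, seed = 1), train,
                         epochs = 1, seed = 9)
  expect_true(is.finite(m1$history$loss))
  expect_equal(nrow(m1$history), 1)
  m2 <- train_confluency(build_confluency_net(sp, seed = 1), train,
                         epochs = 1, seed = 9)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_error(train_confluency(build_confluency_net(sp), list()), "empty")

  ch <- lapply(1:2, function(i) gen_chamber_scene(710 + i, size = 32,
                                                  n = 3))
  c1 <- train_count_model(build_count_net(base_scale = 1 / 16, seed = 1),
                          ch, epochs = 1, seed = 4)
  expect_true(is.finite(c1$history$loss))
  expect_gt(c1$train_diameter_px, 0)
  c2 <- train_count_model(build_count_net(base_scale = 1 / 16, seed = 1),
                          ch, epochs = 1, seed = 4)
  expect_identical(c1$history$loss, c2$history$loss)

  st <- lapply(1:2, function(i)
    gen_stained_scene(720 + i, size = 32, n = 4, dead_fraction = 0.5))
  v1 <- train_viability(build_viability_net(conv_filters = c(4, 8, 8, 8),
                                            seed = 1), st,
                        epochs = 1, seed = 4)
  expect_true(is.finite(v1$history$loss))
  all_live <- lapply(1:2, function(i)
    gen_stained_scene(730 + i, size = 32, n = 4, dead_fraction = 0))
  expect_warning(train_viability(
    build_viability_net(conv_filters = c(4, 8, 8, 8), seed = 1),
    all_live, epochs = 1, seed = 1), "imbalance")
})

test_that("viability calls are independent of label permutation", {
  m <- build_viability_net(conv_filters = c(4, 8, 8, 8), seed = 6)
  m$trained <- TRUE
  s <- gen_stained_scene(740, size = 48, n = 6, dead_fraction = 0.5)
  inst <- s$instance_map
  calls1 <- classify_objects(m, s$image, inst)
  perm <- sample(max(inst))
  inst2 <- inst
  inst2[inst > 0] <- perm[inst[inst > 0]]
  calls2 <- classify_objects(m, s$image, inst2)
  m1 <- calls1$score[order(calls1$label_id)]
  m2 <- calls2$score[match(perm[calls1$label_id[order(calls1$label_id)]],
                           calls2$label_id)]
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_equal(nrow(classify_objects(m, s$image, matrix(0L, 48, 48))), 0)
})

test_that("viability percentage is simple live share arithmetic", {
  calls <- data.frame(call = c(rep("live", 3), "dead"))
  expect_equal(viability_percent(calls), 75)
  expect_equal(viability_percent(data.frame(call = rep("live", 5))), 100)
  expect_equal(viability_percent(
    data.frame(call = rep(c("live", "dead"), c(70, 30)))), 70)
  expect_error(viability_percent(data.frame(call = character())), "no")
})
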