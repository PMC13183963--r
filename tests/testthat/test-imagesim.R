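# Generator contracts: determinism, ground-truth consistency, coverage
# control, stain separability, defocus.

test_that("identical scene specs render bit-identical samples", {
  sp <- scene_spec("adherent_field", 96, 96, target_confluency_pct = 35,
                   seed = 7)
  expect_identical(render_adherent_field(sp), render_adherent_field(sp))
  spc <- scene_spec("chamber", 96, 96, n_objects = 12, seed = 9,
                    stain = "trypan_blue", dead_fraction = 0.5)
  expect_identical(render_chamber_scene(spc), render_chamber_scene(spc))
})

test_that("adherent coverage hits the target band and is self-consistent", {
  s0 <- render_adherent_field(
    scene_spec("adherent_field", 128, 128, target_confluency_pct = 0,
               seed = 1))
  expect_equal(s0$coverage_pct, 0)
  expect_equal(nrow(s0$objects), 0)
  s40 <- render_adherent_field(
    scene_spec("adherent_field", 256, 256, target_confluency_pct = 40,
               seed = 7))
  cov_pixels <- 100 * sum(s40$semantic_mask) / length(s40$semantic_mask)
  expect_equal(s40$coverage_pct, cov_pixels, tolerance = 1e-9)
  expect_gte(cov_pixels, 38); expect_lte(cov_pixels, 42)
  s100 <- render_adherent_field(
    scene_spec("adherent_field", 128, 128, target_confluency_pct = 100,
               seed = 2))
  expect_gte(s100$coverage_pct, 98)
  expect_error(scene_spec("adherent_field", 128, 128,
                          target_confluency_pct = 120), "0, 100")
  expect_error(render_adherent_field(
    scene_spec("adherent_field", 8, 8, target_confluency_pct = 10,
               microns_per_px = 1, seed = 1)), "smaller")
})

test_that("chamber ground truth is exact: labels, classes, dead counts", {
  s <- gen_chamber_scene(101, size = 96, n = 0,
                         mix = default_object_mix())
  expect_true(all(s$instance_map == 0L))
  # 50 objects placed with a guard gap: connected components equal labels
  sp <- scene_spec("chamber", 256, 256, microns_per_px = 2,
                   n_objects = 50, object_mix = default_object_mix(14, 1),
                   overlap_cap = 0, seed = 11)
  s50 <- render_chamber_scene(sp)
  expect_equal(nrow(s50$objects), 50)
  expect_equal(sort(unique(as.integer(s50$instance_map))), 0:50)
  expect_equal(max(EBImage::bwlabel(s50$instance_map > 0)), 50)
  # every label appears exactly once in the object table
  expect_identical(sort(s50$objects$label_id), 1:50)
  # exactly round(n_cells * dead_fraction) dead cells
  sd <- gen_chamber_scene(102, size = 160, n = 100,
                          mix = default_object_mix(14, 1),
                          stain = "trypan_blue", dead_fraction = 0.3)
  expect_equal(sum(sd$objects$viability == "dead"), 30)
})

test_that("debris is labelled but excluded from the semantic ground truth", {
  s <- gen_chamber_scene(103, n = 12)
  deb <- s$objects$label_id[s$objects$class == "debris"]
  expect_gt(length(deb), 0)
  expect_true(all(s$semantic_mask[s$instance_map %in% deb] == 0))
  keep <- s$objects$label_id[s$objects$class != "debris"]
  expect_true(all(s$semantic_mask[s$instance_map %in% keep] == 1))
  tr <- truth_instances(s)
  expect_true(all(!(tr %in% deb)))
})

test_that("stained scenes separate dead from live interiors by >= 0.2", {
  for (st in c("trypan_blue", "erythrosin_b")) {
    s <- gen_chamber_scene(104, size = 128, n = 30,
                           mix = default_object_mix(16, 2), stain = st,
                           dead_fraction = 0.5)
    lum <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    mean_int <- function(ids) mean(lum[s$instance_map %in% ids])
    live <- s$objects$label_id[s$objects$viability == "live"]
    dead <- s$objects$label_id[s$objects$viability == "dead"]
    expect_gte(mean_int(live) - mean_int(dead), 0.2)
  }
})

test_that("defocus blur honours its kernel contract", {
  set.seed(51)
  img <- matrix(stats::runif(64 * 64), 64, 64)
  expect_identical(apply_defocus(img, 5, 0), img)
  blurred <- apply_defocus(img, 5, 2)
  expect_lt(stats::var(as.numeric(blurred)), stats::var(as.numeric(img)))
  expect_error(apply_defocus(img, 4, 1), "odd")
  expect_error(scene_spec("adherent_field", 64, 64,
                          target_confluency_pct = 10,
                          defocus = c(4, 1)), "odd")
  # blur grid kernels used in augmentation all behave
  for (k in c(5, 9, 13, 15)) for (sg in c(0.5, 1.5))
    expect_equal(dim(apply_defocus(img, k, sg)), dim(img))
})

test_that("object mix fractions must sum to one", {
  bad <- data.frame(class = c("cell", "bead"), diameter_um = c(10, 6),
                    diameter_sd_um = c(1, 0.1), fraction = c(0.6, 0.5))
  expect_error(scene_spec("chamber", 64, 64, n_objects = 5,
                          object_mix = bad), "sum to 1")
  beads <- bead_mix()
  expect_equal(sum(beads$fraction), 1, tolerance = 1e-12)
})
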