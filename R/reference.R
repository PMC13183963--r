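# Desk-scale reference configuration: the synthetic study conditions and
# training recipes used by the validation suite. One CPU-friendly scale,
# chosen once; thresholds match the full-scale goals (see the methods
# vignette).

ref_seed <- function(seed, i) obj_seed(seed, 7000000L + i)

#' Reference synthetic adherent field
#'
#' 14 um cells at 1 um/px on a 64 px field by default (the training
#' scale); panels probing resolution robustness render the same fields
#' at native microscope scale with `size = 256, mpp = 0.25` (~56 px per
#' cell, 14 px after letterboxing into the 64 px model input).
#'
#' @param seed Integer seed.
#' @param size Field side in px.
#' @param mpp Microns per pixel.
#' @param target Target confluency percent; drawn U(5, 95) if `NULL`.
#' @return A `rendered_sample`.
#' @export
reference_field <- function(seed, size = 64, mpp = 1, target = NULL) {
  if (is.null(target)) {
    set.seed(seed)
    target <- stats::runif(1, 5, 95)
  }
  render_adherent_field(scene_spec(
    "adherent_field", size, size, microns_per_px = mpp,
    target_confluency_pct = target,
    object_mix = default_object_mix(14, 2.1), seed = seed))
}

#' Reference synthetic chamber scene
#'
#' Counting-chamber scenes in the desk-scale geometry: 64 px fields at
#' 2 um/px with grid lines, cells of 10-20 um with 20% debris
#' (`kind = "cell"`), monodisperse beads at 1 um/px with 15% debris
#' (`kind = "bead"`), or debris only (`kind = "debris"`). Stained scenes
#' add the dye rendering used for viability training.
#'
#' @param seed Integer seed.
#' @param kind Scene family.
#' @param size Field side in px.
#' @param n Object count; a family-specific default range if `NULL`.
#' @param bead_diameter_um Bead diameter (drawn U(6, 17) if `NULL`).
#' @param stain,dead_fraction Passed to [scene_spec()].
#' @return A `rendered_sample`.
#' @export
reference_chamber <- function(seed, kind = c("cell", "bead", "debris"),
                              size = 64, n = NULL,
                              bead_diameter_um = NULL, stain = "none",
                              dead_fraction = 0) {
  kind <- match.arg(kind)
  set.seed(seed)
  grid <- chamber_geometry(grid_pitch_mm = 0.06)
  if (stain != "none") {
    # stained viability scenes: cells only, 6-16 objects
    if (is.null(n)) n <- sample(6:16, 1)
    return(render_chamber_scene(scene_spec(
      "chamber", size, size, microns_per_px = 2, n_objects = n,
      object_mix = default_object_mix(16, 2), grid = grid,
      stain = stain, dead_fraction = dead_fraction, seed = seed)))
  }
  if (kind == "cell") {
    if (is.null(n)) n <- sample(3:18, 1)
    d <- stats::runif(1, 10, 20)
    mix <- data.frame(class = c("cell", "debris"),
                      diameter_um = c(d, 4),
                      diameter_sd_um = c(d * 0.12, 1),
                      fraction = c(0.8, 0.2))
    mpp <- 2
  } else if (kind == "bead") {
    if (is.null(n)) n <- sample(5:15, 1)
    d <- if (is.null(bead_diameter_um)) stats::runif(1, 6, 17)
         else bead_diameter_um
    mix <- data.frame(class = c("bead", "debris"),
                      diameter_um = c(d, 4),
                      diameter_sd_um = c(d * 0.05, 1),
                      fraction = c(0.85, 0.15))
    mpp <- 1
  } else {
    if (is.null(n)) n <- sample(8:16, 1)
    mix <- data.frame(class = "debris", diameter_um = 4,
                      diameter_sd_um = 1, fraction = 1)
    mpp <- sample(c(1, 2), 1)
  }
  render_chamber_scene(scene_spec(
    "chamber", size, size, microns_per_px = mpp, n_objects = n,
    object_mix = mix, grid = grid, seed = seed))
}

#' Train the desk-scale reference confluency model
#'
#' 110 training and 20 validation fields from [reference_field()], a
#' `base_scale = 1/16` U-Net with 64 px input, dropout 0.1, learning
#' rate 1.5e-3.
#'
#' @param seed Seed for data generation and training.
#' @param n_train,n_val Dataset sizes.
#' @param epochs Training epochs.
#' @param verbose Print per-epoch progress.
#' @return A trained `confluency_net`.
#' @export
train_reference_confluency <- function(seed = 1L, n_train = 110,
                                       n_val = 20, epochs = 32,
                                       verbose = FALSE) {
  train <- lapply(seq_len(n_train),
                  function(i) reference_field(ref_seed(seed, i)))
  val <- lapply(seq_len(n_val),
                function(i) reference_field(ref_seed(seed, 100000 + i)))
  spec <- unet_spec(input_size = c(64, 64, 1), base_scale = 1 / 16,
                    dropout_rate = 0.1, learning_rate = 1.5e-3)
  m <- build_confluency_net(spec, seed = seed)
  train_confluency(m, train, val, epochs = epochs, seed = seed,
                   verbose = verbose)
}

#' Train the desk-scale reference count model
#'
#' 80 cell scenes, 18 bead scenes and 24 debris-only scenes
#' ([reference_chamber()]), a `base_scale = 1/4` backbone, learning rate
#' 2e-3.
#'
#' @param seed Seed for data generation and training.
#' @param epochs Training epochs.
#' @param verbose Print per-epoch progress.
#' @return A trained `count_net`.
#' @export
train_reference_count <- function(seed = 1L, epochs = 14,
                                  verbose = FALSE) {
  train <- c(
    lapply(1:80, function(i) reference_chamber(ref_seed(seed, 200000 + i),
                                               "cell")),
    lapply(1:18, function(i) reference_chamber(ref_seed(seed, 300000 + i),
                                               "bead")),
    lapply(1:24, function(i) reference_chamber(ref_seed(seed, 400000 + i),
                                               "debris")))
  m <- build_count_net(base_scale = 1 / 4, learning_rate = 2e-3,
                       seed = seed)
  train_count_model(m, train, epochs = epochs, seed = seed,
                    verbose = verbose)
}

#' Train the desk-scale reference viability model
#'
#' 40 Trypan Blue and 40 Erythrosin B stained scenes with dead fractions
#' U(0.1, 0.9), filters 8/16/32/32, learning rate 2e-3.
#'
#' @param seed Seed for data generation and training.
#' @param n_per_dye Scenes per dye.
#' @param epochs Training epochs.
#' @param verbose Print per-epoch progress.
#' @return A trained `viability_net`.
#' @export
train_reference_viability <- function(seed = 1L, n_per_dye = 40,
                                      epochs = 8, verbose = FALSE) {
  gen <- function(i, stain) {
    s <- ref_seed(seed, 500000 + i)
    set.seed(s)
    reference_chamber(s, "cell", stain = stain,
                      dead_fraction = stats::runif(1, 0.1, 0.9))
  }
  train <- c(lapply(seq_len(n_per_dye), gen, stain = "trypan_blue"),
             lapply(n_per_dye + seq_len(n_per_dye), gen,
                    stain = "erythrosin_b"))
  m <- build_viability_net(conv_filters = c(8, 16, 32, 32),
                           learning_rate = 2e-3, seed = seed)
  train_viability(m, train, epochs = epochs, seed = seed,
                  verbose = verbose)
}

#' Density strata for scaled chamber evaluation
#'
#' Object-count ranges for 128 px (2 um/px, 0.0655 mm^2) evaluation
#' fields matching the <50 / 50-300 / >300 objects-per-mm^2 strata of a
#' 1 x 1 mm chamber square.
#'
#' @return Named list of `c(lo, hi)` count ranges.
#' @export
reference_density_strata <- function() {
  list(low = c(1, 3), mid = c(4, 19), high = c(21, 40))
}
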