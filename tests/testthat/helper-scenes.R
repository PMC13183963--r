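# Shared generators for the desk-scale study conditions. Cells are ~14 um
# rendered at 1 um/px (14 px across a 64 px model field), matching the
# relative cell size of 10x brightfield images letterboxed into the
# full-scale network.

cell_debris_mix <- function(diameter_um) data.frame(
  class = c("cell", "debris"),
  diameter_um = c(diameter_um, 4), diameter_sd_um = c(diameter_um * 0.12, 1),
  fraction = c(0.8, 0.2), stringsAsFactors = FALSE)

bead_debris_mix <- function(diameter_um) data.frame(
  class = c("bead", "debris"),
  diameter_um = c(diameter_um, 4), diameter_sd_um = c(diameter_um * 0.05, 1),
  fraction = c(0.85, 0.15), stringsAsFactors = FALSE)

gen_field <- function(seed, size = 64, target = NULL, mpp = 1,
                      diameter_um = 14) {
  if (is.null(target)) { set.seed(seed); target <- stats::runif(1, 5, 95) }
  sp <- scene_spec("adherent_field", size, size, microns_per_px = mpp,
                   target_confluency_pct = target,
                   object_mix = default_object_mix(diameter_um,
                                                   diameter_um * 0.15),
                   seed = seed)
  render_adherent_field(sp)
}

gen_chamber_scene <- function(seed, size = 64, n = NULL, mix = NULL,
                              mpp = 2, cap = 0.3, stain = "none",
                              dead_fraction = 0, grid_pitch = 0.06) {
  set.seed(seed)
  if (is.null(n)) n <- sample(3:18, 1)
  if (is.null(mix)) mix <- cell_debris_mix(stats::runif(1, 10, 20))
  g <- chamber_geometry(grid_pitch_mm = grid_pitch)
  sp <- scene_spec("chamber", size, size, microns_per_px = mpp,
                   n_objects = n, object_mix = mix, grid = g,
                   overlap_cap = cap, stain = stain,
                   dead_fraction = dead_fraction, seed = seed)
  render_chamber_scene(sp)
}

gen_bead_scene <- function(seed, lo = 5.5, hi = 17) {
  set.seed(seed)
  d <- stats::runif(1, lo, hi)
  gen_chamber_scene(seed, n = sample(6:14, 1),
                    mix = data.frame(class = "bead", diameter_um = d,
                                     diameter_sd_um = d * 0.04,
                                     fraction = 1), mpp = 1)
}

gen_stained_scene <- function(seed, stain = "trypan_blue", size = 64,
                              n = NULL, dead_fraction = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:16, 1)
  if (is.null(dead_fraction)) dead_fraction <- stats::runif(1, 0.1, 0.9)
  gen_chamber_scene(seed, size = size, n = n,
                    mix = default_object_mix(16, 2), stain = stain,
                    dead_fraction = dead_fraction)
}

# instance map with debris removed (counting/segmentation ground truth)
truth_instances <- function(s) {
  inst <- s$instance_map
  drop <- s$objects$label_id[s$objects$class == "debris"]
  if (length(drop)) inst[inst %in% drop] <- 0L
  inst
}

# disc-shaped instance map for constructed toys (0-based centres)
disc_map <- function(H, W, centres, radius) {
  m <- matrix(0L, H, W)
  for (k in seq_len(nrow(centres))) {
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if ((i - 1 - centres[k, 1])^2 + (j - 1 - centres[k, 2])^2 <=
          radius^2 && m[i, j] == 0L) m[i, j] <- k
    }
  }
  m
}
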