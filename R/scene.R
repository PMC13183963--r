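#' Chamber geometry for counting-chamber scenes
#'
#' Describes one counting square of a hemocytometer-style chamber. A
#' standard hemocytometer big square is 1 x 1 mm with a 0.1 mm chamber
#' depth, giving 1e-4 mL per square; high-density samples are counted in
#' the smaller 0.2 mm squares. `dilution_factor` is the fold-dilution
#' applied to the sample before loading (mixing 1:1 with Trypan Blue gives
#' 2).
#'
#' @param square_side_mm Side length of the counted square in mm.
#' @param depth_mm Chamber depth in mm.
#' @param grid_pitch_mm Spacing of rendered grid lines in mm; defaults to
#'   the square side.
#' @param dilution_factor Fold dilution applied before loading.
#' @return An object of class `chamber_geometry`.
#' @export
chamber_geometry <- function(square_side_mm = 1, depth_mm = 0.1,
                             grid_pitch_mm = square_side_mm,
                             dilution_factor = 1) {
  stopifnot(square_side_mm > 0, depth_mm > 0, grid_pitch_mm > 0,
            dilution_factor > 0)
  structure(list(square_side_mm = square_side_mm, depth_mm = depth_mm,
                 grid_pitch_mm = grid_pitch_mm,
                 dilution_factor = dilution_factor),
            class = "chamber_geometry")
}

#' Volume of one counted square in mL
#' @param geometry A [chamber_geometry()].
#' @return Volume in mL (1 mm^3 = 1e-3 mL).
#' @export
square_volume_ml <- function(geometry) {
  geometry$square_side_mm^2 * geometry$depth_mm * 1e-3
}

#' Specification of a synthetic microscopy scene
#'
#' Declarative description of one synthetic image: either an adherent
#' culture field (driven by a target confluency) or a counting-chamber
#' scene (driven by an object count). The generator is fully deterministic
#' given the spec, including its `seed`.
#'
#' @param scene_kind `"adherent_field"` or `"chamber"`.
#' @param width_px,height_px Image size in pixels.
#' @param microns_per_px Physical pixel pitch.
#' @param target_confluency_pct Target percent coverage (adherent only).
#' @param n_objects Number of objects to place (chamber only).
#' @param object_mix Data frame with columns `class` (`"cell"`, `"bead"`,
#'   `"debris"`), `diameter_um`, `diameter_sd_um`, `fraction`; fractions
#'   must sum to 1.
#' @param dead_fraction Fraction of cells rendered dead; applied
#'   deterministically (`round(n_cells * dead_fraction)` dead cells).
#' @param stain `"none"`, `"trypan_blue"` or `"erythrosin_b"`. Stained
#'   scenes are rendered in RGB with dye-filled dead-cell interiors.
#' @param grid Optional [chamber_geometry()]; chamber scenes render grid
#'   lines at its `grid_pitch_mm`.
#' @param defocus Optional `c(kernel_size, sigma)` Gaussian defocus applied
#'   to the final image.
#' @param overlap_cap Maximum allowed pairwise IoU between placed chamber
#'   objects (default 0.3, so touching/overlapping cells are exercised).
#' @param seed Integer seed; identical specs render bit-identical samples.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(scene_kind = c("adherent_field", "chamber"),
                       width_px = 256, height_px = 256, microns_per_px = 1,
                       target_confluency_pct = NULL, n_objects = NULL,
                       object_mix = default_object_mix(),
                       dead_fraction = 0, stain = c("none", "trypan_blue",
                                                    "erythrosin_b"),
                       grid = NULL, defocus = NULL, overlap_cap = 0.3,
                       seed = 1L) {
  scene_kind <- match.arg(scene_kind)
  stain <- match.arg(stain)
  stopifnot(width_px >= 8, height_px >= 8, microns_per_px > 0,
            dead_fraction >= 0, dead_fraction <= 1)
  if (scene_kind == "adherent_field") {
    if (is.null(target_confluency_pct))
      stop("adherent_field requires target_confluency_pct")
    if (target_confluency_pct < 0 || target_confluency_pct > 100)
      stop("target_confluency_pct must be in [0, 100]")
  } else {
    if (is.null(n_objects) || n_objects < 0)
      stop("chamber scenes require n_objects >= 0")
  }
  stopifnot(is.data.frame(object_mix),
            all(c("class", "diameter_um", "diameter_sd_um", "fraction") %in%
                  names(object_mix)),
            all(object_mix$diameter_um > 0),
            all(object_mix$class %in% c("cell", "bead", "debris")))
  if (abs(sum(object_mix$fraction) - 1) > 1e-9)
    stop("object_mix fractions must sum to 1")
  if (!is.null(defocus)) {
    stopifnot(length(defocus) == 2, defocus[2] >= 0)
    if (defocus[1] %% 2 == 0) stop("defocus kernel_size must be odd")
  }
  if (!is.null(grid)) stopifnot(inherits(grid, "chamber_geometry"))
  structure(list(scene_kind = scene_kind, width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_px = microns_per_px,
                 target_confluency_pct = target_confluency_pct,
                 n_objects = if (is.null(n_objects)) NULL
                             else as.integer(n_objects),
                 object_mix = object_mix, dead_fraction = dead_fraction,
                 stain = stain, grid = grid, defocus = defocus,
                 overlap_cap = overlap_cap, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default object mix: a single population of ~16 um cells
#' @param diameter_um,diameter_sd_um Mean and SD of cell diameter.
#' @return Data frame usable as `object_mix` in [scene_spec()].
#' @export
default_object_mix <- function(diameter_um = 16, diameter_sd_um = 2) {
  data.frame(class = "cell", diameter_um = diameter_um,
             diameter_sd_um = diameter_sd_um, fraction = 1,
             stringsAsFactors = FALSE)
}

#' Mix of reference beads (6 / 10 / 16 um) in equal proportions
#' @param sizes_um Bead diameters in um.
#' @return Data frame usable as `object_mix` in [scene_spec()].
#' @export
bead_mix <- function(sizes_um = c(6, 10, 16)) {
  data.frame(class = "bead", diameter_um = sizes_um, diameter_sd_um = 0.15,
             fraction = rep(1 / length(sizes_um), length(sizes_um)),
             stringsAsFactors = FALSE)
}

# Hierarchical seed streams: the scene seed spawns one sub-stream per
# object so that changing the object count never reshuffles earlier
# objects. Kept below 2^31.
obj_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec>", x$scene_kind, sprintf("%dx%d px", x$width_px,
      x$height_px), sprintf("(%g um/px)", x$microns_per_px), "\n")
  if (x$scene_kind == "adherent_field")
    cat("  target confluency:", x$target_confluency_pct, "%\n")
  else cat("  n_objects:", x$n_objects, " stain:", x$stain,
           " dead_fraction:", x$dead_fraction, "\n")
  invisible(x)
}
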