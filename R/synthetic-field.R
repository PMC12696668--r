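#' A 3D scalar volume on a world-coordinate grid
#'
#' Minimal container for pressure/intensity fields and masks: an array of
#' voxel values plus an axis-aligned RAS+ world mapping
#' (world = origin + (index - 1) * spacing, in mm). The package-wide
#' convention is RAS+, millimetres: right = +x, anterior = +y,
#' superior = +z; for a left-hemisphere target (x < 0), medial = +x.
#'
#' @param values 3D numeric array.
#' @param spacing Voxel spacing in mm (length 1 or 3).
#' @param origin World coordinates of voxel (1,1,1) in mm.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(values, spacing = 1, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3)
  spacing <- rep_len(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("vol3d: %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$spacing, collapse = "x"),
              paste(x$origin, collapse = ", ")))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' @param vol A [vol3d()].
#' @param idx Voxel index triple (1-based) or matrix of triples.
#' @return World mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' @rdname voxel_to_world
#' @param world World mm coordinates.
#' @export
world_to_voxel <- function(vol, world) {
  if (is.null(dim(world))) world <- matrix(world, nrow = 1)
  sweep(sweep(world, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

#' World coordinates along each grid axis
#' @noRd
axis_coords <- function(grid_shape, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(grid_shape[a]) - 1) * spacing[a])
}

#' Configuration for the synthetic acoustic-field generator
#'
#' Emulates the geometry of post-hoc acoustic simulations of a
#' TMS-hotspot-guided transducer placement over left M1: a
#' Gaussian-ellipsoid focus with configurable intensity FWHM, placed at
#' the omega-formation target plus a systematic anteromedial bias and
#' per-axis Gaussian jitter (truncated at 2 SD so the focus stays within
#' the synthetic head). The defaults encode the dispersion observed when
#' transducer placement follows the TMS hotspot: anterior shift
#' 10.5 +/- 14.2 mm, a strongly consistent small medial shift, a
#' non-significant inferior shift, and in-situ peak intensities of
#' 1.20 +/- 0.43 W/cm2.
#'
#' @param grid_shape Voxel counts per axis (default 96^3).
#' @param spacing Voxel spacing in mm (default 1, isotropic).
#' @param origin World mm of voxel (1,1,1) (default -48 per axis).
#' @param target_point Omega-formation target, world mm (~30 mm depth
#'   below the synthetic scalp plane at z = 48).
#' @param lip_point Precentral gyral lip landmark (~18 mm depth).
#' @param roi_radius M1 spherical ROI radius in mm (default 15); the ROI
#'   is centred midway between omega and lip so it covers both.
#' @param focus_fwhm Intensity full-width half-maximum per axis in mm
#'   (default 6 x 6 x 30: lateral, lateral, axial).
#' @param placement_bias Mean peak displacement (medial, anterior,
#'   superior) in mm.
#' @param placement_sd Per-axis jitter SD in mm.
#' @param peak_insitu_isppa Mean in-situ peak Isppa in W/cm2.
#' @param peak_insitu_sd SD of the in-situ peak Isppa.
#' @param seed Integer seed.
#' @return A list of class `field_gen_config`.
#' @export
field_gen_config <- function(grid_shape = c(96, 96, 96), spacing = 1,
                             origin = c(-48, -48, -48),
                             target_point = c(-10, 0, 18),
                             lip_point = c(-10, 0, 30),
                             roi_radius = 15,
                             focus_fwhm = c(6, 6, 30),
                             placement_bias = c(5, 10.5, -3),
                             placement_sd = c(2.6, 14.2, 7),
                             peak_insitu_isppa = 1.20,
                             peak_insitu_sd = 0.43,
                             seed = 1L) {
  spacing <- rep_len(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(focus_fwhm <= 0)) stop("focus FWHM must be positive")
  if (peak_insitu_isppa <= 0) stop("peak in-situ Isppa must be positive")
  lo <- origin
  hi <- origin + (grid_shape - 1) * spacing
  if (any(target_point < lo | target_point > hi)) {
    stop("target point lies outside the grid")
  }
  if (any(focus_fwhm > (hi - lo))) stop("focus is larger than the grid")
  structure(list(
    grid_shape = grid_shape, spacing = spacing, origin = origin,
    target_point = target_point, lip_point = lip_point,
    roi_radius = roi_radius, focus_fwhm = focus_fwhm,
    placement_bias = placement_bias, placement_sd = placement_sd,
    peak_insitu_isppa = peak_insitu_isppa, peak_insitu_sd = peak_insitu_sd,
    seed = seed
  ), class = "field_gen_config")
}

#' Sample focus placements and peak intensities without building volumes
#'
#' Draws the per-participant focus-centre world coordinates
#' (target + bias + truncated Gaussian jitter) and peak in-situ Isppa
#' values that [generate_pressure_field()] realises as full 3D fields.
#' Used directly by Monte-Carlo suites where only the placement geometry
#' matters.
#'
#' @param config A [field_gen_config()].
#' @param n Number of participants.
#' @return A list with `centre` (n x 3 matrix, world mm) and `isppa`
#'   (length-n vector, W/cm2).
#' @export
sample_focus_placements <- function(config, n) {
  stopifnot(inherits(config, "field_gen_config"))
  with_seed(config$seed, sample_focus_placements_impl(config, n))
}

#' @noRd
sample_focus_placements_impl <- function(config, n) {
  jit <- matrix(stats::rnorm(3 * n), ncol = 3)
  jit <- pmin(pmax(jit, -2), 2)   # truncate at 2 SD to stay in the head
  jit <- sweep(jit, 2, config$placement_sd, `*`)
  centre <- sweep(jit, 2, config$target_point + config$placement_bias, `+`)
  isppa <- stats::rnorm(n, config$peak_insitu_isppa, config$peak_insitu_sd)
  isppa <- pmax(isppa, 0.05 * config$peak_insitu_isppa)
  list(centre = centre, isppa = isppa)
}

#' Synthetic head model: brain mask, landmarks and M1 ROI
#'
#' The synthetic brain is a rectangular slab (|x|, |y| <= 42 mm,
#' z <= 40 mm, i.e. everything deeper than an 8 mm scalp/skull shell
#' below the z = 48 scalp plane). It is a geometric stand-in, sufficient
#' for threshold, overlap and distance arithmetic.
#'
#' @param config A [field_gen_config()].
#' @return A list of class `head_model` with `brain_mask` (vol3d, 0/1),
#'   `omega`, `lip` (world mm), and `m1_roi` (list: centre, radius).
#' @export
synthetic_head_model <- function(config = field_gen_config()) {
  ax <- axis_coords(config$grid_shape, config$spacing, config$origin)
  inx <- abs(ax[[1]]) <= 42
  iny <- abs(ax[[2]]) <= 42
  inz <- ax[[3]] <= 40
  mask <- array(0, config$grid_shape)
  mask[inx, iny, inz] <- 1
  structure(list(
    brain_mask = vol3d(mask, config$spacing, config$origin),
    omega = config$target_point,
    lip = config$lip_point,
    m1_roi = list(centre = (config$target_point + config$lip_point) / 2,
                  radius = config$roi_radius)
  ), class = "head_model")
}

#' Generate a synthetic acoustic pressure field for one participant
#'
#' Realises one sampled placement as a separable Gaussian-ellipsoid
#' pressure field whose plane-wave intensity has the configured FWHM and
#' peak value: p(r) = p_peak * exp(-2 ln2 * sum(d_i^2 / w_i^2)), so that
#' I = p^2/(2 rho c) = I_peak * exp(-4 ln2 * sum(d_i^2 / w_i^2)).
#'
#' @param config A [field_gen_config()]; its `seed` drives the placement.
#' @param constants Output of [acoustic_constants()].
#' @return A list with `pressure` (vol3d, Pa), `head`
#'   ([synthetic_head_model()]), `focus_centre` (world mm) and
#'   `peak_isppa` (W/cm2).
#' @export
generate_pressure_field <- function(config = field_gen_config(),
                                    constants = acoustic_constants()) {
  stopifnot(inherits(config, "field_gen_config"))
  draw <- sample_focus_placements(config, 1)
  centre <- draw$centre[1, ]
  p_peak <- pressure_from_isppa(draw$isppa[1], constants)
  ax <- axis_coords(config$grid_shape, config$spacing, config$origin)
  # separable exponent: pressure falls at exp(-2 ln2 u), intensity at
  # exp(-4 ln2 u), giving the intensity field the configured FWHM
  gx <- exp(-2 * log(2) * ((ax[[1]] - centre[1]) / config$focus_fwhm[1])^2)
  gy <- exp(-2 * log(2) * ((ax[[2]] - centre[2]) / config$focus_fwhm[2])^2)
  gz <- exp(-2 * log(2) * ((ax[[3]] - centre[3]) / config$focus_fwhm[3])^2)
  values <- p_peak * (gx %o% gy %o% gz)
  list(pressure = vol3d(values, config$spacing, config$origin),
       head = synthetic_head_model(config),
       focus_centre = centre,
       peak_isppa = draw$isppa[1])
}

#' Generate acoustic pressure fields for a cohort
#'
#' Per-participant fields share the grid and head model; participant i
#' uses seed `config$seed + i - 1` so the cohort is reproducible and each
#' member individually regenerable.
#'
#' @param config A [field_gen_config()].
#' @param n_participants Number of participants.
#' @param constants Output of [acoustic_constants()].
#' @return A list with `fields` (list of [generate_pressure_field()]
#'   outputs) and `head` (shared head model).
#' @export
generate_field_cohort <- function(config = field_gen_config(),
                                  n_participants = 15,
                                  constants = acoustic_constants()) {
  fields <- lapply(seq_len(n_participants), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    generate_pressure_field(cfg_i, constants)
  })
  list(fields = fields, head = synthetic_head_model(config))
}
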