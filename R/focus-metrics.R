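#' Voxel-wise plane-wave intensity from a pressure volume
#'
#' @param pressure A [vol3d()] of pressure amplitude in Pa.
#' @param constants Output of [acoustic_constants()].
#' @return A [vol3d()] of pulse-average intensity in W/cm2.
#' @export
intensity_volume_from_pressure <- function(pressure,
                                           constants = acoustic_constants()) {
  stopifnot(inherits(pressure, "vol3d"))
  vol3d(isppa_from_pressure(pressure$values, constants),
        pressure$spacing, pressure$origin)
}

#' Location and value of the in-brain intensity maximum
#'
#' Argmax of the intensity restricted to brain-mask voxels; ties are
#' broken by the lowest linear voxel index.
#'
#' @param intensity A [vol3d()] of intensity.
#' @param brain_mask A [vol3d()] 0/1 mask on the same grid.
#' @return A list with `voxel` (index triple), `world` (mm) and `value`.
#' @export
in_brain_peak <- function(intensity, brain_mask) {
  check_same_grid(intensity, brain_mask)
  inb <- which(brain_mask$values > 0)
  if (length(inb) == 0) stop("empty brain mask")
  lin <- inb[which.max(intensity$values[inb])]  # which.max: first = lowest index
  vox <- arrayInd(lin, dim(intensity$values))[1, ]
  list(voxel = vox, world = drop(voxel_to_world(intensity, vox)),
       value = intensity$values[lin])
}

#' @noRd
check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      any(a$spacing != b$spacing) || any(a$origin != b$origin)) {
    stop("volumes are not on the same grid")
  }
  invisible(TRUE)
}

#' Full-width half-maximum acoustic focus
#'
#' The focus is the set of brain voxels whose intensity is greater than
#' or equal to half of the in-brain maximum (voxels at exactly half
#' maximum are included). No connected-component filtering is applied;
#' the focus is restricted to the brain mask.
#'
#' @param intensity A [vol3d()] of intensity.
#' @param brain_mask A [vol3d()] 0/1 mask on the same grid.
#' @return A list with `mask` (vol3d, 0/1), `volume_mm3`, `peak` (from
#'   [in_brain_peak()]) and `threshold`.
#' @export
fwhm_focus <- function(intensity, brain_mask) {
  pk <- in_brain_peak(intensity, brain_mask)
  if (pk$value <= 0) stop("in-brain intensity maximum is zero")
  thr <- pk$value / 2
  m <- (intensity$values >= thr) & (brain_mask$values > 0)
  storage.mode(m) <- "double"
  vol <- sum(m) * prod(intensity$spacing)
  list(mask = vol3d(m, intensity$spacing, intensity$origin),
       volume_mm3 = vol, peak = pk, threshold = thr)
}

#' Spherical region-of-interest mask on a volume grid
#'
#' @param vol A [vol3d()] providing the grid.
#' @param centre World mm centre.
#' @param radius Radius in mm.
#' @return A [vol3d()] 0/1 mask.
#' @export
sphere_roi <- function(vol, centre, radius) {
  if (radius <= 0) stop("radius must be positive")
  ax <- axis_coords(dim(vol$values), vol$spacing, vol$origin)
  dx2 <- (ax[[1]] - centre[1])^2
  dy2 <- (ax[[2]] - centre[2])^2
  dz2 <- (ax[[3]] - centre[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  m <- d2 <= radius^2
  storage.mode(m) <- "double"
  vol3d(m, vol$spacing, vol$origin)
}

#' Focus/ROI overlap and ROI peak intensity
#'
#' @param focus_mask Focus mask ([vol3d()], 0/1) from [fwhm_focus()].
#' @param roi_mask ROI mask ([vol3d()], 0/1) on the same grid.
#' @param intensity Intensity [vol3d()] on the same grid.
#' @return A list with `overlap_pct` (percentage of focus voxels inside
#'   the ROI) and `roi_peak_isppa` (max intensity over ROI voxels).
#' @export
roi_overlap <- function(focus_mask, roi_mask, intensity) {
  check_same_grid(focus_mask, roi_mask)
  check_same_grid(focus_mask, intensity)
  nf <- sum(focus_mask$values > 0)
  if (nf == 0) stop("empty focus mask")
  inter <- sum(focus_mask$values > 0 & roi_mask$values > 0)
  roi_vox <- which(roi_mask$values > 0)
  list(overlap_pct = 100 * inter / nf,
       roi_peak_isppa = if (length(roi_vox)) max(intensity$values[roi_vox])
                        else NA_real_)
}

#' Distances and signed axis shifts from the intensity peak to landmarks
#'
#' Euclidean distances from the peak location to the omega-formation and
#' gyral-lip landmarks, plus the signed displacement of the peak relative
#' to the omega target in the package's RAS+/medial convention: for a
#' left-hemisphere target, medial = +x; anterior = +y; superior = +z.
#'
#' @param peak_loc World mm location of the intensity peak.
#' @param head A [synthetic_head_model()] (or any list with `omega` and
#'   `lip` world coordinates).
#' @return A list with `dist_omega`, `dist_lip` (mm) and `axis_shift`
#'   (named vector: medial, anterior, superior).
#' @export
landmark_distances <- function(peak_loc, head) {
  d <- peak_loc - head$omega
  list(dist_omega = sqrt(sum(d^2)),
       dist_lip = sqrt(sum((peak_loc - head$lip)^2)),
       axis_shift = stats::setNames(d, c("medial", "anterior", "superior")))
}

#' Complete targeting report for one participant
#'
#' Runs the full focus-quantification chain: plane-wave intensity
#' conversion, in-brain peak, FWHM focus, M1 ROI overlap, and landmark
#' distances.
#'
#' @param pressure A [vol3d()] pressure field in Pa.
#' @param head A [synthetic_head_model()].
#' @param constants Output of [acoustic_constants()].
#' @return An object of class `focus_report`.
#' @export
focus_report <- function(pressure, head, constants = acoustic_constants()) {
  intensity <- intensity_volume_from_pressure(pressure, constants)
  foc <- fwhm_focus(intensity, head$brain_mask)
  roi <- sphere_roi(intensity, head$m1_roi$centre, head$m1_roi$radius)
  ov <- roi_overlap(foc$mask, roi, intensity)
  ld <- landmark_distances(foc$peak$world, head)
  structure(list(
    peak_loc = foc$peak$world,
    peak_isppa = foc$peak$value,
    focus_mask = foc$mask,
    focus_volume_mm3 = foc$volume_mm3,
    overlap_pct = ov$overlap_pct,
    roi_peak_isppa = ov$roi_peak_isppa,
    dist_omega = ld$dist_omega,
    dist_lip = ld$dist_lip,
    axis_shift = ld$axis_shift
  ), class = "focus_report")
}

#' @export
print.focus_report <- function(x, ...) {
  cat("Acoustic focus report\n")
  cat(sprintf("  peak Isppa:     %.3f W/cm2 at (%s) mm\n", x$peak_isppa,
              paste(sprintf("%.1f", x$peak_loc), collapse = ", ")))
  cat(sprintf("  focus volume:   %.0f mm3\n", x$focus_volume_mm3))
  cat(sprintf("  ROI overlap:    %.1f%%  (ROI peak %.3f W/cm2)\n",
              x$overlap_pct, x$roi_peak_isppa))
  cat(sprintf("  dist to omega:  %.1f mm;  dist to lip: %.1f mm\n",
              x$dist_omega, x$dist_lip))
  cat(sprintf("  axis shift:     medial %+.1f, anterior %+.1f, superior %+.1f mm\n",
              x$axis_shift[1], x$axis_shift[2], x$axis_shift[3]))
  invisible(x)
}

#' One-sample t-tests of per-axis focus shifts against zero
#'
#' @param shifts n x 3 matrix of per-participant axis shifts (medial,
#'   anterior, superior), in mm.
#' @return A data.frame with one row per axis: mean, sd, t, df, p, and a
#'   `degenerate` flag for zero-variance axes with nonzero mean (where p
#'   underflows to 0).
#' @export
group_axis_tests <- function(shifts) {
  shifts <- as.matrix(shifts)
  if (nrow(shifts) < 2) stop("need at least two participants per axis")
  axes <- c("medial", "anterior", "superior")
  rows <- lapply(1:3, function(a) {
    x <- shifts[, a]
    m <- mean(x); s <- stats::sd(x); n <- length(x)
    if (s == 0) {
      data.frame(axis = axes[a], mean = m, sd = s,
                 t = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
                 p = if (m == 0) 1 else 0, degenerate = m != 0)
    } else {
      tt <- stats::t.test(x, mu = 0)
      data.frame(axis = axes[a], mean = m, sd = s,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sum binary focus masks across participants
#'
#' @param masks List of focus-mask [vol3d()]s on one common grid.
#' @return A [vol3d()] count volume (max value <= number of masks).
#' @export
group_focus_map <- function(masks) {
  if (length(masks) == 0) stop("no masks supplied")
  for (m in masks[-1]) check_same_grid(masks[[1]], m)
  total <- Reduce(`+`, lapply(masks, function(m) m$values))
  vol3d(total, masks[[1]]$spacing, masks[[1]]$origin)
}
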