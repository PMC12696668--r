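#' Write a volume to NIfTI-1
#'
#' The axis-aligned world mapping (spacing + origin, RAS+ mm) is stored
#' in the sform.
#'
#' @param vol A [vol3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol3d"))
  aff <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' Requires an axis-aligned affine (no rotation/shear), which is what
#' [write_volume()] produces.
#'
#' @param path NIfTI file path.
#' @return A [vol3d()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6) {
    stop("only axis-aligned affines are supported")
  }
  vol3d(as.array(img), spacing = diag(rot), origin = aff[1:3, 4])
}

#' Write and read trial tables as CSV
#'
#' The column dictionary: `trial_id` (unique key into the waveform
#' store), design columns (`participant`, `condition`, `timepoint`,
#' `muscle`, `pulse_type`, `trial`), the drawn `amplitude` (mV),
#' ground-truth artefact labels (`gt_*`, logical), derived measures
#' (`mep_pp`, `pre_rms`, `pre_pp`, mV) and exclusion flags (`outlier`,
#' `precontraction`, `noise`, `excluded`, logical) when present.
#'
#' @param trials A trial table.
#' @param path CSV path.
#' @return `path` invisibly (write) or the trial table (read).
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(c("gt_outlier", "gt_precontraction", "gt_noise",
                         "outlier", "precontraction", "noise", "excluded"),
                       names(tr))) {
    tr[[cl]] <- as.logical(tr[[cl]])
  }
  tr
}

#' Write and read a waveform store
#'
#' The store is a trials x samples matrix keyed by trial id, with
#' sampling-rate and stimulus-sample metadata; it is serialised with R's
#' native format.
#'
#' @param waveforms Waveform matrix from [generate_emg_cohort()].
#' @param path Output path (`.rds`).
#' @return `path` invisibly (write) or the waveform matrix (read).
#' @export
write_waveforms <- function(waveforms, path) {
  saveRDS(waveforms, path)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  readRDS(path)
}
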