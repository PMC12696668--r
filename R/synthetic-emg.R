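#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic EMG cohort generator
#'
#' Encodes the design of a two-session, four-timepoint TUS-TMS study:
#' right-skewed (log-normal) trial-level MEP amplitudes centred near
#' 1 mV at baseline, paired-pulse conditioning ratios (SICI below 1,
#' ICF above 1), a per-timepoint multiplicative condition effect under
#' verum (1 = null), and independent injection of amplitude-outlier,
#' pre-contraction and noise-dominated artefact trials.
#'
#' @param n_participants Number of participants (default 15).
#' @param trials_per_block Trials per measurement block (default 25).
#' @param timepoints Ordered timepoint labels.
#' @param conditions Condition labels (first label is the active one).
#' @param muscles Muscle labels.
#' @param sampling_rate EMG sampling rate in Hz (default 5000).
#' @param mep_log_mu,mep_log_sigma Log-normal parameters of the
#'   trial-level single-pulse amplitude in mV. Defaults (-0.114, 0.45),
#'   with `participant_sd` 0.35, put the grand baseline mean near
#'   1.05 mV.
#' @param participant_sd SD of the participant-level random effect on the
#'   log-amplitude scale.
#' @param sici_ratio,icf_ratio Multiplicative conditioning factors
#'   (defaults 0.45 and 1.3).
#' @param condition_effect Named per-timepoint multiplicative MEP change
#'   under verum; default all 1 (null effect).
#' @param outlier_rate,precontraction_rate,noise_rate Artefact injection
#'   probabilities (defaults 0.016, 0.018, 0.0055).
#' @param outlier_multiplier Amplitude multiplier for injected outliers.
#' @param precontraction_rms_mult Pre-window RMS multiplier for injected
#'   pre-contraction trials.
#' @param baseline_noise_sd Resting EMG noise SD in mV (default 0.005).
#' @param noise_rms RMS (mV) of the broadband contamination added to
#'   injected noise trials (default 0.08, above the 0.045 inspection
#'   threshold).
#' @param seed Integer seed.
#' @return A list of class `emg_gen_config`.
#' @export
emg_gen_config <- function(n_participants = 15, trials_per_block = 25,
                           timepoints = c("Baseline", "T5", "T30", "T60"),
                           conditions = c("verum", "sham"),
                           muscles = c("FDI", "APB", "ADM"),
                           sampling_rate = 5000,
                           mep_log_mu = -0.114, mep_log_sigma = 0.45,
                           participant_sd = 0.35,
                           sici_ratio = 0.45, icf_ratio = 1.3,
                           condition_effect = NULL,
                           outlier_rate = 0.016, precontraction_rate = 0.018,
                           noise_rate = 0.0055,
                           outlier_multiplier = 8,
                           precontraction_rms_mult = 10,
                           baseline_noise_sd = 0.005,
                           noise_rms = 0.08,
                           seed = 1L) {
  if (n_participants < 1 || trials_per_block < 1) {
    stop("participant and trial counts must be positive")
  }
  if (anyDuplicated(timepoints) || anyDuplicated(conditions) ||
      anyDuplicated(muscles)) {
    stop("timepoint, condition and muscle labels must be unique")
  }
  if (any(c(outlier_rate, precontraction_rate, noise_rate) < 0) ||
      any(c(outlier_rate, precontraction_rate, noise_rate) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  if (mep_log_sigma <= 0) stop("mep_log_sigma must be positive")
  if (is.null(condition_effect)) {
    condition_effect <- stats::setNames(rep(1, length(timepoints)), timepoints)
  }
  if (is.null(names(condition_effect)) ||
      !all(timepoints %in% names(condition_effect))) {
    stop("condition_effect must be named by timepoint")
  }
  structure(list(
    n_participants = n_participants, trials_per_block = trials_per_block,
    timepoints = timepoints, conditions = conditions, muscles = muscles,
    sampling_rate = sampling_rate, mep_log_mu = mep_log_mu,
    mep_log_sigma = mep_log_sigma, participant_sd = participant_sd,
    sici_ratio = sici_ratio, icf_ratio = icf_ratio,
    condition_effect = condition_effect, outlier_rate = outlier_rate,
    precontraction_rate = precontraction_rate, noise_rate = noise_rate,
    outlier_multiplier = outlier_multiplier,
    precontraction_rms_mult = precontraction_rms_mult,
    baseline_noise_sd = baseline_noise_sd, noise_rms = noise_rms,
    seed = seed
  ), class = "emg_gen_config")
}

#' The facilitation preset reported for the original 5 Hz-rTUS protocol
#'
#' A `condition_effect` vector encoding excitatory neuromodulation of the
#' size originally reported for this protocol: ~1.4x MEP facilitation at
#' 5 and 30 min post-sonication, decaying by 60 min. Used for power and
#' effect-recovery simulations.
#'
#' @return Named numeric vector over the default timepoints.
#' @export
original_study_effect <- function() {
  c(Baseline = 1, T5 = 1.4, T30 = 1.4, T60 = 1.2)
}

#' Generate a synthetic EMG cohort
#'
#' Produces a trial table with one row per participant x condition x
#' timepoint x muscle x pulse type x trial, and (optionally) a waveform
#' store with one sampled EMG trace per trial. Pulse types are `single`
#' (single-pulse at SI_1mV), `TS` (test stimulus alone within the
#' paired-pulse block), `SICI` and `ICF` (conditioned). Trial amplitudes
#' are drawn log-normally; the condition effect multiplies single-pulse
#' and TS amplitudes under verum. Artefact trials are injected
#' independently and recorded in ground-truth columns (`gt_outlier`,
#' `gt_precontraction`, `gt_noise`) that downstream filters never see.
#'
#' Waveforms are 220 ms traces sampled at `sampling_rate`: 100 ms of
#' resting EMG noise, a stimulus at sample 501, and a biphasic
#' Gaussian-windowed MEP deflection with ~22 ms onset scaled to the drawn
#' peak-to-peak amplitude. With `waveforms = FALSE` the derived measures
#' (`mep_pp`, `pre_rms`, `pre_pp`) are emulated directly from the same
#' model, which is faster and is what the Monte-Carlo suites use.
#'
#' @param config An [emg_gen_config()].
#' @param waveforms Generate sampled waveforms (default TRUE)?
#' @return A list with `trials` (data.frame) and `waveforms` (matrix with
#'   trial-id rownames and `sampling_rate`/`stimulus_sample` attributes,
#'   or NULL).
#' @export
generate_emg_cohort <- function(config = emg_gen_config(), waveforms = TRUE) {
  stopifnot(inherits(config, "emg_gen_config"))
  with_seed(config$seed, generate_emg_cohort_impl(config, waveforms))
}

#' @noRd
generate_emg_cohort_impl <- function(config, waveforms) {
  cf <- config
  pulse_types <- c("single", "TS", "SICI", "ICF")
  grid <- expand.grid(
    trial = seq_len(cf$trials_per_block),
    pulse_type = pulse_types,
    muscle = cf$muscles,
    timepoint = cf$timepoints,
    condition = cf$conditions,
    participant = sprintf("P%02d", seq_len(cf$n_participants)),
    stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  u <- stats::rnorm(cf$n_participants, 0, cf$participant_sd)
  names(u) <- sprintf("P%02d", seq_len(cf$n_participants))
  mu <- cf$mep_log_mu + u[grid$participant]
  # conditioning shifts for paired-pulse measures
  mu <- mu + log(ifelse(grid$pulse_type == "SICI", cf$sici_ratio,
                 ifelse(grid$pulse_type == "ICF", cf$icf_ratio, 1)))
  # condition effect on corticospinal measures under verum
  eff <- ifelse(grid$condition == cf$conditions[1] &
                  grid$pulse_type %in% c("single", "TS"),
                cf$condition_effect[grid$timepoint], 1)
  amplitude <- exp(mu + log(eff) + stats::rnorm(n, 0, cf$mep_log_sigma))
  gt_outlier <- stats::runif(n) < cf$outlier_rate
  gt_precontraction <- stats::runif(n) < cf$precontraction_rate
  gt_noise <- stats::runif(n) < cf$noise_rate
  amplitude[gt_outlier] <- amplitude[gt_outlier] * cf$outlier_multiplier

  trials <- data.frame(
    trial_id = sprintf("%s_%s_%s_%s_%s_T%02d", grid$participant,
                       grid$condition, grid$timepoint, grid$muscle,
                       grid$pulse_type, grid$trial),
    participant = grid$participant, condition = grid$condition,
    timepoint = grid$timepoint, muscle = grid$muscle,
    pulse_type = grid$pulse_type, trial = grid$trial,
    amplitude = amplitude,
    gt_outlier = gt_outlier, gt_precontraction = gt_precontraction,
    gt_noise = gt_noise,
    stringsAsFactors = FALSE
  )

  if (waveforms) {
    store <- synth_waveforms(trials, cf)
    list(trials = trials, waveforms = store)
  } else {
    trials <- emulate_trial_measures(trials, cf)
    list(trials = trials, waveforms = NULL)
  }
}

#' @noRd
mep_template <- function(sampling_rate, post_samples) {
  t_ms <- (seq_len(post_samples) - 1) / sampling_rate * 1000
  # biphasic deflection: 50 Hz carrier under a Gaussian window centred 30 ms
  # post-stimulus (onset ~22 ms), spanning the 15-60 ms response window
  w <- sin(2 * pi * 50 * (t_ms - 30) / 1000) * exp(-((t_ms - 30)^2) / (2 * 5^2))
  w / (max(w) - min(w))  # unit peak-to-peak
}

#' @noRd
synth_waveforms <- function(trials, cf) {
  sr <- cf$sampling_rate
  n_pre <- round(0.100 * sr)
  n_post <- round(0.120 * sr)
  len <- n_pre + 1 + n_post
  stim <- n_pre + 1
  n <- nrow(trials)
  wf <- matrix(stats::rnorm(n * len, 0, cf$baseline_noise_sd), nrow = n)
  tmpl <- mep_template(sr, n_post)
  amp <- trials$amplitude
  amp[trials$gt_noise] <- amp[trials$gt_noise] * 0.1
  post_idx <- (stim + 1):len
  wf[, post_idx] <- wf[, post_idx] + outer(amp, tmpl)
  pc <- which(trials$gt_precontraction)
  if (length(pc)) {
    pre_idx <- 1:n_pre
    extra_sd <- cf$baseline_noise_sd *
      sqrt(cf$precontraction_rms_mult^2 - 1)
    wf[pc, pre_idx] <- wf[pc, pre_idx] +
      matrix(stats::rnorm(length(pc) * n_pre, 0, extra_sd),
             nrow = length(pc))
  }
  nz <- which(trials$gt_noise)
  if (length(nz)) {
    wf[nz, ] <- wf[nz, ] +
      matrix(stats::rnorm(length(nz) * len, 0, cf$noise_rms),
             nrow = length(nz))
  }
  rownames(wf) <- trials$trial_id
  attr(wf, "sampling_rate") <- sr
  attr(wf, "stimulus_sample") <- stim
  wf
}

#' @noRd
emulate_trial_measures <- function(trials, cf) {
  n <- nrow(trials)
  n_pre <- round(0.100 * cf$sampling_rate)
  # RMS of n_pre Gaussian samples: sd * sqrt(chi2_n / n)
  rms_mult <- ifelse(trials$gt_precontraction, cf$precontraction_rms_mult, 1)
  base_sd <- cf$baseline_noise_sd * rms_mult
  base_sd[trials$gt_noise] <- sqrt(base_sd[trials$gt_noise]^2 + cf$noise_rms^2)
  pre_rms <- base_sd * sqrt(stats::rchisq(n, n_pre) / n_pre)
  # expected peak-to-peak excursion of n_pre iid normals ~ 6.5 sd
  pre_pp <- pre_rms * 6.5
  mep_pp <- trials$amplitude
  mep_pp[trials$gt_noise] <- mep_pp[trials$gt_noise] * 0.1 + cf$noise_rms * 6
  trials$mep_pp <- mep_pp
  trials$pre_rms <- pre_rms
  trials$pre_pp <- pre_pp
  trials
}

#' Counterbalanced condition-order schedule
#'
#' Assigns each participant an ordered session pair (verum then sham, or
#' sham then verum) such that the two orders are as balanced as possible
#' (counts differ by at most 1), with the assignment permuted by seed.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed.
#' @param conditions Two condition labels.
#' @return A data.frame with `participant`, `session1`, `session2`.
#' @export
assign_condition_order <- function(n_participants, seed = 1L,
                                   conditions = c("verum", "sham")) {
  if (n_participants < 1) stop("need at least one participant")
  stopifnot(length(conditions) == 2)
  orders <- with_seed(seed, {
    base <- rep(c(1, 2), length.out = n_participants)
    sample(base)
  })
  data.frame(
    participant = sprintf("P%02d", seq_len(n_participants)),
    session1 = conditions[orders],
    session2 = conditions[3 - orders],
    stringsAsFactors = FALSE
  )
}

#' Gaussian white masking noise
#'
#' Auditory masking stimulus: i.i.d. standard-normal samples before any
#' amplitude scaling.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz (default 44100).
#' @param seed Integer seed.
#' @return Numeric vector of `round(duration_s * sampling_rate)` samples.
#' @export
generate_masking_noise <- function(duration_s, sampling_rate = 44100,
                                   seed = 1L) {
  if (duration_s <= 0 || sampling_rate <= 0) {
    stop("duration and sampling rate must be positive")
  }
  n <- round(duration_s * sampling_rate)
  with_seed(seed, stats::rnorm(n))
}
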