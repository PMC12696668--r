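#' Default cleaning rules for trial-level MEP preprocessing
#'
#' Thresholds governing trial exclusion: the Grubbs significance level for
#' amplitude outliers, the SD multiplier for the pre-contraction rule, the
#' length of the pre-stimulus window, the liberal RMS threshold above which
#' trials are screened for noise, and the minimum signal-to-noise ratio
#' (MEP peak-to-peak over pre-window peak-to-peak) below which a screened
#' trial is excluded as noise.
#'
#' @param grubbs_alpha Two-sided significance level for the iterative
#'   Grubbs test (default 0.05).
#' @param precontraction_k SD multiplier for the pre-contraction rule
#'   (default 2).
#' @param pre_window_ms Pre-stimulus window length in ms (default 100).
#' @param rms_inspect_threshold Pre-stimulus RMS (mV) above which a trial
#'   enters noise screening (default 0.045).
#' @param noise_snr_min Minimum MEP/pre-window peak-to-peak ratio for a
#'   screened trial to be retained (default 2).
#' @return A list of class `cleaning_rules`.
#' @export
cleaning_rules <- function(grubbs_alpha = 0.05, precontraction_k = 2,
                           pre_window_ms = 100, rms_inspect_threshold = 0.045,
                           noise_snr_min = 2) {
  vals <- c(grubbs_alpha, precontraction_k, pre_window_ms,
            rms_inspect_threshold, noise_snr_min)
  if (any(vals <= 0)) stop("all cleaning thresholds must be positive")
  structure(list(grubbs_alpha = grubbs_alpha,
                 precontraction_k = precontraction_k,
                 pre_window_ms = pre_window_ms,
                 rms_inspect_threshold = rms_inspect_threshold,
                 noise_snr_min = noise_snr_min),
            class = "cleaning_rules")
}

#' Peak-to-peak amplitude within a response window
#'
#' @param waveform Numeric vector of sampled voltage (mV).
#' @param window Integer indices (within the waveform) of the response
#'   window, e.g. 15-60 ms post-stimulus for hand-muscle MEPs.
#' @return max - min over the window; non-negative, invariant to DC offset
#'   and sign flip.
#' @export
compute_peak_to_peak <- function(waveform, window) {
  if (length(window) == 0) stop("empty response window")
  if (min(window) < 1 || max(window) > length(waveform)) {
    stop("response window outside waveform")
  }
  seg <- waveform[window]
  max(seg) - min(seg)
}

#' Root-mean-square of the pre-stimulus window
#'
#' RMS over exactly `pre_window_ms` milliseconds ending at (and excluding)
#' the stimulus sample.
#'
#' @param waveform Numeric vector (mV).
#' @param stimulus_sample Index of the stimulus artefact.
#' @param sampling_rate Sampling rate in Hz.
#' @param pre_window_ms Window length in ms (default 100).
#' @return RMS in mV.
#' @export
compute_pre_rms <- function(waveform, stimulus_sample, sampling_rate,
                            pre_window_ms = 100) {
  n_pre <- round(pre_window_ms / 1000 * sampling_rate)
  if (stimulus_sample - n_pre < 1) {
    stop("insufficient pre-stimulus samples for the requested window")
  }
  seg <- waveform[(stimulus_sample - n_pre):(stimulus_sample - 1)]
  sqrt(mean(seg^2))
}

#' Flag pre-contraction trials within a block
#'
#' A trial is flagged when its pre-stimulus RMS exceeds the block mean by
#' `k` standard deviations. The mean and SD are computed once over all
#' trials in the block, candidates included (non-iterative); SD uses the
#' n-1 denominator.
#'
#' @param pre_rms Numeric vector of pre-stimulus RMS values for one block.
#' @param k SD multiplier (default 2).
#' @return Logical vector of flags.
#' @export
flag_precontraction <- function(pre_rms, k = 2) {
  if (length(pre_rms) < 3) stop("pre-contraction rule needs at least 3 trials")
  m <- mean(pre_rms)
  s <- stats::sd(pre_rms)
  if (s == 0) return(rep(FALSE, length(pre_rms)))
  pre_rms > m + k * s
}

#' Critical value of the two-sided Grubbs test
#'
#' @param n Sample size.
#' @param alpha Two-sided significance level.
#' @return The critical value for G = max|x - mean|/sd.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Flag amplitude outliers with an iterative two-sided Grubbs test
#'
#' At each step the most extreme value (largest |x - mean|/sd) is tested
#' against the Grubbs critical value for the current sample size; if
#' rejected it is removed and the test repeats on the remainder until no
#' rejection occurs or fewer than 3 values remain.
#'
#' @param x Numeric vector of MEP amplitudes for one block (>= 3 values).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Logical vector of outlier flags aligned with `x`.
#' @export
flag_outliers_grubbs <- function(x, alpha = 0.05) {
  n0 <- length(x)
  if (n0 < 3) stop("Grubbs test needs at least 3 trials")
  flags <- rep(FALSE, n0)
  keep <- seq_len(n0)
  repeat {
    n <- length(keep)
    if (n < 3) break
    xv <- x[keep]
    s <- stats::sd(xv)
    if (s == 0) break
    dev <- abs(xv - mean(xv))
    i <- which.max(dev)
    g <- dev[i] / s
    if (g > grubbs_critical(n, alpha)) {
      flags[keep[i]] <- TRUE
      keep <- keep[-i]
    } else break
  }
  flags
}

#' Flag noise-dominated trials
#'
#' Deterministic surrogate for manual inspection of high-RMS trials: a
#' trial is flagged when its pre-stimulus RMS exceeds the liberal
#' inspection threshold AND the MEP peak-to-peak amplitude is less than
#' `noise_snr_min` times the pre-window peak-to-peak excursion, i.e. the
#' response cannot be sufficiently quantified above the background.
#'
#' @param pre_rms Pre-stimulus RMS (mV).
#' @param mep_pp MEP peak-to-peak amplitude (mV).
#' @param pre_pp Pre-stimulus-window peak-to-peak excursion (mV).
#' @param rules A [cleaning_rules()] object.
#' @return Logical flag(s).
#' @export
flag_noise <- function(pre_rms, mep_pp, pre_pp, rules = cleaning_rules()) {
  above <- pre_rms > rules$rms_inspect_threshold
  snr <- ifelse(pre_pp > 0, mep_pp / pre_pp, Inf)
  above & (snr < rules$noise_snr_min)
}

#' Clean a trial table: derive measures and apply exclusion rules per block
#'
#' Derived measures (`mep_pp`, `pre_rms`, `pre_pp`) are computed from the
#' waveform store if not already present, then the three exclusion rules
#' run per block (participant x condition x timepoint x muscle x
#' pulse_type) in the fixed order Grubbs -> pre-contraction -> noise.
#' Flags are attributed disjointly in that order: a trial already flagged
#' by an earlier rule is not counted again by a later one.
#'
#' @param trials Trial table (data.frame) as produced by
#'   [generate_emg_cohort()]; must carry `mep_pp`, `pre_rms`, `pre_pp`
#'   columns or be accompanied by `waveforms`.
#' @param waveforms Optional waveform matrix (rows = trials, rownames =
#'   trial ids) with attributes `sampling_rate` and `stimulus_sample`.
#' @param rules A [cleaning_rules()] object.
#' @param response_window_ms MEP response window in ms post-stimulus
#'   (default c(15, 60), bracketing hand-muscle MEP latencies).
#' @return The trial table with logical columns `outlier`,
#'   `precontraction`, `noise`, `excluded` (union of the three) added.
#' @export
clean_trials <- function(trials, waveforms = NULL, rules = cleaning_rules(),
                         response_window_ms = c(15, 60)) {
  if (!is.null(waveforms)) {
    trials <- derive_trial_measures(trials, waveforms, rules, response_window_ms)
  }
  need <- c("mep_pp", "pre_rms", "pre_pp")
  if (!all(need %in% names(trials))) {
    stop("trial table lacks derived measures; supply waveforms")
  }
  key <- interaction(trials$participant, trials$condition, trials$timepoint,
                     trials$muscle, trials$pulse_type, drop = TRUE)
  n <- nrow(trials)
  outlier <- precontraction <- noise <- rep(FALSE, n)
  for (b in levels(key)) {
    idx <- which(key == b)
    if (length(idx) >= 3) {
      outlier[idx] <- flag_outliers_grubbs(trials$mep_pp[idx], rules$grubbs_alpha)
      pc <- flag_precontraction(trials$pre_rms[idx], rules$precontraction_k)
      precontraction[idx] <- pc & !outlier[idx]
    }
    nz <- flag_noise(trials$pre_rms[idx], trials$mep_pp[idx],
                     trials$pre_pp[idx], rules)
    noise[idx] <- nz & !outlier[idx] & !precontraction[idx]
  }
  trials$outlier <- outlier
  trials$precontraction <- precontraction
  trials$noise <- noise
  trials$excluded <- outlier | precontraction | noise
  trials
}

#' Derive trial measures from stored waveforms
#'
#' @inheritParams clean_trials
#' @return The trial table with `mep_pp`, `pre_rms` and `pre_pp` columns.
#' @export
derive_trial_measures <- function(trials, waveforms, rules = cleaning_rules(),
                                  response_window_ms = c(15, 60)) {
  sr <- attr(waveforms, "sampling_rate")
  stim <- attr(waveforms, "stimulus_sample")
  if (is.null(sr) || is.null(stim)) {
    stop("waveform store lacks sampling_rate/stimulus_sample attributes")
  }
  w0 <- stim + round(response_window_ms[1] / 1000 * sr)
  w1 <- stim + round(response_window_ms[2] / 1000 * sr)
  window <- w0:w1
  n_pre <- round(rules$pre_window_ms / 1000 * sr)
  pre_idx <- (stim - n_pre):(stim - 1)
  rows <- match(trials$trial_id, rownames(waveforms))
  if (anyNA(rows)) stop("trial ids missing from waveform store")
  wf <- waveforms[rows, , drop = FALSE]
  resp <- wf[, window, drop = FALSE]
  pre <- wf[, pre_idx, drop = FALSE]
  trials$mep_pp <- apply(resp, 1, max) - apply(resp, 1, min)
  trials$pre_rms <- sqrt(rowMeans(pre^2))
  trials$pre_pp <- apply(pre, 1, max) - apply(pre, 1, min)
  trials
}

#' Exclusion percentages by rule
#'
#' @param trials Cleaned trial table from [clean_trials()].
#' @return Named numeric vector of percentages (outlier, precontraction,
#'   noise, total) over all trials.
#' @export
exclusion_summary <- function(trials) {
  n <- nrow(trials)
  c(outlier = 100 * sum(trials$outlier) / n,
    precontraction = 100 * sum(trials$precontraction) / n,
    noise = 100 * sum(trials$noise) / n,
    total = 100 * sum(trials$excluded) / n)
}

#' Square-root transform of MEP amplitudes
#'
#' Variance-stabilising transform for right-skewed trial-level amplitudes
#' ahead of linear mixed modelling.
#'
#' @param x Non-negative amplitudes (mV).
#' @return Element-wise square root.
#' @export
transform_amplitudes <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("amplitudes must be non-negative")
  sqrt(x)
}
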