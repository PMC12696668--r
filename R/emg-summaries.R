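#' Summarise cleaned trials into block-level excitability measures
#'
#' For each block (participant x condition x timepoint x muscle) the mean
#' amplitude over unexcluded trials is computed per pulse type, and the
#' paired-pulse measures are expressed as a ratio to the mean
#' test-stimulus (TS) amplitude: SICI ratio = mean(SICI)/mean(TS),
#' ICF ratio = mean(ICF)/mean(TS). A measure left empty after cleaning
#' yields `NA`, never a silent zero.
#'
#' @param trials Cleaned trial table from [clean_trials()].
#' @return A data.frame with one row per block: `participant`,
#'   `condition`, `timepoint`, `muscle`, trial counts (`n_total`,
#'   `n_excluded`), mean amplitudes per pulse type (`mean_single`,
#'   `mean_TS`, `mean_SICI`, `mean_ICF`) and `sici_ratio`, `icf_ratio`.
#' @export
summarize_blocks <- function(trials) {
  if (!"excluded" %in% names(trials)) {
    stop("trials must be cleaned first (see clean_trials)")
  }
  key <- interaction(trials$participant, trials$condition, trials$timepoint,
                     trials$muscle, drop = TRUE)
  rows <- lapply(levels(key), function(b) {
    idx <- which(key == b)
    tt <- trials[idx, ]
    keep <- tt[!tt$excluded, ]
    mean_of <- function(pt) {
      v <- keep$mep_pp[keep$pulse_type == pt]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    ms <- mean_of("single"); mts <- mean_of("TS")
    msici <- mean_of("SICI"); micf <- mean_of("ICF")
    data.frame(
      participant = tt$participant[1], condition = tt$condition[1],
      timepoint = tt$timepoint[1], muscle = tt$muscle[1],
      n_total = nrow(tt), n_excluded = sum(tt$excluded),
      mean_single = ms, mean_TS = mts, mean_SICI = msici, mean_ICF = micf,
      sici_ratio = if (!is.na(mts) && mts > 0) msici / mts else NA_real_,
      icf_ratio = if (!is.na(mts) && mts > 0) micf / mts else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Express post-sonication block means as a ratio to baseline
#'
#' Within each participant x condition x muscle cell, the mean amplitude
#' at each post timepoint is divided by the baseline mean (baseline
#' correction).
#'
#' @param summaries Block summary table from [summarize_blocks()].
#' @param measure Column to normalise (default `"mean_single"`; also
#'   sensible for `"sici_ratio"` and `"icf_ratio"`).
#' @param baseline Label of the baseline timepoint (default "Baseline").
#' @return A data.frame of post-timepoint rows with a `baseline_ratio`
#'   column. Errors if a cell lacks its baseline block.
#' @export
normalize_to_baseline <- function(summaries, measure = "mean_single",
                                  baseline = "Baseline") {
  if (!measure %in% names(summaries)) stop("unknown measure column: ", measure)
  key <- interaction(summaries$participant, summaries$condition,
                     summaries$muscle, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    ss <- summaries[idx, ]
    base <- ss[ss$timepoint == baseline, measure]
    if (length(base) != 1 || is.na(base)) {
      stop("missing baseline block for ", k)
    }
    post <- ss[ss$timepoint != baseline, ]
    post$baseline_ratio <- post[[measure]] / base
    post
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
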