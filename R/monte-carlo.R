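#' Monte-Carlo replication of the generator -> cleaning -> LMM chain
#'
#' Repeats the full single-pulse analysis chain over seeded synthetic
#' cohorts: generate a cohort, clean it, fit the trial-level linear mixed
#' model, and record the p-value of each fixed-effect term. Used to
#' check the type-I error of the pipeline under the null
#' (`condition_effect = 1`) and its power under an injected facilitation
#' preset.
#'
#' Replicates use the primary muscle only and the emulated-measures
#' generator path (no sampled waveforms), with the `cells` random
#' structure (uncorrelated by-participant effects spanning every
#' condition x timepoint cell contrast in sum coding), so that hundreds
#' of replicates run on one CPU while the fixed-effect tests keep
#' participant-level denominators.
#'
#' @param n_reps Number of replicates.
#' @param config An [emg_gen_config()]; replicate r uses seed
#'   `config$seed + r - 1`.
#' @param rules A [cleaning_rules()].
#' @param random Random-effects rung passed to [fit_trial_lmm()].
#' @return A data.frame with one row per replicate and columns `seed`,
#'   `p_condition`, `p_timepoint`, `p_interaction`.
#' @export
lmm_monte_carlo <- function(n_reps, config = emg_gen_config(muscles = "FDI"),
                            rules = cleaning_rules(), random = "cells") {
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    cohort <- generate_emg_cohort(cfg, waveforms = FALSE)
    tr <- clean_trials(cohort$trials, rules = rules)
    tr <- tr[tr$pulse_type == "single" & tr$muscle == cfg$muscles[1], ]
    fit <- fit_trial_lmm(tr, random = random)
    p <- fit$anova$p
    names(p) <- fit$anova$term
    data.frame(seed = cfg$seed,
               p_condition = unname(p["condition"]),
               p_timepoint = unname(p["timepoint"]),
               p_interaction = unname(p["condition:timepoint"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo targeting-accuracy replication
#'
#' Repeats the placement sampling of the acoustic-field generator over
#' seeded replicates and records the mean peak-to-omega Euclidean
#' distance and the per-axis one-sample t-test p-values across the
#' simulated cohort.
#'
#' @param n_reps Number of replicates.
#' @param config A [field_gen_config()]; replicate r uses seed
#'   `config$seed + r - 1`.
#' @param n_participants Cohort size per replicate.
#' @return A data.frame with `seed`, `mean_dist_omega`, `p_medial`,
#'   `p_anterior`, `p_superior`.
#' @export
targeting_monte_carlo <- function(n_reps, config = field_gen_config(),
                                  n_participants = 15) {
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    draw <- sample_focus_placements(cfg, n_participants)
    shifts <- sweep(draw$centre, 2, cfg$target_point, `-`)
    d <- sqrt(rowSums(shifts^2))
    tests <- group_axis_tests(shifts)
    data.frame(seed = cfg$seed, mean_dist_omega = mean(d),
               p_medial = tests$p[tests$axis == "medial"],
               p_anterior = tests$p[tests$axis == "anterior"],
               p_superior = tests$p[tests$axis == "superior"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
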