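#' Configuration of the end-to-end replication pipeline
#'
#' Bundles the generator configurations, cleaning rules, sonication
#' protocol and power specification, with a master seed that offsets the
#' component seeds so the whole run is reproducible from one integer.
#'
#' @param emg An [emg_gen_config()].
#' @param field A [field_gen_config()].
#' @param rules A [cleaning_rules()].
#' @param protocol A [sonication_protocol()].
#' @param power A [power_spec()].
#' @param seed Master seed; overrides the generator seeds.
#' @param waveforms Generate sampled waveforms and derive trial measures
#'   from them (TRUE), or use the emulated-measures path (FALSE).
#' @param out_dir Optional output directory for the JSON report and CSV
#'   intermediates.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(emg = emg_gen_config(),
                            field = field_gen_config(),
                            rules = cleaning_rules(),
                            protocol = sonication_protocol(0.020, 0.200, 80),
                            power = power_spec(eta_p2 = 0.602),
                            seed = 1L, waveforms = TRUE, out_dir = NULL) {
  seed <- as.integer(seed)
  emg$seed <- seed
  field$seed <- seed + 1000L
  structure(list(emg = emg, field = field, rules = rules,
                 protocol = protocol, power = power, seed = seed,
                 waveforms = waveforms, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full replication analysis on a synthetic cohort
#'
#' Orchestrates every stage: condition-order schedule, EMG cohort
#' generation, trial cleaning and exclusion accounting, block summaries
#' and baseline normalisation, paired baseline tests, the trial-level
#' linear mixed model and repeated-measures ANOVA (primary muscle),
#' dosimetry, per-participant acoustic-focus reports, group targeting
#' statistics, the targeting-accuracy subgroup analysis, the
#' overlap-vs-MEP-change regressions, and the sample-size computation.
#' Deterministic given the master seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `replication_report`. If
#'   `config$out_dir` is set, a JSON report plus CSV/NIfTI intermediates
#'   are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  muscle <- config$emg$muscles[1]

  schedule <- assign_condition_order(config$emg$n_participants,
                                     seed = config$seed,
                                     conditions = config$emg$conditions)

  cohort <- generate_emg_cohort(config$emg, waveforms = config$waveforms)
  trials <- clean_trials(cohort$trials, cohort$waveforms,
                         rules = config$rules)
  excl <- exclusion_summary(trials)

  summaries <- summarize_blocks(trials)
  ratios <- normalize_to_baseline(summaries)

  prim <- summaries[summaries$muscle == muscle, ]
  base <- prim[prim$timepoint == config$emg$timepoints[1], ]
  conds <- config$emg$conditions
  baseline_wide <- do.call(rbind, lapply(
    c(mep = "mean_single", sici = "sici_ratio", icf = "icf_ratio"),
    function(col) {
      w <- stats::reshape(base[, c("participant", "condition", col)],
                          direction = "wide", idvar = "participant",
                          timevar = "condition", v.names = col)
      names(w) <- sub(paste0("^", col, "\\."), "", names(w))
      w$measure <- col
      w
    }))
  baseline_tests <- baseline_paired_tests(baseline_wide, conds)

  single <- trials[trials$pulse_type == "single" & trials$muscle == muscle, ]
  lmm <- fit_trial_lmm(single)
  cells <- prim[, c("participant", "condition", "timepoint", "mean_single")]
  names(cells)[4] <- "value"
  anova_rm <- rm_anova(cells)

  fields <- generate_field_cohort(config$field, config$emg$n_participants)
  reports <- lapply(fields$fields, function(f) focus_report(f$pressure, fields$head))
  overlap_pct <- vapply(reports, `[[`, numeric(1), "overlap_pct")
  roi_peak <- vapply(reports, `[[`, numeric(1), "roi_peak_isppa")
  peak_isppa <- vapply(reports, `[[`, numeric(1), "peak_isppa")
  dist_omega <- vapply(reports, `[[`, numeric(1), "dist_omega")
  shifts <- t(vapply(reports, `[[`, numeric(3), "axis_shift"))
  axis_tests <- group_axis_tests(shifts)
  focus_map <- group_focus_map(lapply(reports, `[[`, "focus_mask"))

  dose <- dose_estimates(config$protocol,
                         isppa_tc_simulated = mean(peak_isppa))

  participants <- sprintf("P%02d", seq_len(config$emg$n_participants))
  mep_ratios <- ratios[ratios$muscle == muscle &
                         ratios$condition == conds[1],
                       c("participant", "timepoint", "baseline_ratio")]
  names(mep_ratios)[3] <- "mep_ratio"
  reg_dat <- merge(mep_ratios,
                   data.frame(participant = participants,
                              overlap_pct = overlap_pct))
  regression <- overlap_regression(reg_dat)
  subgroup <- accuracy_subgroup(overlap_pct, roi_peak, mep_ratios,
                                participants)

  n_required <- required_sample_size(config$power)

  report <- structure(list(
    provenance = list(package = "tusmep",
                      version = as.character(utils::packageVersion("tusmep")),
                      seed = config$seed, schema = "1.0"),
    schedule = schedule,
    exclusion_pct = excl,
    baseline_tests = baseline_tests,
    lmm = lmm,
    rm_anova = anova_rm,
    dose = dose,
    targeting = list(
      overlap_pct = overlap_pct, roi_peak_isppa = roi_peak,
      peak_isppa = peak_isppa, dist_omega = dist_omega,
      mean_dist_omega = mean(dist_omega), sd_dist_omega = stats::sd(dist_omega),
      n_overlapping = sum(overlap_pct > 0),
      axis_shift_mean = colMeans(shifts), axis_tests = axis_tests,
      transmission_pct = transmission_rate(mean(peak_isppa),
                                           config$protocol$isppa_fw)),
    focus_map = focus_map,
    subgroup = subgroup,
    regression = regression,
    n_required = n_required,
    summaries = summaries,
    baseline_ratios = ratios
  ), class = "replication_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.replication_report <- function(x, ...) {
  cat("TUS-TMS replication analysis report (seed", x$provenance$seed, ")\n\n")
  cat(sprintf("Exclusions: outliers %.2f%%, pre-contraction %.2f%%, noise %.2f%% (total %.2f%%)\n\n",
              x$exclusion_pct["outlier"], x$exclusion_pct["precontraction"],
              x$exclusion_pct["noise"], x$exclusion_pct["total"]))
  cat("Baseline paired tests:\n")
  print(x$baseline_tests, digits = 3)
  cat("\n")
  print(x$lmm)
  cat("\n")
  print(x$rm_anova)
  cat("\n")
  print(x$dose)
  tg <- x$targeting
  cat(sprintf("\nTargeting: peak-omega distance %.1f +/- %.1f mm; focus overlapped M1 ROI in %d/%d participants\n",
              tg$mean_dist_omega, tg$sd_dist_omega, tg$n_overlapping,
              length(tg$overlap_pct)))
  cat(sprintf("  transmission rate %.1f%%; overlap > %.0f%% in %d participants (%.0f%%)\n",
              tg$transmission_pct, x$subgroup$threshold, x$subgroup$n_above,
              x$subgroup$pct_above))
  cat(sprintf("  recommended sample size at the specified effect size: %d\n",
              x$n_required))
  invisible(x)
}

#' Write a replication report to disk
#'
#' Writes a JSON report (volumes excluded), the block summaries and
#' baseline ratios as CSV, and the group focus-count map as NIfTI.
#'
#' @param report A `replication_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    provenance = report$provenance,
    exclusion_pct = as.list(report$exclusion_pct),
    baseline_tests = report$baseline_tests,
    lmm = list(anova = report$lmm$anova,
               marginal_means = report$lmm$marginal_means,
               random_structure = report$lmm$random_structure,
               fallback_used = report$lmm$fallback_used),
    rm_anova = report$rm_anova$anova,
    dose = report$dose[setdiff(names(report$dose), "protocol")],
    protocol = unclass(report$dose$protocol),
    targeting = report$targeting[setdiff(names(report$targeting),
                                         "axis_tests")],
    axis_tests = report$targeting$axis_tests,
    subgroup = report$subgroup,
    regression = report$regression,
    n_required = report$n_required
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$summaries,
                   file.path(out_dir, "block_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$baseline_ratios,
                   file.path(out_dir, "baseline_ratios.csv"),
                   row.names = FALSE)
  write_volume(report$focus_map, file.path(out_dir, "focus_count_map.nii.gz"))
  invisible(out_dir)
}
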