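#' Paired baseline comparisons between conditions
#'
#' Two-sided paired t-tests of participant-level baseline values between
#' the two conditions, with Cohen's d for paired data
#' (mean(diff)/sd(diff)).
#'
#' @param x,y Participant-level values under each condition, paired by
#'   position.
#' @return A list with `t`, `df`, `p`, `d`, `mean_x`, `se_x`, `mean_y`,
#'   `se_y`, and a `degenerate` flag (TRUE when all differences are
#'   identical, so sd(diff) = 0).
#' @export
baseline_paired_test <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must be paired")
  if (length(x) < 2) stop("need at least two pairs")
  d <- x - y
  n <- length(d)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = if (mean(d) == 0) 1 else 0,
                d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                mean_x = mean(x), se_x = se(x),
                mean_y = mean(y), se_y = se(y), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       d = mean(d) / stats::sd(d),
       mean_x = mean(x), se_x = se(x), mean_y = mean(y), se_y = se(y),
       degenerate = FALSE)
}

#' Baseline test table over several measures
#'
#' @param baseline_wide A data.frame with columns `participant`,
#'   `measure`, and one column per condition holding participant-level
#'   baseline values.
#' @param conditions Length-2 character vector naming the condition
#'   columns (active first).
#' @return A data.frame with one row per measure: t, df, p, d and
#'   per-condition mean/SE.
#' @export
baseline_paired_tests <- function(baseline_wide,
                                  conditions = c("verum", "sham")) {
  stopifnot(all(conditions %in% names(baseline_wide)))
  rows <- lapply(split(baseline_wide, baseline_wide$measure), function(bb) {
    r <- baseline_paired_test(bb[[conditions[1]]], bb[[conditions[2]]])
    data.frame(measure = bb$measure[1], t = r$t, df = r$df, p = r$p, d = r$d,
               mean_verum = r$mean_x, se_verum = r$se_x,
               mean_sham = r$mean_y, se_sham = r$se_y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partial eta squared from an F statistic
#'
#' eta_p^2 = F * df1 / (F * df1 + df2).
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0).
#' @return Partial eta squared in `[0, 1)`.
#' @export
eta_from_F <- function(f, df1, df2) {
  if (any(df1 <= 0) || any(df2 <= 0)) stop("degrees of freedom must be positive")
  if (any(f < 0)) stop("F must be non-negative")
  f * df1 / (f * df1 + df2)
}

#' Cohen's f from partial eta squared
#'
#' f = sqrt(eta^2 / (1 - eta^2)).
#'
#' @param eta_p2 Partial eta squared in `[0, 1)`.
#' @return Cohen's f.
#' @export
cohens_f_from_eta <- function(eta_p2) {
  if (any(eta_p2 < 0) || any(eta_p2 >= 1)) stop("eta squared must lie in [0, 1)")
  sqrt(eta_p2 / (1 - eta_p2))
}

#' Trial-level linear mixed model of MEP amplitudes
#'
#' Fits square-root-transformed trial amplitudes with fixed effects for
#' condition, timepoint and their interaction, and by-participant random
#' effects. F-tests use the Satterthwaite approximation of degrees of
#' freedom. The random-effects ladder is, from richest to simplest:
#' `"maximal"` (intercept + condition, timepoint and interaction slopes
#' with full covariance), `"slopes"` (intercept + condition and timepoint
#' slopes), `"cells"` (uncorrelated by-participant random effects
#' spanning every condition x timepoint cell contrast in deviation (sum)
#' coding -- the cell-saturated structure of the maximal model without
#' its covariances), `"varcomp"` (uncorrelated variance components for
#' participant, participant x condition, participant x timepoint and
#' participant x block), `"condition"` (intercept + condition slope),
#' `"intercept"`. When a fit errors or fails to converge the next rung is
#' tried and the fallback is recorded in the result. Singular fits are
#' kept (boundary estimates are expected when a variance component is
#' truly zero).
#'
#' @param trials Cleaned trial table; rows with `excluded == TRUE` are
#'   dropped. Must contain `amplitude` (or `mep_pp`), `participant`,
#'   `condition`, `timepoint`.
#' @param random Starting rung of the random-effects ladder.
#' @param response Column holding the raw amplitude (default `"mep_pp"`,
#'   falling back to `"amplitude"`).
#' @return An object of class `tusmep_lmm`: list with `anova`
#'   (data.frame: term, F, df1, df2, p, eta_p2), `marginal_means`
#'   (participant-weighted condition means with SE on the transformed
#'   scale), `random_structure`, `fallback_used`, and `model`.
#' @export
fit_trial_lmm <- function(trials,
                          random = c("maximal", "slopes", "cells",
                                     "varcomp", "condition", "intercept"),
                          response = NULL) {
  random <- match.arg(random)
  if (is.null(response)) {
    response <- if ("mep_pp" %in% names(trials)) "mep_pp" else "amplitude"
  }
  if ("excluded" %in% names(trials)) trials <- trials[!trials$excluded, ]
  if (length(unique(trials$participant)) < 2) {
    stop("need at least two participants")
  }
  dat <- data.frame(
    y = transform_amplitudes(trials[[response]]),
    participant = factor(trials$participant),
    condition = factor(trials$condition),
    timepoint = factor(trials$timepoint,
                       levels = unique(trials$timepoint))
  )
  zc <- stats::model.matrix(
    ~ condition * timepoint, dat,
    contrasts.arg = list(condition = "contr.sum",
                         timepoint = "contr.sum"))[, -1, drop = FALSE]
  colnames(zc) <- paste0("z", seq_len(ncol(zc)))
  dat <- cbind(dat, zc)
  ladder <- c("maximal", "slopes", "cells", "varcomp", "condition",
              "intercept")
  ladder <- ladder[seq(match(random, ladder), length(ladder))]
  re_term <- c(
    maximal = "(1 + condition * timepoint | participant)",
    slopes = "(1 + condition + timepoint | participant)",
    cells = paste(c("(1 | participant)",
                    sprintf("(0 + z%d | participant)",
                            seq_len(ncol(zc)))), collapse = " + "),
    varcomp = paste("(1 | participant) + (1 | participant:condition) +",
                    "(1 | participant:timepoint) +",
                    "(1 | participant:condition:timepoint)"),
    condition = "(1 + condition | participant)",
    intercept = "(1 | participant)")
  fit <- NULL; used <- NULL
  for (rung in ladder) {
    fml <- stats::as.formula(paste("y ~ condition * timepoint +", re_term[rung]))
    res <- tryCatch({
      m <- suppressWarnings(suppressMessages(
        lmerTest::lmer(fml, data = dat,
                       control = lme4::lmerControl(optimizer = "bobyqa"))
      ))
      msgs <- unlist(m@optinfo$conv$lme4$messages)
      if (any(grepl("failed to converge", msgs))) NULL else m
    }, error = function(e) NULL)
    if (!is.null(res)) { fit <- res; used <- rung; break }
  }
  if (is.null(fit)) stop("linear mixed model failed to converge at every rung")
  at <- stats::anova(fit, type = 3)
  tab <- data.frame(term = rownames(at), F = at[["F value"]],
                    df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                    p = at[["Pr(>F)"]], stringsAsFactors = FALSE)
  tab$eta_p2 <- eta_from_F(tab$F, tab$df1, tab$df2)
  pm <- stats::aggregate(y ~ participant + condition, dat, mean)
  mm <- do.call(rbind, lapply(split(pm, pm$condition), function(g) {
    data.frame(condition = g$condition[1], mean = mean(g$y),
               se = stats::sd(g$y) / sqrt(nrow(g)), stringsAsFactors = FALSE)
  }))
  rownames(mm) <- NULL
  structure(list(anova = tab, marginal_means = mm,
                 random_structure = used,
                 fallback_used = used != random, model = fit),
            class = "tusmep_lmm")
}

#' @export
print.tusmep_lmm <- function(x, ...) {
  cat("Trial-level linear mixed model (Satterthwaite df)\n")
  cat(sprintf("  random effects: %s%s\n", x$random_structure,
              if (x$fallback_used) " (fallback)" else ""))
  tab <- x$anova
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-20s F(%g, %.1f) = %.3f, p = %.3g, eta_p2 = %.3f\n",
                tab$term[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i],
                tab$eta_p2[i]))
  }
  for (i in seq_len(nrow(x$marginal_means))) {
    cat(sprintf("  %s: M = %.3f, SE = %.3f (sqrt scale)\n",
                x$marginal_means$condition[i], x$marginal_means$mean[i],
                x$marginal_means$se[i]))
  }
  invisible(x)
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject condition x timepoint ANOVA on participant-level
#' cell means (raw scale, no square-root correction), via the
#' multivariate linear model route. Reports uncorrected F tests,
#' Greenhouse-Geisser epsilon, corrected degrees of freedom and corrected
#' p-values, and SS-based partial eta squared.
#'
#' @param cells A data.frame with columns `participant`, `condition`,
#'   `timepoint`, `value`; every participant must have every
#'   condition x timepoint cell exactly once.
#' @return An object of class `tusmep_rm_anova`: a data.frame `anova`
#'   with term, F, df1, df2, p, gg_epsilon, df1_gg, df2_gg, p_gg, eta_p2.
#' @export
rm_anova <- function(cells) {
  need <- c("participant", "condition", "timepoint", "value")
  stopifnot(all(need %in% names(cells)))
  cells$condition <- factor(cells$condition)
  cells$timepoint <- factor(cells$timepoint, levels = unique(cells$timepoint))
  # build participant x (condition x timepoint) matrix explicitly
  conds <- levels(cells$condition); tps <- levels(cells$timepoint)
  parts <- unique(cells$participant)
  Y <- matrix(NA_real_, nrow = length(parts),
              ncol = length(conds) * length(tps))
  design <- expand.grid(timepoint = tps, condition = conds,
                        stringsAsFactors = FALSE)
  for (j in seq_len(nrow(design))) {
    sel <- cells$condition == design$condition[j] &
      cells$timepoint == design$timepoint[j]
    sub <- cells[sel, ]
    Y[, j] <- sub$value[match(parts, sub$participant)]
  }
  if (anyNA(Y)) stop("missing condition x timepoint cells")
  mlm <- stats::lm(Y ~ 1)
  idata <- data.frame(condition = factor(design$condition, levels = conds),
                      timepoint = factor(design$timepoint, levels = tps))
  aov_res <- car::Anova(mlm, idata = idata,
                        idesign = ~ condition * timepoint, type = 3)
  s <- suppressWarnings(summary(aov_res, multivariate = FALSE))
  ut <- s$univariate.tests
  terms <- setdiff(rownames(ut), "(Intercept)")
  adj <- s$pval.adjustments
  rows <- lapply(terms, function(tm) {
    ss <- ut[tm, "Sum Sq"]; sse <- ut[tm, "Error SS"]
    df1 <- ut[tm, "num Df"]; df2 <- ut[tm, "den Df"]
    fval <- ut[tm, "F value"]; pval <- ut[tm, "Pr(>F)"]
    eps <- 1; pgg <- pval
    if (!is.null(adj) && tm %in% rownames(adj) &&
        is.finite(adj[tm, "GG eps"])) {
      eps <- adj[tm, "GG eps"]
      pgg <- adj[tm, "Pr(>F[GG])"]
    }
    if (!is.finite(fval)) {  # 0/0: no effect and no error variance
      fval <- 0; pval <- 1; pgg <- 1; eps <- 1
    }
    data.frame(term = tm, F = fval, df1 = df1, df2 = df2,
               p = pval, gg_epsilon = eps,
               df1_gg = df1 * eps, df2_gg = df2 * eps, p_gg = pgg,
               eta_p2 = if (ss + sse > 0) ss / (ss + sse) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(anova = out), class = "tusmep_rm_anova")
}

#' @export
print.tusmep_rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  tab <- x$anova
  for (i in seq_len(nrow(tab))) {
    cat(sprintf(
      "  %-20s F(%.1f, %.1f) = %.3f, p(GG) = %.3g, eta_p2 = %.3f\n",
      tab$term[i], tab$df1_gg[i], tab$df2_gg[i], tab$F[i], tab$p_gg[i],
      tab$eta_p2[i]))
  }
  invisible(x)
}

#' Per-timepoint regression of MEP change on targeting accuracy
#'
#' Ordinary least squares of the baseline-normalised MEP ratio on the
#' percentage acoustic-focus overlap with the M1 ROI, fitted separately
#' at each post timepoint.
#'
#' @param data A data.frame with columns `participant`, `timepoint`,
#'   `overlap_pct`, `mep_ratio`.
#' @return A data.frame with one row per timepoint: slope, se, t, df, p.
#' @export
overlap_regression <- function(data) {
  need <- c("timepoint", "overlap_pct", "mep_ratio")
  stopifnot(all(need %in% names(data)))
  rows <- lapply(split(data, data$timepoint), function(dd) {
    if (nrow(dd) < 3) stop("need at least three participants per timepoint")
    if (stats::sd(dd$overlap_pct) == 0) stop("overlap percentage is constant")
    fit <- stats::lm(mep_ratio ~ overlap_pct, data = dd)
    cf <- summary(fit)$coefficients
    data.frame(timepoint = dd$timepoint[1], slope = cf[2, 1], se = cf[2, 2],
               t = cf[2, 3], df = fit$df.residual, p = cf[2, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subgroup analysis by targeting accuracy
#'
#' Partitions participants by whether the focus/ROI overlap exceeds a
#' threshold and summarises each subgroup: size, mean and SD of the ROI
#' peak intensity, and mean baseline-normalised MEP ratio per timepoint.
#'
#' @param overlap_pct Per-participant overlap percentages.
#' @param roi_peak_isppa Per-participant ROI peak intensities (W/cm2).
#' @param mep_ratios A data.frame with `participant`, `timepoint`,
#'   `mep_ratio`; participants ordered as in `overlap_pct` via the
#'   `participants` argument.
#' @param participants Participant ids aligned with `overlap_pct`.
#' @param threshold Overlap threshold in percent (default 20).
#' @return A list with `threshold`, `n_above`, `n_total`,
#'   `pct_above`, `roi_peak_mean`, `roi_peak_sd` (above-threshold
#'   subgroup), and `mep_by_timepoint` (data.frame: timepoint, subgroup,
#'   n, mean_ratio). Empty subgroups are reported as empty, not errors.
#' @export
accuracy_subgroup <- function(overlap_pct, roi_peak_isppa, mep_ratios,
                              participants, threshold = 20) {
  above <- overlap_pct > threshold
  ids_above <- participants[above]
  mep_ratios$subgroup <- ifelse(mep_ratios$participant %in% ids_above,
                                "above", "below")
  by_tp <- do.call(rbind, lapply(
    split(mep_ratios, list(mep_ratios$timepoint, mep_ratios$subgroup),
          drop = TRUE),
    function(g) data.frame(timepoint = g$timepoint[1],
                           subgroup = g$subgroup[1], n = nrow(g),
                           mean_ratio = mean(g$mep_ratio),
                           stringsAsFactors = FALSE)))
  if (!is.null(by_tp)) rownames(by_tp) <- NULL
  list(threshold = threshold,
       n_above = sum(above), n_total = length(above),
       pct_above = 100 * mean(above),
       roi_peak_mean = if (any(above)) mean(roi_peak_isppa[above]) else NA_real_,
       roi_peak_sd = if (sum(above) > 1) stats::sd(roi_peak_isppa[above])
                     else NA_real_,
       mep_by_timepoint = by_tp)
}
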