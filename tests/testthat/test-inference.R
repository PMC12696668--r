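test_that("paired baseline tests reproduce closed-form values", {
  x <- c(1, 2, 3, 4, 5)
  r0 <- baseline_paired_test(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$d, 0)

  rd <- baseline_paired_test(c(2, 3, 4), c(1, 2, 3))  # diffs all 1
  expect_true(rd$degenerate)

  y <- x - c(0.2, -0.1, 0.3, 0.0, 0.1)
  r <- baseline_paired_test(x, y)
  expect_equal(r$t, 0.1 / (sd(c(0.2, -0.1, 0.3, 0.0, 0.1)) / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(r$t, 1.4142, tolerance = 1e-4)
  expect_equal(r$p, 0.230, tolerance = 1e-3)
  expect_equal(r$d, r$t / sqrt(5), tolerance = 1e-12)
  expect_error(baseline_paired_test(1:3, 1:4), "paired")
})

test_that("effect-size conversions are exact", {
  expect_equal(eta_from_F(21.19, 2, 28), 0.602, tolerance = 5e-4)
  expect_equal(eta_from_F(0, 3, 14), 0)
  expect_equal(eta_from_F(1, 1, 10), 1 / 11)
  expect_error(eta_from_F(1, 0, 10), "positive")

  expect_equal(cohens_f_from_eta(0), 0)
  expect_equal(cohens_f_from_eta(0.5), 1)
  expect_equal(cohens_f_from_eta(0.602), 1.2299, tolerance = 1e-4)
  expect_error(cohens_f_from_eta(1), "\\[0, 1\\)")
})

test_that("repeated-measures ANOVA matches the sum-of-squares oracle", {
  set.seed(21)
  cells <- expand.grid(participant = paste0("P", 1:6),
                       condition = c("verum", "sham"),
                       timepoint = c("Baseline", "T5"),
                       stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells), 1, 0.3) +
    ifelse(cells$condition == "verum" & cells$timepoint == "T5", 0.4, 0)
  fit <- rm_anova(cells)
  orc <- rm_anova_oracle(cells)
  tab <- fit$anova
  expect_equal(tab$F[tab$term == "condition"], orc$F_condition,
               tolerance = 1e-8)
  expect_equal(tab$F[tab$term == "timepoint"], orc$F_timepoint,
               tolerance = 1e-8)
  expect_equal(tab$F[tab$term == "condition:timepoint"], orc$F_interaction,
               tolerance = 1e-8)
  # SS-based partial eta squared equals the F/df reconstruction
  expect_equal(tab$eta_p2, eta_from_F(tab$F, tab$df1, tab$df2),
               tolerance = 1e-8)
  expect_equal(tab$eta_p2[tab$term == "condition"], orc$eta_condition,
               tolerance = 1e-8)
})

test_that("rm-ANOVA handles flat condition effects and reports GG epsilon", {
  cells <- expand.grid(participant = paste0("P", 1:5),
                       condition = c("verum", "sham"),
                       timepoint = c("Baseline", "T5", "T30", "T60"),
                       stringsAsFactors = FALSE)
  # participant offsets only: no condition/timepoint effect at all
  cells$value <- as.numeric(factor(cells$participant))
  fit <- rm_anova(cells)
  expect_equal(fit$anova$F, rep(0, 3), tolerance = 1e-10)
  set.seed(5)
  cells$value <- cells$value + rnorm(nrow(cells), 0, 0.5)
  fit2 <- rm_anova(cells)$anova
  tp <- fit2[fit2$term == "timepoint", ]
  expect_gte(tp$gg_epsilon, 1 / 3)   # lower bound 1/(m-1)
  expect_lte(tp$gg_epsilon, 1)
  expect_equal(tp$df1_gg, 3 * tp$gg_epsilon)
  expect_error(rm_anova(cells[-1, ]), "missing")
})

test_that("trial-level LMM recovers an injected multiplicative effect", {
  ratios <- sapply(1:5, function(s) {
    eff <- c(Baseline = 1.5, T5 = 1.5, T30 = 1.5, T60 = 1.5)
    cfg <- emg_gen_config(muscles = "FDI", condition_effect = eff, seed = s)
    co <- generate_emg_cohort(cfg, waveforms = FALSE)
    tr <- clean_trials(co$trials)
    fit <- fit_trial_lmm(tr[tr$pulse_type == "single", ], random = "varcomp")
    mm <- fit$marginal_means
    (mm$mean[mm$condition == "verum"] / mm$mean[mm$condition == "sham"])^2
  })
  expect_equal(mean(ratios), 1.5, tolerance = 0.1)
})

test_that("LMM reports Satterthwaite tables and falls back when singular fits fail", {
  cfg <- small_emg_config(seed = 2)
  co <- generate_emg_cohort(cfg, waveforms = FALSE)
  tr <- clean_trials(co$trials)
  fit <- fit_trial_lmm(tr[tr$pulse_type == "single", ], random = "varcomp")
  expect_s3_class(fit, "tusmep_lmm")
  expect_setequal(fit$anova$term,
                  c("condition", "timepoint", "condition:timepoint"))
  expect_true(all(fit$anova$p >= 0 & fit$anova$p <= 1))
  expect_true(all(fit$anova$df2 > 0))
  expect_equal(fit$anova$eta_p2,
               eta_from_F(fit$anova$F, fit$anova$df1, fit$anova$df2))
  expect_output(print(fit), "Satterthwaite")
  expect_error(fit_trial_lmm(tr[tr$participant == "P01", ]),
               "two participants")
})

test_that("repeated-measures power is monotone and equals alpha at f = 0", {
  sp0 <- power_spec(f = 0)
  expect_equal(rm_anova_power(sp0, 10), 0.05, tolerance = 1e-9)
  sp <- power_spec(eta_p2 = 0.3)
  pows <- sapply(seq(4, 40, by = 2), rm_anova_power, spec = sp)
  expect_true(all(diff(pows) >= -1e-12))
  for (fam in c("between", "within", "interaction")) {
    spf <- power_spec(f = 0.25, family = fam)
    p1 <- rm_anova_power(spf, 20)
    p2 <- rm_anova_power(power_spec(f = 0.4, family = fam), 20)
    expect_gt(p2, p1)
  }
  expect_error(rm_anova_power(sp, 2), "exceed")
})

test_that("the recommended sample size brackets the power target", {
  sp <- power_spec(eta_p2 = 0.602, family = "between")
  n <- required_sample_size(sp)
  expect_equal(n, 6)
  expect_gte(rm_anova_power(sp, n), 0.8)
  expect_lt(rm_anova_power(sp, n - sp$n_groups), 0.8)
  # tiny effect: monotone sanity bound
  expect_gte(required_sample_size(power_spec(f = 0.1)), 100)
  # degenerate target at alpha is reached at the smallest balanced N
  spa <- power_spec(f = 0.5, power_target = 0.051)
  expect_equal(required_sample_size(spa), 4)
})

test_that("overlap regression recovers exact linear relationships", {
  d <- data.frame(participant = paste0("P", 1:10),
                  timepoint = "T5",
                  overlap_pct = seq(0, 90, by = 10))
  d$mep_ratio <- 2 * d$overlap_pct
  r <- overlap_regression(d)
  expect_equal(r$slope, 2, tolerance = 1e-10)
  d$mep_ratio <- 1
  expect_equal(overlap_regression(d)$slope, 0, tolerance = 1e-10)
  d$overlap_pct <- 5
  expect_error(overlap_regression(d), "constant")

  # independent draws: the slope CI covers zero about 95% of the time
  set.seed(99)
  cover <- replicate(60, {
    dd <- data.frame(participant = paste0("P", 1:15), timepoint = "T5",
                     overlap_pct = runif(15, 0, 60),
                     mep_ratio = rnorm(15, 1, 0.2))
    rr <- overlap_regression(dd)
    abs(rr$slope) < qt(0.975, rr$df) * rr$se
  })
  expect_gte(mean(cover), 0.85)
})

test_that("accuracy subgroup partitions by the overlap threshold", {
  mr <- expand.grid(participant = paste0("P", 1:3), timepoint = c("T5", "T30"),
                    stringsAsFactors = FALSE)
  mr$mep_ratio <- 1
  sg <- accuracy_subgroup(c(10, 25, 30), c(0.5, 1.0, 1.2), mr,
                          paste0("P", 1:3), threshold = 20)
  expect_equal(sg$n_above, 2)
  expect_equal(sg$roi_peak_mean, 1.1)
  sg0 <- accuracy_subgroup(c(0, 0, 0), c(1, 1, 1), mr, paste0("P", 1:3))
  expect_equal(sg0$n_above, 0)
  expect_true(is.na(sg0$roi_peak_mean))
  sgall <- accuracy_subgroup(c(10, 25, 30), c(1, 1, 1), mr, paste0("P", 1:3),
                             threshold = 0)
  expect_equal(sgall$n_above, 3)
})
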