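#' Specification for repeated-measures ANOVA power analysis
#'
#' Parameters of the noncentral-F power computation for a g-group,
#' m-measurement repeated-measures design, following the conventions of
#' the G*Power repeated-measures module. The effect size may be given as
#' partial eta squared (converted to Cohen's f) or as f directly.
#'
#' @param eta_p2 Partial eta squared (used if `f` is NULL).
#' @param f Cohen's f; overrides `eta_p2` when given.
#' @param alpha Type-I error rate (default 0.05).
#' @param power_target Target power (default 0.8).
#' @param n_groups Number of between-subject groups g (default 2).
#' @param n_measurements Number of repeated measurements m (default 4).
#' @param rho_rm Correlation among repeated measures (default 0.5).
#' @param epsilon Nonsphericity correction in (0, 1] (default 1).
#' @param family Which repeated-measures effect the power refers to:
#'   `"between"` (between-group main effect), `"within"` (within-subject
#'   main effect) or `"interaction"`. The `"between"` family is the one
#'   that reproduces classic sample-size recommendations for
#'   between-condition effects on repeated measures.
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(eta_p2 = NULL, f = NULL, alpha = 0.05,
                       power_target = 0.8, n_groups = 2,
                       n_measurements = 4, rho_rm = 0.5, epsilon = 1,
                       family = c("between", "within", "interaction")) {
  family <- match.arg(family)
  if (is.null(f)) {
    if (is.null(eta_p2)) stop("supply eta_p2 or f")
    f <- cohens_f_from_eta(eta_p2)
  }
  if (alpha <= 0 || alpha >= 1 || power_target <= 0 || power_target >= 1) {
    stop("alpha and power_target must lie in (0, 1)")
  }
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]")
  if (rho_rm < 0 || rho_rm >= 1) stop("rho_rm must lie in [0, 1)")
  structure(list(f = f, alpha = alpha, power_target = power_target,
                 n_groups = n_groups, n_measurements = n_measurements,
                 rho_rm = rho_rm, epsilon = epsilon, family = family),
            class = "power_spec")
}

#' Noncentral-F power of a repeated-measures ANOVA
#'
#' Implements the G*Power-style noncentrality and degrees of freedom for
#' the three repeated-measures effect families. With g groups, m
#' measurements, correlation rho among repeated measures, nonsphericity
#' epsilon and total sample size N:
#' \itemize{
#'   \item between: lambda = f^2 N m / (1 + (m-1) rho), df1 = g-1,
#'     df2 = N-g;
#'   \item within: lambda = f^2 N m epsilon / (1-rho),
#'     df1 = (m-1) epsilon, df2 = (N-g)(m-1) epsilon;
#'   \item interaction: as within but df1 = (g-1)(m-1) epsilon.
#' }
#' Power = P(F' > F_crit) with F' noncentral F(df1, df2, lambda).
#'
#' @param spec A [power_spec()].
#' @param n_total Total sample size N (> number of groups).
#' @return Power in (0, 1).
#' @export
rm_anova_power <- function(spec, n_total) {
  stopifnot(inherits(spec, "power_spec"))
  g <- spec$n_groups; m <- spec$n_measurements
  if (n_total <= g) stop("total N must exceed the number of groups")
  f2 <- spec$f^2; rho <- spec$rho_rm; eps <- spec$epsilon
  if (spec$family == "between") {
    lambda <- f2 * n_total * m / (1 + (m - 1) * rho)
    df1 <- g - 1
    df2 <- n_total - g
  } else {
    lambda <- f2 * n_total * m * eps / (1 - rho)
    df1 <- if (spec$family == "within") (m - 1) * eps else
      (g - 1) * (m - 1) * eps
    df2 <- (n_total - g) * (m - 1) * eps
  }
  fcrit <- stats::qf(1 - spec$alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimum sample size reaching the target power
#'
#' Smallest total N, stepping by the number of groups so groups stay
#' balanced, whose repeated-measures power reaches the target.
#'
#' @param spec A [power_spec()].
#' @param n_max Search ceiling (default 10000).
#' @return Total sample size N.
#' @export
required_sample_size <- function(spec, n_max = 10000) {
  stopifnot(inherits(spec, "power_spec"))
  g <- spec$n_groups
  for (n in seq(2 * g, n_max, by = g)) {
    if (rm_anova_power(spec, n) >= spec$power_target) return(n)
  }
  stop("target power not achievable below n_max")
}
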