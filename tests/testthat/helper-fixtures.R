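# Small reusable fixtures and independent oracles.

small_emg_config <- function(seed = 1L, ...) {
  emg_gen_config(n_participants = 4, trials_per_block = 10,
                 muscles = "FDI", seed = seed, ...)
}

# Independent iterative two-sided Grubbs oracle, written directly from the
# t-based critical-value definition.
grubbs_oracle <- function(x, alpha = 0.05) {
  flags <- rep(FALSE, length(x))
  idx <- seq_along(x)
  repeat {
    n <- length(idx)
    if (n < 3) break
    xv <- x[idx]
    s <- sd(xv)
    if (s == 0) break
    dev <- abs(xv - mean(xv))
    i <- which.max(dev)
    tcrit <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (dev[i] / s > gcrit) {
      flags[idx[i]] <- TRUE
      idx <- idx[-i]
    } else break
  }
  flags
}

# Brute-force sum-of-squares oracle for a fully within-subject two-way
# repeated-measures ANOVA (balanced, complete).
rm_anova_oracle <- function(cells) {
  cells$participant <- factor(cells$participant)
  cells$condition <- factor(cells$condition)
  cells$timepoint <- factor(cells$timepoint)
  n <- nlevels(cells$participant)
  a <- nlevels(cells$condition)
  b <- nlevels(cells$timepoint)
  gm <- mean(cells$value)
  pm <- tapply(cells$value, cells$participant, mean)
  am <- tapply(cells$value, cells$condition, mean)
  bm <- tapply(cells$value, cells$timepoint, mean)
  abm <- tapply(cells$value, list(cells$condition, cells$timepoint), mean)
  apm <- tapply(cells$value, list(cells$condition, cells$participant), mean)
  bpm <- tapply(cells$value, list(cells$timepoint, cells$participant), mean)
  ss_a <- n * b * sum((am - gm)^2)
  ss_b <- n * a * sum((bm - gm)^2)
  ss_ab <- n * sum((abm - matrix(am, a, b) -
                      matrix(bm, a, b, byrow = TRUE) + gm)^2)
  ss_err_a <- b * sum((apm - matrix(am, a, n) -
                         matrix(pm, a, n, byrow = TRUE) + gm)^2)
  ss_err_b <- a * sum((bpm - matrix(bm, b, n) -
                         matrix(pm, b, n, byrow = TRUE) + gm)^2)
  cell_fit <- array(0, c(a, b, n))
  for (i in 1:a) for (j in 1:b) for (k in 1:n) {
    cell_fit[i, j, k] <- abm[i, j] + apm[i, k] + bpm[j, k] -
      am[i] - bm[j] - pm[k] + gm
  }
  y <- array(NA_real_, c(a, b, n))
  for (r in seq_len(nrow(cells))) {
    y[as.integer(cells$condition[r]), as.integer(cells$timepoint[r]),
      as.integer(cells$participant[r])] <- cells$value[r]
  }
  ss_err_ab <- sum((y - cell_fit)^2)
  list(
    F_condition = (ss_a / (a - 1)) / (ss_err_a / ((a - 1) * (n - 1))),
    F_timepoint = (ss_b / (b - 1)) / (ss_err_b / ((b - 1) * (n - 1))),
    F_interaction = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_err_ab / ((a - 1) * (b - 1) * (n - 1))),
    eta_condition = ss_a / (ss_a + ss_err_a),
    eta_timepoint = ss_b / (ss_b + ss_err_b),
    eta_interaction = ss_ab / (ss_ab + ss_err_ab)
  )
}
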