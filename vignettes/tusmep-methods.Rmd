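---
title: "Models and methods behind tusmep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tusmep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tusmep)
```

## What the package analyses

`tusmep` implements the complete analysis chain of a double-blind
TUS–TMS corticospinal-excitability experiment: two sessions (verum and
sham ultrasound) per participant, motor-evoked potentials (MEPs)
recorded from hand muscles at baseline and 5, 30 and 60 minutes after
sonication, with single-pulse amplitude, short-interval intracortical
inhibition (SICI, 2 ms interstimulus interval) and intracortical
facilitation (ICF, 10 ms) as outcome measures, plus post-hoc acoustic
simulations that quantify where the ultrasound focus actually landed.

Because no participant data ship with the package, a seeded
synthetic-cohort generator produces inputs with the statistical
structure this design assumes. Every downstream stage — trial cleaning,
excitability summaries, dosimetry, focus metrics, mixed models, power
analysis — is exercised against that generator.

## The synthetic EMG cohort

Trial-level MEP peak-to-peak amplitudes are right-skewed, so the
generator draws them log-normally:

$$A_{it} = \exp\left(\mu + u_i + \log e_{c,\tau} + \sigma z_{it}\right),$$

with a participant-level random effect $u_i \sim N(0, 0.35^2)$, trial
noise $\sigma = 0.45$ on the log scale, and a per-timepoint
multiplicative condition effect $e_{c,\tau}$ applied to single-pulse and
test-stimulus amplitudes under verum. The default
$\mu = -0.114$ puts the grand baseline mean near 1.05 mV, matching the
~1 mV operating point of the SI_1mV procedure. SICI and ICF trials are
scaled by their conditioning ratios (defaults 0.45 and 1.3). The
default condition effect is 1 at every timepoint — the null — and
`original_study_effect()` provides the facilitation preset
(1.4x at T5/T30, 1.2x at T60) representative of the originally reported
excitatory protocol, used for power and recovery simulations.

The design is the study's: 15 participants, 2 conditions, 4 timepoints,
4 pulse types, 25 trials per block, three hand muscles (FDI primary),
5 kHz sampling. Waveforms are 220 ms traces: 100 ms of resting EMG
noise (SD 0.005 mV), a stimulus marker, and a biphasic Gaussian-windowed
deflection (onset ~22 ms, centred 30 ms post-stimulus) scaled to the
drawn amplitude. Only the peak-to-peak amplitude and the pre-stimulus
window feed the analysis, so no further electrophysiological realism is
attempted. With `waveforms = FALSE` the derived measures are emulated
directly from the same model (the pre-stimulus RMS is drawn from its
exact sampling distribution); the Monte-Carlo suites use this path.

Artefact trials are injected independently at the rates such studies
report: amplitude outliers (1.6%, amplitude times 8), pre-contraction
trials (1.8%, pre-stimulus RMS times 10), and noise-dominated trials
(0.55%, broadband contamination of 0.08 mV RMS with the MEP attenuated).
The injection magnitudes were fixed once so that a correctly implemented
filter bank recovers them with sensitivity at least 0.9 — they are meant
to be detectable artefacts, not adversarial ones. Ground-truth labels
travel in `gt_*` columns that the filters never read.

What the generator does **not** emulate: session-order effects,
amplitude drift within a block, muscle-to-muscle correlation,
participant-specific artefact propensity, or heavy-tailed residuals
beyond the log-normal. Passing tests therefore show that the analysis
machinery is correct under the stated model, not that it is robust to
every failure mode of real EMG.

## Trial cleaning

Cleaning runs per block (participant x condition x timepoint x muscle x
pulse type) in a fixed order, with disjoint attribution:

1. **Amplitude outliers** — iterative two-sided Grubbs test at
   alpha = 0.05 on the raw amplitudes: the most extreme value is tested
   against the critical value
   $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with
   $t = t_{\alpha/(2n),\,n-2}$, removed if rejected, and the test
   repeats. The iterative two-sided variant was chosen because blocks
   can contain more than one artefact and deviations occur in both
   directions; running it on raw (untransformed) amplitudes mirrors the
   convention of reporting exclusion percentages before any transform.
2. **Pre-contraction** — a trial is flagged when its 100 ms
   pre-stimulus RMS exceeds the block mean by two SDs. The mean and SD
   are computed once over all trials of the block, candidates included,
   exactly as the rule is usually stated; the rule is deliberately
   non-iterative.
3. **Noise** — manual inspection of high-RMS trials is replaced by a
   deterministic surrogate: flag when the pre-stimulus RMS exceeds the
   liberal 0.045 mV inspection threshold *and* the MEP peak-to-peak is
   less than twice the pre-window peak-to-peak excursion (the response
   cannot be quantified above background). Reproducibility requires
   removing the human step; both thresholds are exposed in
   `cleaning_rules()`.

A trial already flagged by an earlier rule is not re-attributed by a
later one, so exclusion percentages add up. In practice injected noise
trials are usually caught by the pre-contraction rule first (their
whole-trace contamination necessarily raises the pre-window RMS); they
are excluded either way, which is what matters downstream.

The MEP response window is 15–60 ms post-stimulus (configurable),
bracketing hand-muscle MEP latencies and the generator's deflection.

## Excitability summaries and inference

Block means are taken over unexcluded trials; SICI and ICF are ratios
to the mean test stimulus of the same block, and post-sonication means
are expressed as ratios to the baseline mean within participant x
condition x muscle. A measure emptied by cleaning propagates `NA`.

The trial-level linear mixed model uses square-root-transformed
amplitudes (variance stabilisation for right-skewed MEPs), fixed
effects condition x timepoint, by-participant random effects, and
Satterthwaite degrees of freedom for F tests. The random-structure
ladder runs maximal (full covariance of intercept and all slopes) →
slopes (condition + timepoint) → `cells` (uncorrelated by-participant
effects spanning every condition x timepoint cell contrast, in
deviation coding) → `varcomp` (uncorrelated variance components for
participant, participant x condition, participant x timepoint and
participant x block) → condition slope → intercept; a
fit that errors or fails to converge falls to the next rung and the
fallback is recorded in the result. Singular fits are retained:
boundary estimates are the expected outcome when a variance component
is truly zero.

Partial eta squared for every F test is reconstructed as
$F\,df_1/(F\,df_1+df_2)$, which on balanced data equals the SS-based
definition (a test verifies this against a brute-force sum-of-squares
oracle).

The repeated-measures ANOVA runs on raw participant-level cell means
through the multivariate-model route, reporting uncorrected and
Greenhouse–Geisser-corrected degrees of freedom and p-values. When both
effect and error sums of squares vanish (a constant table), F is
reported as 0 with p = 1 rather than 0/0.

The Monte-Carlo suites (`lmm_monte_carlo()`) run the full generator →
cleaning → LMM chain on the primary muscle at the `cells` rung. The
choice of random structure matters here more than one might expect:
per-block Grubbs trimming stabilises each block's retained sample while
leaving genuine selection noise in the block mean, so the within-block
residual variance understates the variance of the trimmed means. A
condition-slope-only model then inflates the timepoint and interaction
tests to ~0.11–0.15 type-I error, and even explicit block variance
components only bring the interaction back to ~0.08 (their Satterthwaite
denominators still borrow trial-level information). Structures whose
denominators live at the participant stratum behave correctly: the
repeated-measures ANOVA on cleaned cell means is exactly nominal
(~0.05), the maximal LMM is conservative (at ~19 s per fit), and the
`cells` structure — the maximal model's cell-saturated random effects
without their covariances, in deviation coding — is nominal
(condition ~0.03, timepoint ~0.04, interaction ~0.05) at ~1 s per fit.
The suites use 200 replicates of the 15-participant, 25-trial design —
the size chosen as a reasonable Monte-Carlo resolution for a 5% rate.

Power analysis implements the noncentral-F formulations of the
repeated-measures families. With $g$ groups, $m$ measurements,
repeated-measure correlation $\rho$ and nonsphericity $\varepsilon$:

- between: $\lambda = f^2 N m/(1+(m-1)\rho)$, $df_1 = g-1$, $df_2 = N-g$;
- within: $\lambda = f^2 N m\varepsilon/(1-\rho)$,
  $df_1 = (m-1)\varepsilon$, $df_2=(N-g)(m-1)\varepsilon$;
- interaction: as within, $df_1 = (g-1)(m-1)\varepsilon$.

For the published design parameters (partial eta squared 0.602, alpha
0.05, power 0.8, 2 groups, 4 measurements, correlation 0.5,
epsilon 1), only the **between** family reproduces the recommended
total sample size of 6 (power 0.810 at N = 6, 0.647 at N = 5); the
within and interaction families saturate by N = 4. The family is
therefore a documented switch in `power_spec()` with `"between"` as the
default. Sample-size search steps by the number of groups so group
sizes stay balanced.

## Dosimetry

All intensity arithmetic is centralised: intensities externally in
W/cm2, pressures in Pa (MPa only inside the mechanical index), with the
plane-wave pair $I = p^2/(2\rho c)$ and $p = \sqrt{2\rho c\,I\cdot10^4}$
($\rho$ = 1000 kg/m3, $c$ = 1500 m/s) exact inverses. The pulse train
(20 ms pulses every 200 ms for 80 s) yields PRF 5 Hz, 10% duty cycle,
400 pulses; `round()` guards the pulse count against float
representation. The transducer depth setting adds the coupling stack
(10 mm gel pad + 0.5 mm gel film) to the 33 mm target depth. The
conventional fixed derating multiplies the free-water intensity by
(1 − attenuation) with attenuation 0.75; the simulated in-situ
intensity gives the transmission rate directly. The mechanical index
uses the peak pressure from the plane-wave inversion of the in-situ
intensity ($p$ in MPa over $\sqrt{f_0\,\mathrm{MHz}}$), since reports
in this literature quote MI alongside in-situ intensity without stating
a separate pressure source; at 1.2 W/cm2 and 500 kHz this gives 0.268.

## Acoustic fields and focus metrics

The field generator realises each participant's simulated pressure
field as a separable Gaussian ellipsoid whose *intensity* full-width
half-maximum equals the configured 6 x 6 x 30 mm focus — the acoustic
solver itself is out of scope, and every focus metric depends only on
the intensity geometry. The world convention is RAS+ millimetres;
for the left-hemisphere target, medial = +x. The synthetic head is a
rectangular brain slab below an 8 mm scalp/skull shell, with the
omega-formation target at ~30 mm depth, the precentral gyral lip at
~18 mm (the lip depth is config-exposed since reports vary between ~15
and ~18 mm), and the 15 mm M1 ROI centred midway between the two so the
sphere covers both landmarks.

Focus placement is target + bias + jitter. The defaults encode the
dispersion observed when transducer placement follows the TMS hotspot:
anterior bias 10.5 mm with 14.2 mm SD; a small, highly consistent
medial bias (5 mm, SD 2.6 mm — the magnitude is not published, so it
was calibrated once to give a medial one-sample t near the reported
~7.4); and an inferior bias of −3 mm with SD 7 mm, which leaves the
inferior shift relative to the omega non-significant while the shift
relative to the shallower lip is strongly significant. Jitter is
truncated at 2 SD so foci stay inside the synthetic head. Peak in-situ
intensities are drawn at 1.20 ± 0.43 W/cm2 (floored at 5% of the
mean). Under these defaults the mean peak-to-omega distance over
simulated cohorts falls in the 15–27 mm band reported for this
targeting method.

The focus is the set of brain voxels at or above half the in-brain
intensity maximum — the threshold is inclusive, no connected-component
filtering is applied, and the focus is restricted to the brain mask so
that overlap percentages stay interpretable. Peak ties break at the
lowest linear voxel index. Overlap is the percentage of focus voxels
inside the ROI; axis shifts are tested per axis with two-sided
one-sample t-tests, a zero-variance axis with nonzero mean being
flagged and reported with p = 0.

One numerical caveat is deliberate: on a 1 mm grid with the focus
centred on a voxel, the half-maximum boundary falls exactly on voxel
centres and floating-point rounding can exclude that shell, biasing the
measured volume by ~5% for a 6 mm focus. The geometric validation
therefore samples at 0.5 mm, where the discretisation error is ~0.5%.

## The pipeline and its outputs

`run_pipeline()` chains every stage deterministically from one master
seed and returns a `replication_report` (printable; serialisable to
JSON + CSV + NIfTI with `write_report()`): exclusion percentages per
rule, the paired baseline test table, LMM and rm-ANOVA tables, dose
estimates with the simulated transmission rate, per-participant focus
metrics, group targeting statistics, the >20% overlap subgroup summary,
the overlap-vs-MEP-change regressions, and the sample-size
recommendation. `scripts/acceptance.R` re-runs this end to end and
writes the headline numbers as JSON.

## Known limitations

- The generator's between-participant variance components are chosen,
  not fitted — published group summaries do not identify them.
- The noise-trial surrogate rule is one reasonable formalisation of a
  manual step; its thresholds are exposed rather than validated.
- The synthetic head has no skull, so attenuation is injected as a
  distribution on peak intensity rather than computed from anatomy.
- Focus masks live on a shared grid; registration across native spaces
  is out of scope.
- The rm-ANOVA requires complete condition x timepoint cells per
  participant; incomplete designs are an error, not an imputation.
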