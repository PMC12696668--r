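#' Derive pulse-train descriptors from a sonication protocol
#'
#' A repetitive TUS protocol is described by the pulse duration (PD), the
#' pulse repetition interval (PRI) and the pulse train duration (PTD).
#' From these the pulse repetition frequency (PRF = 1/PRI), the duty cycle
#' (PD/PRI) and the total number of pulses (round(PTD/PRI)) follow exactly.
#'
#' @param pd Pulse duration in seconds (e.g. 0.020).
#' @param pri Pulse repetition interval in seconds (e.g. 0.200).
#' @param ptd Pulse train duration in seconds (e.g. 80).
#' @param f0 Fundamental frequency in Hz (default 500 kHz).
#' @param isppa_fw Free-water spatial-peak pulse-average intensity in
#'   W/cm2 (default 10).
#' @return An object of class `sonication_protocol`: a list with the
#'   inputs plus `prf` (Hz), `duty_cycle` (fraction) and `n_pulses`.
#' @examples
#' sonication_protocol(0.020, 0.200, 80)  # PRF 5 Hz, 10% duty cycle, 400 pulses
#' @export
sonication_protocol <- function(pd, pri, ptd, f0 = 500e3, isppa_fw = 10) {
  stopifnot(is.numeric(pd), is.numeric(pri), is.numeric(ptd))
  if (pd <= 0) stop("pulse duration must be positive")
  if (pd > pri) stop("pulse duration cannot exceed the pulse repetition interval")
  if (pri > ptd) stop("pulse repetition interval cannot exceed the train duration")
  if (f0 <= 0) stop("fundamental frequency must be positive")
  structure(list(
    pd = pd, pri = pri, ptd = ptd, f0 = f0, isppa_fw = isppa_fw,
    prf = 1 / pri,
    duty_cycle = pd / pri,
    n_pulses = round(ptd / pri)
  ), class = "sonication_protocol")
}

#' @export
print.sonication_protocol <- function(x, ...) {
  cat("Sonication protocol\n")
  cat(sprintf("  f0:          %.0f kHz\n", x$f0 / 1e3))
  cat(sprintf("  PD / PRI:    %.1f ms / %.1f ms\n", x$pd * 1e3, x$pri * 1e3))
  cat(sprintf("  PTD:         %.1f s\n", x$ptd))
  cat(sprintf("  PRF:         %g Hz\n", x$prf))
  cat(sprintf("  duty cycle:  %.1f%%\n", 100 * x$duty_cycle))
  cat(sprintf("  n pulses:    %d\n", x$n_pulses))
  cat(sprintf("  Isppa (fw):  %.2f W/cm2\n", x$isppa_fw))
  invisible(x)
}

#' Transducer depth setting for a coupled sonication target
#'
#' The depth programmed on the transducer power output (TPO) unit must
#' include the coupling stack between transducer face and scalp: gel pad
#' plus the thin film of ultrasound gel.
#'
#' @param target_depth Scalp-to-target depth in mm.
#' @param gel_pad Gel-pad thickness in mm (default 10).
#' @param gel_film Gel-film thickness in mm (default 0.5).
#' @return TPO depth setting in mm.
#' @examples
#' tpo_depth(33)  # 43.5
#' @export
tpo_depth <- function(target_depth, gel_pad = 10, gel_film = 0.5) {
  if (any(c(target_depth, gel_pad, gel_film) < 0)) {
    stop("depths and coupling thicknesses must be non-negative")
  }
  target_depth + gel_pad + gel_film
}

#' Acoustic constants for the plane-wave intensity approximation
#'
#' @param rho Medium density in kg/m3 (default 1000, soft tissue/water).
#' @param c Sound speed in m/s (default 1500).
#' @return A list with `rho` and `c`.
#' @export
acoustic_constants <- function(rho = 1000, c = 1500) {
  if (rho <= 0 || c <= 0) stop("acoustic constants must be positive")
  list(rho = rho, c = c)
}

#' Plane-wave intensity from pressure amplitude
#'
#' Pulse-average intensity under the plane-wave approximation
#' I = p^2 / (2 rho c), converted from W/m2 to W/cm2.
#'
#' @param p Pressure amplitude in Pa (scalar or array); must be >= 0.
#' @param constants Output of [acoustic_constants()].
#' @return Intensity in W/cm2, same shape as `p`.
#' @export
isppa_from_pressure <- function(p, constants = acoustic_constants()) {
  if (any(p < 0)) stop("pressure amplitude must be non-negative")
  p^2 / (2 * constants$rho * constants$c) / 1e4
}

#' Pressure amplitude from plane-wave intensity
#'
#' Inverse of [isppa_from_pressure()]: p = sqrt(2 rho c I * 1e4).
#'
#' @param isppa Intensity in W/cm2; must be >= 0.
#' @param constants Output of [acoustic_constants()].
#' @return Pressure amplitude in Pa.
#' @export
pressure_from_isppa <- function(isppa, constants = acoustic_constants()) {
  if (any(isppa < 0)) stop("intensity must be non-negative")
  sqrt(2 * constants$rho * constants$c * isppa * 1e4)
}

#' Fixed-attenuation transcranial intensity estimate
#'
#' The conventional derating applies a fixed fractional attenuation to the
#' free-water intensity: I_tc = I_fw * (1 - attenuation). A 75% skull
#' attenuation takes 10 W/cm2 free-water to 2.5 W/cm2 in situ.
#'
#' @param isppa_fw Free-water Isppa in W/cm2.
#' @param attenuation Fractional attenuation in `[0, 1)` (default 0.75).
#' @return Estimated transcranial Isppa in W/cm2.
#' @export
fixed_attenuation_estimate <- function(isppa_fw, attenuation = 0.75) {
  if (attenuation < 0 || attenuation >= 1) stop("attenuation must lie in [0, 1)")
  isppa_fw * (1 - attenuation)
}

#' Intensity transmission rate through the skull
#'
#' @param isppa_tc Transcranial (in-situ) Isppa in W/cm2.
#' @param isppa_fw Free-water Isppa in W/cm2; must be > 0.
#' @return Transmission rate in percent.
#' @export
transmission_rate <- function(isppa_tc, isppa_fw) {
  if (isppa_fw <= 0) stop("free-water intensity must be positive")
  100 * isppa_tc / isppa_fw
}

#' Mechanical index
#'
#' MI = peak negative pressure in MPa divided by the square root of the
#' fundamental frequency in MHz.
#'
#' @param p_neg_mpa Peak negative pressure in MPa; >= 0.
#' @param f0_mhz Fundamental frequency in MHz; > 0.
#' @return Dimensionless mechanical index.
#' @export
mechanical_index <- function(p_neg_mpa, f0_mhz) {
  if (f0_mhz <= 0) stop("frequency must be positive")
  if (any(p_neg_mpa < 0)) stop("peak negative pressure must be non-negative")
  p_neg_mpa / sqrt(f0_mhz)
}

#' Full dose-estimate report for a sonication protocol
#'
#' Combines the fixed-attenuation convention, a simulated (or measured)
#' in-situ intensity, the implied transmission rate, and the mechanical
#' index derived from the in-situ intensity through the plane-wave
#' inversion.
#'
#' @param protocol A [sonication_protocol()].
#' @param attenuation Fractional skull attenuation for the fixed estimate.
#' @param isppa_tc_simulated Simulated in-situ Isppa in W/cm2; `NA` if no
#'   simulation is available.
#' @param constants Output of [acoustic_constants()].
#' @return An object of class `dose_estimates`.
#' @export
dose_estimates <- function(protocol, attenuation = 0.75,
                           isppa_tc_simulated = NA_real_,
                           constants = acoustic_constants()) {
  stopifnot(inherits(protocol, "sonication_protocol"))
  fixed <- fixed_attenuation_estimate(protocol$isppa_fw, attenuation)
  trans <- if (is.na(isppa_tc_simulated)) NA_real_ else
    transmission_rate(isppa_tc_simulated, protocol$isppa_fw)
  ref_tc <- if (is.na(isppa_tc_simulated)) fixed else isppa_tc_simulated
  p_neg <- pressure_from_isppa(ref_tc, constants)
  mi <- mechanical_index(p_neg / 1e6, protocol$f0 / 1e6)
  structure(list(
    protocol = protocol,
    attenuation = attenuation,
    isppa_fw = protocol$isppa_fw,
    isppa_tc_fixed = fixed,
    isppa_tc_simulated = isppa_tc_simulated,
    transmission_pct = trans,
    peak_neg_pressure_mpa = p_neg / 1e6,
    mechanical_index = mi
  ), class = "dose_estimates")
}

#' @export
print.dose_estimates <- function(x, ...) {
  print(x$protocol)
  cat("Dose estimates\n")
  cat(sprintf("  Isppa fw:                 %.2f W/cm2\n", x$isppa_fw))
  cat(sprintf("  Isppa tc (%.0f%% atten.):  %.2f W/cm2\n",
              100 * x$attenuation, x$isppa_tc_fixed))
  if (!is.na(x$isppa_tc_simulated)) {
    cat(sprintf("  Isppa tc (simulated):     %.2f W/cm2\n", x$isppa_tc_simulated))
    cat(sprintf("  transmission rate:        %.1f%%\n", x$transmission_pct))
  }
  cat(sprintf("  peak negative pressure:   %.3f MPa\n", x$peak_neg_pressure_mpa))
  cat(sprintf("  mechanical index:         %.3f\n", x$mechanical_index))
  invisible(x)
}
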