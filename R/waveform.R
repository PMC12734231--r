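#' Left-ventricular volume waveform with E/A-structured filling
#'
#' Builds a smooth periodic volume curve V(t) over one heartbeat: a half-cosine
#' systolic ejection from EDV down to ESV, then a diastolic dV/dt made of an
#' E-wave and an A-wave (raised-cosine bumps) separated by a diastasis, with a
#' prescribed ratio of E to A peak dV/dt. Both filling waves integrate back to
#' EDV, so the waveform is exactly periodic. The diastasis occupies the part of
#' diastole left over by the two waves; since wave widths are fractions of the
#' diastolic duration, the diastasis shrinks in absolute terms as heart rate
#' rises and diastole shortens.
#'
#' @param EDV,ESV end-diastolic and end-systolic volume (mL), `EDV > ESV > 0`.
#' @param period heartbeat period T (s).
#' @param systolic_fraction fraction of the cycle spent in systole (0, 1).
#' @param e_a_ratio ratio of E-wave to A-wave peak dV/dt (> 0). Ignored when
#'   `waves = "merged"`.
#' @param waves `"ea"` for distinct E and A waves, `"merged"` for a single
#'   diastolic filling wave (high-rate phases where the waves fuse).
#' @param e_width_frac,a_width_frac widths of the E and A bumps as fractions of
#'   the diastolic duration.
#' @param margin_frac quiet margin after end-systole and before end-diastole,
#'   as a fraction of the diastolic duration.
#' @return An object of class `volume_waveform`: a list with vectorized
#'   functions `V(t)` and `dVdt(t)` (mL, mL/s; periodic in t), the systolic
#'   duration `t_es`, the analytic E/A peak values and times, the E-wave
#'   window, and the input parameters.
#' @examples
#' wf <- volume_waveform(90, 36, period = 60 / 76, systolic_fraction = 0.34,
#'                       e_a_ratio = 1.6)
#' wf$e_peak / wf$a_peak   # 1.6 by construction
#' @export
volume_waveform <- function(EDV, ESV, period, systolic_fraction,
                            e_a_ratio = 1.6, waves = c("ea", "merged"),
                            e_width_frac = 0.42, a_width_frac = 0.34,
                            margin_frac = 0.02) {
  waves <- match.arg(waves)
  if (!(EDV > ESV && ESV > 0)) stop("need EDV > ESV > 0")
  if (!(period > 0)) stop("period must be positive")
  if (!(systolic_fraction > 0 && systolic_fraction < 1))
    stop("systolic_fraction must lie in (0, 1)")
  if (waves == "ea" && !(e_a_ratio > 0)) stop("e_a_ratio must be positive")

  SV <- EDV - ESV
  ts <- systolic_fraction * period
  td <- period - ts

  if (waves == "ea") {
    wE <- e_width_frac * td
    wA <- a_width_frac * td
    gap <- td * (1 - 2 * margin_frac) - wE - wA
    if (gap < 0)
      stop(sprintf(paste0("filling waves do not fit in diastole ",
                          "(T=%.3g s, systolic_fraction=%.3g, widths %.3g+%.3g s ",
                          "exceed available %.3g s)"),
                   period, systolic_fraction, wE, wA, td * (1 - 2 * margin_frac)))
    t_e0 <- ts + margin_frac * td
    t_a1 <- period - margin_frac * td
    t_a0 <- t_a1 - wA
    # raised-cosine bumps have area amplitude*width/2; solve for the two
    # amplitudes from the filled volume and the peak ratio
    a_amp <- 2 * SV / (e_a_ratio * wE + wA)
    e_amp <- e_a_ratio * a_amp
    bumps <- list(list(t0 = t_e0, w = wE, amp = e_amp),
                  list(t0 = t_a0, w = wA, amp = a_amp))
  } else {
    w <- td * (1 - 2 * margin_frac)
    t_e0 <- ts + margin_frac * td
    bumps <- list(list(t0 = t_e0, w = w, amp = 2 * SV / w))
    e_amp <- bumps[[1L]]$amp
    a_amp <- NA_real_
    wE <- w
  }

  bump <- function(t, b) {
    u <- (t - b$t0) / b$w
    ifelse(u > 0 & u < 1, b$amp * sin(pi * u)^2, 0)
  }
  bump_int <- function(t, b) {       # integral of bump from b$t0 to t
    u <- pmin(pmax((t - b$t0) / b$w, 0), 1)
    b$amp * b$w * (u - sin(2 * pi * u) / (2 * pi)) / 2
  }

  dVdt <- function(t) {
    t <- t %% period
    sys <- t < ts
    out <- numeric(length(t))
    out[sys] <- -SV * pi / (2 * ts) * sin(pi * t[sys] / ts)
    for (b in bumps) out[!sys] <- out[!sys] + bump(t[!sys], b)
    out
  }
  V <- function(t) {
    t <- t %% period
    sys <- t < ts
    out <- numeric(length(t))
    out[sys] <- ESV + SV * (1 + cos(pi * t[sys] / ts)) / 2
    fill <- rep(0, sum(!sys))
    for (b in bumps) fill <- fill + bump_int(t[!sys], b)
    out[!sys] <- ESV + fill
    out
  }

  structure(list(
    V = V, dVdt = dVdt,
    EDV = EDV, ESV = ESV, period = period, t_es = ts,
    e_peak = e_amp, a_peak = a_amp,
    t_e_peak = bumps[[1L]]$t0 + bumps[[1L]]$w / 2,
    t_a_peak = if (waves == "ea") bumps[[2L]]$t0 + bumps[[2L]]$w / 2 else NA_real_,
    t_e_onset = bumps[[1L]]$t0, T_E = wE,
    waves = waves, bumps = bumps,
    systolic_fraction = systolic_fraction, e_a_ratio = if (waves == "ea") e_a_ratio else NA_real_
  ), class = "volume_waveform")
}

#' @export
print.volume_waveform <- function(x, ...) {
  cat(sprintf("volume_waveform: EDV %.1f mL, ESV %.1f mL, T %.3f s (%s waves)\n",
              x$EDV, x$ESV, x$period, x$waves))
  if (x$waves == "ea")
    cat(sprintf("  E peak %.0f mL/s, A peak %.0f mL/s (E/A = %.2f)\n",
                x$e_peak, x$a_peak, x$e_peak / x$a_peak))
  invisible(x)
}
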