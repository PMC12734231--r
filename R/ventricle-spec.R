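#' Exercise phase labels
#'
#' The five acquisition time points of the exercise protocol plus the
#' resting reference cohort.
#' @export
phase_labels <- c("Control", "Rest", "Mid", "Peak", "Recovery5", "Recovery10")

#' Mid- and peak-exercise target heart rates
#'
#' Peak target is 85% of the age-predicted maximum, `(220 - age) * 0.85`;
#' the mid-exercise target sits midway between baseline and peak,
#' `(peak - baseline) / 2 + baseline`.
#'
#' @param age subject age in years (0 < age < 120).
#' @param baseline_hr resting heart rate in beats/min (>= 0).
#' @return named numeric vector `c(mid = , peak = )` in beats/min.
#' @examples
#' target_heart_rates(age = 10, baseline_hr = 76)
#' @export
target_heart_rates <- function(age, baseline_hr) {
  if (!is.finite(age) || age <= 0 || age >= 120)
    stop("age must lie in (0, 120) years")
  if (!is.finite(baseline_hr) || baseline_hr < 0)
    stop("baseline_hr must be non-negative")
  peak <- (220 - age) * 0.85
  mid <- (peak - baseline_hr) / 2 + baseline_hr
  c(mid = mid, peak = peak)
}

#' Parameter specification for one synthetic ventricle
#'
#' Collects the physiologic and numerical parameters that define one subject
#' at one exercise phase. Defaults not supplied are derived: the systolic
#' fraction follows a square-root rate correction (systolic duration
#' `0.3 * sqrt(T)` seconds, clamped to 25-60% of the cycle), so systole
#' claims a growing share of the shortening cycle as heart rate rises.
#'
#' @param EDV,ESV end-diastolic / end-systolic volume (mL), `EDV > ESV > 0`.
#' @param HR heart rate (beats/min, > 0); the period is `60 / HR`.
#' @param e_a_ratio E-wave to A-wave peak dV/dt ratio (> 0).
#' @param systolic_fraction fraction of the cycle in systole, in (0, 1);
#'   `NULL` for the rate-corrected default.
#' @param twist_deg apical-basal torsion at end systole, degrees.
#' @param long_circ_split fraction of volumetric shortening assigned to the
#'   longitudinal direction (0 = all circumferential, 1 = all longitudinal).
#' @param split_lead temporal lead of the dominant (circumferential)
#'   contraction: during the first half of systole the longitudinal split
#'   exponent ramps from `long_circ_split - split_lead` up to
#'   `long_circ_split`, so a positive value makes the dominant direction
#'   contract first and stretches the cross direction early in systole
#'   (transient positive secondary strain). 0 disables the lead.
#' @param n_frames frames per cardiac cycle (>= 10).
#' @param seed integer seed recorded with the spec.
#' @return object of class `ventricle_spec`.
#' @export
ventricle_spec <- function(EDV, ESV, HR, e_a_ratio = 1.6,
                           systolic_fraction = NULL,
                           twist_deg = 10, long_circ_split = 0.25,
                           split_lead = 0, n_frames = 32L, seed = 1L) {
  if (!(is.finite(EDV) && is.finite(ESV) && EDV > ESV && ESV > 0))
    stop("need EDV > ESV > 0")
  if (!(is.finite(HR) && HR > 0)) stop("HR must be positive")
  if (!(e_a_ratio > 0)) stop("e_a_ratio must be positive")
  period <- 60 / HR
  if (is.null(systolic_fraction))
    systolic_fraction <- min(max(0.3 * sqrt(period) / period, 0.25), 0.6)
  if (!(systolic_fraction > 0 && systolic_fraction < 1))
    stop("systolic_fraction must lie in (0, 1)")
  if (!(long_circ_split >= 0 && long_circ_split <= 1))
    stop("long_circ_split must lie in [0, 1]")
  n_frames <- as.integer(n_frames)
  if (n_frames < 10L)
    stop("n_frames must be >= 10 (minimum frames per cardiac cycle)")
  structure(list(EDV = EDV, ESV = ESV, HR = HR, period = period,
                 e_a_ratio = e_a_ratio, systolic_fraction = systolic_fraction,
                 twist_deg = twist_deg, long_circ_split = long_circ_split,
                 split_lead = split_lead,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "ventricle_spec")
}

#' @export
print.ventricle_spec <- function(x, ...) {
  cat(sprintf(paste0("ventricle_spec: EDV %.1f / ESV %.1f mL, HR %.0f bpm, ",
                     "E/A %.2f, %d frames\n"),
              x$EDV, x$ESV, x$HR, x$e_a_ratio, x$n_frames))
  invisible(x)
}

#' Default per-phase cohort parameters
#'
#' Phase-wise means and SDs of heart rate, EDV and ESV for a healthy pediatric
#' exercise cohort, the per-phase E/A peak-flow ratios, and typical frames per
#' cycle at each phase (temporal resolution drops as wall velocity rises).
#'
#' @return data.frame with one row per phase.
#' @export
default_phase_table <- function() {
  data.frame(
    phase = phase_labels,
    HR_mean = c(77, 76, 141, 174, 102, 100),
    HR_sd = c(9, 11, 19, 10, 11, 12),
    EDV_mean = c(89, 90, 81, 66, 79, 86),
    EDV_sd = c(21, 24, 31, 19, 17, 19),
    ESV_mean = c(35, 36, 27, 21, 32, 37),
    ESV_sd = c(13, 10, 8, 6.4, 6, 8),
    e_a_ratio = c(1.6, 1.6, 6.3, 1.5, 1.1, 1.2),
    n_frames = c(32L, 26L, 12L, 11L, 17L, 19L),
    stringsAsFactors = FALSE
  )
}
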