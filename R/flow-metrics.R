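#' Vorticity modulus on a masked grid
#'
#' Second-order centred curl at interior mask nodes, falling back to
#' one-sided first-order differences where a neighbour lies outside the
#' mask (or the grid). Returns the modulus |curl v| at every masked node,
#' NA elsewhere.
#'
#' @param field a [grid_velocity_field()].
#' @return numeric array `nx x ny x nz` of |curl v| (NA outside the mask).
#' @export
vorticity_field <- function(field) {
  stopifnot(inherits(field, "grid_velocity_field"))
  M <- field$mask
  h <- field$h
  d <- function(comp, axis) masked_derivative(field$v[, , , comp], M, axis, h)
  w1 <- d(3L, 2L) - d(2L, 3L)
  w2 <- d(1L, 3L) - d(3L, 1L)
  w3 <- d(2L, 1L) - d(1L, 2L)
  out <- sqrt(w1^2 + w2^2 + w3^2)
  out[!M] <- NA_real_
  out
}

# shift an array by +1/-1 node along an axis, padding with NA
shift_axis <- function(A, axis, by) {
  dn <- dim(A)
  idx <- lapply(dn, seq_len)
  src <- idx
  n <- dn[axis]
  if (by > 0) { idx[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1L) }
  else { idx[[axis]] <- 1:(n - 1L); src[[axis]] <- 2:n }
  out <- array(NA, dim = dn)
  out[idx[[1L]], idx[[2L]], idx[[3L]]] <- A[src[[1L]], src[[2L]], src[[3L]]]
  out
}

masked_derivative <- function(A, M, axis, h) {
  A0 <- A
  A[!M] <- NA_real_
  Ap <- shift_axis(A, axis, -1L)   # value at node + 1
  Am <- shift_axis(A, axis, +1L)   # value at node - 1
  okp <- !is.na(Ap); okm <- !is.na(Am)
  d <- array(NA_real_, dim = dim(A))
  both <- okp & okm
  d[both] <- (Ap[both] - Am[both]) / (2 * h)
  fp <- okp & !okm
  d[fp] <- (Ap[fp] - A[fp]) / h
  fm <- okm & !okp
  d[fm] <- (A[fm] - Am[fm]) / h
  lone <- M & !(okp | okm)
  if (any(lone)) {
    # single-node chord: no in-mask neighbour along this axis; fall back to
    # the full-grid values (defined everywhere on these fixtures)
    Bp <- shift_axis(A0, axis, -1L); Bm <- shift_axis(A0, axis, +1L)
    gb <- lone & !is.na(Bp) & !is.na(Bm)
    d[gb] <- (Bp[gb] - Bm[gb]) / (2 * h)
    g1 <- lone & !gb & !is.na(Bp)
    d[g1] <- (Bp[g1] - A0[g1]) / h
    g2 <- lone & !gb & !g1 & !is.na(Bm)
    d[g2] <- (A0[g2] - Bm[g2]) / h
    if (any(lone & is.na(d)))
      stop("mask interior needs at least 2 nodes in each direction")
  }
  d
}

#' Dimensionless mean vorticity
#'
#' Volume-mean vorticity modulus over the chamber mask, made dimensionless
#' with the heartbeat period: `omega_bar = (T/V) * integral(|curl v|) dV`,
#' evaluated by mask-restricted midpoint quadrature.
#'
#' @param field a [grid_velocity_field()] or a list of them (one per frame).
#' @param period heartbeat period T (s).
#' @return numeric scalar (or vector over frames).
#' @export
mean_vorticity <- function(field, period) {
  if (is.list(field) && !inherits(field, "grid_velocity_field"))
    return(vapply(field, mean_vorticity, numeric(1), period = period))
  w <- vorticity_field(field)
  period * mean(w[field$mask])
}

#' Diastolic peak of a mean-vorticity series
#'
#' @param omega_bar per-frame dimensionless mean vorticity.
#' @param diastolic_frames indices of the diastolic frames (after end systole).
#' @return scalar maximum over diastole.
#' @export
vorticity_diastolic_peak <- function(omega_bar, diastolic_frames) {
  if (length(diastolic_frames) == 0L) stop("no diastolic frames")
  max(omega_bar[diastolic_frames])
}

#' Transmitral flow record
#'
#' Flow rate through the mitral orifice with its effective area and the
#' E-wave window, the inputs of the vortex formation time. The effective
#' diameter is that of a circle of area `A_eff`: `d = sqrt(4 A_eff / pi)`.
#'
#' @param times sample times (s).
#' @param Q flow rate (mL/s), non-negative during filling.
#' @param A_eff effective mitral orifice area (mm^2, > 0).
#' @param window length-2 E-wave window `c(onset, end)` in seconds.
#' @return object of class `transmitral_flow`.
#' @export
transmitral_flow <- function(times, Q, A_eff, window) {
  stopifnot(length(times) == length(Q), A_eff > 0, length(window) == 2L,
            window[2L] > window[1L])
  if (window[1L] < min(times) - 1e-9 || window[2L] > max(times) + 1e-9)
    stop("E-wave window lies outside the flow record")
  structure(list(times = times, Q = Q, A_eff = A_eff,
                 d = sqrt(4 * A_eff / pi), window = window,
                 T_E = diff(window)),
            class = "transmitral_flow")
}

#' Transmitral flow from a volume curve
#'
#' Mass conservation with a binary mitral valve: the transmitral flow rate
#' during filling equals dV/dt, and the E-wave window is the volume curve's
#' detected E-wave (onset zero-crossing to E-A minimum).
#'
#' @param vc a [volume_curve()].
#' @param mv_area effective mitral orifice area (mm^2).
#' @return a [transmitral_flow()].
#' @export
transmitral_flow_from_curve <- function(vc, mv_area) {
  stopifnot(inherits(vc, "volume_curve"))
  transmitral_flow(vc$dense$times, pmax(vc$dense$dVdt, 0), mv_area,
                   window = c(vc$t_E_onset, vc$t_EA_min))
}

#' Vortex formation time
#'
#' Dimensionless length of the fluid column driven through the mitral
#' orifice during the E-wave: `VFT = integral over T_E of v_MV(t)/d dt`,
#' with `v_MV = Q/A_eff` the mean orifice velocity and `d` the effective
#' orifice diameter. Trapezoidal integration on the sampled waveform, with
#' the window endpoints interpolated.
#'
#' @param tf a [transmitral_flow()].
#' @return scalar VFT (dimensionless, >= 0).
#' @examples
#' # constant 40 cm/s through a 2 cm orifice for 0.15 s -> VFT = 3
#' A <- pi * 10^2   # mm^2, d = 20 mm
#' tf <- transmitral_flow(seq(0, 0.2, 0.01), rep(400 * A / 1000, 21), A,
#'                        window = c(0.02, 0.17))
#' vortex_formation_time(tf)
#' @export
vortex_formation_time <- function(tf) {
  stopifnot(inherits(tf, "transmitral_flow"))
  tt <- tf$times; v <- tf$Q * 1000 / tf$A_eff       # mm/s
  w <- tf$window
  inside <- tt > w[1L] & tt < w[2L]
  ts_ <- c(w[1L], tt[inside], w[2L])
  vs_ <- c(stats::approx(tt, v, w[1L], rule = 2)$y, v[inside],
           stats::approx(tt, v, w[2L], rule = 2)$y)
  if (all(vs_ <= 0)) stop("transmitral flow is non-positive throughout the E-wave window")
  sum(diff(ts_) * (vs_[-1L] + vs_[-length(vs_)]) / 2) / tf$d
}

#' Classify a vortex formation time
#'
#' Below 3 the filling vortex is underdeveloped (suboptimal propulsion);
#' 3 to 4 is the optimal range; up to 5 is still acceptable; above 5 the
#' forming vortex breaks down.
#'
#' @param vft numeric VFT values (>= 0).
#' @return character vector with levels suboptimal / optimal / acceptable /
#'   high.
#' @export
classify_vft <- function(vft) {
  if (any(vft < 0)) stop("VFT must be non-negative")
  out <- character(length(vft))
  out[vft < 3] <- "suboptimal"
  out[vft >= 3 & vft <= 4] <- "optimal"
  out[vft > 4 & vft <= 5] <- "acceptable"
  out[vft > 5] <- "high"
  out
}
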