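#' Material wall velocities of a mesh sequence
#'
#' Periodic time differentiation of every vertex trajectory on the uniform
#' frame grid. `"spectral"` (default) differentiates the Fourier
#' interpolant; `"central"` uses second-order centred differences. Under the
#' no-slip condition the wall fluid velocity equals this wall velocity.
#'
#' @param mesh a [mesh_sequence()] sampled on a uniform time grid over one
#'   period (as produced by the generator or [resample_cycle()]).
#' @param method differentiation scheme.
#' @param harmonics optional Fourier truncation: keep only this many
#'   harmonics (smoothing for low frame counts); `NULL` keeps all.
#' @return array `nv x 3 x nf` of velocities (mm/s).
#' @export
boundary_velocity <- function(mesh, method = c("spectral", "central"),
                              harmonics = NULL) {
  method <- match.arg(method)
  nf <- n_frames(mesh)
  if (nf < 3L) stop("need at least 3 frames to differentiate")
  check_uniform_times(mesh)
  nv <- dim(mesh$vertices)[1L]
  X <- matrix(aperm(mesh$vertices, c(3L, 1L, 2L)), nrow = nf)  # nf x (nv*3)
  D <- time_derivative(X, mesh$period, method = method, harmonics = harmonics)
  aperm(array(D, dim = c(nf, nv, 3L)), c(2L, 3L, 1L))
}

check_uniform_times <- function(mesh) {
  nf <- n_frames(mesh)
  tu <- (seq_len(nf) - 1L) * mesh$period / nf
  if (max(abs(mesh$times - tu)) > 1e-8 * mesh$period)
    stop("frames are not on a uniform grid over the period; resample_cycle() first")
  invisible(TRUE)
}

# periodic time derivative of the columns of X (nf x m)
time_derivative <- function(X, period, method = "spectral", harmonics = NULL) {
  n <- nrow(X)
  if (method == "central") {
    ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
    return((X[ip, , drop = FALSE] - X[im, , drop = FALSE]) / (2 * period / n))
  }
  H <- stats::mvfft(X)
  m <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[seq_len(n)]
  if (!is.null(harmonics)) H[abs(m) > harmonics, ] <- 0
  w <- 2i * pi * m / period
  if (n %% 2L == 0L) w[n %/% 2 + 1L] <- 0      # drop the Nyquist mode
  Re(stats::mvfft(H * w, inverse = TRUE)) / n
}

#' Binary-valve orifice plug velocities from a volume curve
#'
#' Mass-conservation closure of the chamber: during ejection (dV/dt < 0) the
#' aortic valve is open and carries an outward plug velocity |dV/dt| / A_AV
#' while the mitral valve is closed; during filling (dV/dt > 0) the mitral
#' valve carries the inward plug velocity dV/dt / A_MV and the aortic valve
#' is closed.
#'
#' @param vc a [volume_curve()].
#' @param mv_area,av_area effective orifice areas (mm^2, > 0).
#' @return data.frame with `time`, `av_speed` (outward, mm/s) and `mv_speed`
#'   (inward, mm/s).
#' @export
orifice_plug_velocity <- function(vc, mv_area, av_area) {
  stopifnot(inherits(vc, "volume_curve"))
  q <- vc$dVdt * 1000                     # mL/s -> mm^3/s
  if ((mv_area <= 0 && any(q > 0)) || (av_area <= 0 && any(q < 0)))
    stop("zero orifice area with nonzero flux")
  data.frame(time = vc$times,
             av_speed = ifelse(q < 0, -q / av_area, 0),
             mv_speed = ifelse(q > 0, q / mv_area, 0))
}

#' Hemodynamic force time series from boundary data
#'
#' Evaluates the blood-tissue force exchange from surface data alone,
#' F(t) = rho * [ d/dt \eqn{\oint x (v.n) dS} + \eqn{\oint v (v.n) dS} ],
#' where v is the no-slip wall velocity on the moving endocardium and a
#' binary-valve plug velocity on the orifice patches (aortic during
#' ejection, mitral during filling). The time derivative of the first
#' integral is taken by periodic spectral differencing across frames. The
#' force is reported both in Newtons and in the dimensionless percent form
#' f = F / (rho g V(t)) * 100, so f is independent of the fluid density and
#' a rigid translation at peak acceleration g has amplitude 100%.
#'
#' @param mesh a registered [mesh_sequence()] on a uniform time grid,
#'   closed including the basal cap.
#' @param rho fluid density (kg/m^3).
#' @param g gravitational acceleration (m/s^2).
#' @param orifice `"plug"` applies valve plug velocities on the marked cap
#'   patches; `"none"` uses the wall velocity everywhere (rigid-motion
#'   oracles).
#' @param harmonics optional Fourier truncation of the wall velocities.
#' @param vc optional precomputed [volume_curve()].
#' @return object of class `hdf_series`: `times`, `f` (nf x 3, %),
#'   `F_newton` (nf x 3, N), `V` (mL), `i_ED`, `i_ES`, `period`.
#' @export
hdf_time_series <- function(mesh, rho = 1060, g = 9.81,
                            orifice = c("plug", "none"), harmonics = NULL,
                            vc = NULL) {
  orifice <- match.arg(orifice)
  check_uniform_times(mesh)
  nf <- n_frames(mesh)
  vel <- boundary_velocity(mesh, harmonics = harmonics)
  V <- mesh_volume(mesh)
  if (is.null(vc)) {
    q <- drop(time_derivative(cbind(V), mesh$period)) * 1000   # mm^3/s
    i_ED <- which.max(V); i_ES <- which.min(V)
  } else {
    q <- vc$dVdt * 1000
    i_ED <- vc$i_ED; i_ES <- vc$i_ES
  }
  if (diff(range(V)) < 1e-9 * max(V)) q[] <- 0   # rigid motion: no net flux
  tm <- mesh$triangles
  has_orifice <- orifice == "plug" && any(mesh$cap)
  mv_tri <- mesh$cap & !mesh$aortic
  av_tri <- mesh$aortic

  I1 <- matrix(0, nf, 3L)
  I2 <- matrix(0, nf, 3L)
  for (f in seq_len(nf)) {
    Vf <- frame_vertices(mesh, f)
    nds <- triangle_area_vectors(Vf, tm)
    xc <- triangle_centroids(Vf, tm)
    vcn <- (vel[tm[, 1L], , f] + vel[tm[, 2L], , f] + vel[tm[, 3L], , f]) / 3
    if (has_orifice && q[f] != 0) {
      open <- if (q[f] < 0) av_tri else mv_tri
      a_open <- sqrt(rowSums(nds[open, , drop = FALSE]^2))
      A <- sum(a_open)
      if (A <= 0) stop("open orifice patch has zero area")
      nh <- nds[open, , drop = FALSE] / sqrt(rowSums(nds[open, , drop = FALSE]^2))
      speed <- abs(q[f]) / A
      # outward through the AV in ejection, inward through the MV in filling
      vcn[open, ] <- (if (q[f] < 0) speed else -speed) * nh
    }
    flux <- rowSums(vcn * nds)
    I1[f, ] <- colSums(xc * flux)
    I2[f, ] <- colSums(vcn * flux)
  }
  dI1 <- time_derivative(I1, mesh$period)
  Fn <- rho * (dI1 + I2) * 1e-12           # mm^4/s^2 * kg/m^3 -> N
  fpct <- 100 * Fn / (rho * g * V * 1e-6)
  structure(list(times = mesh$times, f = fpct, F_newton = Fn, V = V,
                 i_ED = i_ED, i_ES = i_ES, period = mesh$period,
                 rho = rho, g = g),
            class = "hdf_series")
}

#' @export
print.hdf_series <- function(x, ...) {
  cat(sprintf(paste0("hdf_series: %d frames, T = %.3f s; longitudinal f_z in ",
                     "[%.1f, %.1f]%%\n"),
              length(x$times), x$period, min(x$f[, 3L]), max(x$f[, 3L])))
  invisible(x)
}

#' @export
plot.hdf_series <- function(x, ...) {
  graphics::matplot(x$times, x$f, type = "l", lty = 1, col = c(3, 4, 1),
                    xlab = "time [s]", ylab = "f [%]", ...)
  graphics::abline(v = x$times[x$i_ES], lty = 2)
  graphics::legend("topright", c("f_x", "f_y", "f_z"), col = c(3, 4, 1),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Longitudinal hemodynamic-force parameters
#'
#' Extracts the six scalar descriptors of the longitudinal dimensionless
#' force f_z(t): amplitudes are root-mean-square values (whole cycle /
#' systole / diastole), impulses are time-averages over contiguous lobes of
#' the curve. The systolic impulse averages the positive lobe within
#' systole; the suction parameter averages the negative interval that starts
#' at the first zero-crossing after the systolic positive lobe (spanning
#' late systole and early diastole) and is reported as a magnitude; the
#' diastolic impulse averages the positive lobe immediately following the
#' suction interval. Lobes that do not exist are reported as NA.
#'
#' @param hdf an [hdf_time_series()] result.
#' @param vc optional [volume_curve()] giving the systole/diastole split
#'   (systole = frames from ED up to ES); defaults to the indices stored in
#'   `hdf`.
#' @return object of class `hdf_parameters`: named list with `LVLF`,
#'   `LVsysLF`, `LVsysIm`, `LVs`, `LVdiaLF`, `LVdiaIm` (all %) and the lobe
#'   windows.
#' @export
hdf_parameters <- function(hdf, vc = NULL) {
  stopifnot(inherits(hdf, "hdf_series"))
  i_ED <- if (is.null(vc)) hdf$i_ED else vc$i_ED
  i_ES <- if (is.null(vc)) hdf$i_ES else vc$i_ES
  n <- length(hdf$times)
  # rotate so the cycle starts at end diastole
  rot <- ((seq_len(n) + i_ED - 2L) %% n) + 1L
  fz <- hdf$f[rot, 3L]
  tt <- (seq_len(n) - 1L) * hdf$period / n
  n_sys <- (i_ES - i_ED) %% n
  if (n_sys == 0L) stop("end systole coincides with end diastole")
  sys <- seq_len(n_sys)

  rms <- function(v) sqrt(mean(v^2))
  # piecewise-linear lobe bookkeeping on the periodic series (doubled to
  # allow lobes that wrap through end diastole)
  t2 <- c(tt, tt + hdf$period)
  f2 <- c(fz, fz)

  lobe_mean <- function(i_from, sign_) {
    # first index at/after i_from where sign matches
    idx <- i_from
    while (idx <= length(f2) && !(sign_ * f2[idx] > 0)) idx <- idx + 1L
    if (idx > length(f2) || t2[idx] >= hdf$period * 2) return(NULL)
    i0 <- idx
    while (idx <= length(f2) && sign_ * f2[idx] > 0) idx <- idx + 1L
    i1 <- idx - 1L                      # last index inside the lobe
    # linear zero-crossing endpoints
    ta <- if (i0 > 1L && sign_ * f2[i0 - 1L] <= 0)
      zero_cross(t2[i0 - 1L], t2[i0], f2[i0 - 1L], f2[i0]) else t2[i0]
    tb <- if (i1 < length(f2) && sign_ * f2[i1 + 1L] <= 0)
      zero_cross(t2[i1], t2[i1 + 1L], f2[i1], f2[i1 + 1L]) else t2[i1]
    ts_ <- c(ta, t2[seq(i0, i1)], tb)
    fs_ <- c(if (ta < t2[i0]) 0 else f2[i0], f2[seq(i0, i1)],
             if (tb > t2[i1]) 0 else f2[i1])
    keep <- !duplicated(ts_)
    ts_ <- ts_[keep]; fs_ <- fs_[keep]
    area <- sum(diff(ts_) * (fs_[-1L] + fs_[-length(fs_)]) / 2)
    list(mean = area / (tb - ta), from = ta, to = tb,
         i_peak = i0 - 1L + which.max(sign_ * f2[i0:i1]))
  }

  # systolic positive lobe: around the systolic maximum
  i_max <- which.max(fz[sys])
  sys_lobe <- if (fz[sys][i_max] > 0) {
    i <- i_max
    while (i > 1L && fz[i - 1L] > 0) i <- i - 1L
    lobe_mean(i, +1)
  } else NULL
  suction <- if (!is.null(sys_lobe))
    lobe_mean(sys_lobe$i_peak + 1L, -1) else NULL
  dia_lobe <- if (!is.null(suction))
    lobe_mean(suction$i_peak + 1L, +1) else NULL
  # the diastolic impulse must lie within the cycle following suction
  if (!is.null(dia_lobe) && dia_lobe$from >= hdf$period + (if (is.null(sys_lobe)) 0 else sys_lobe$from))
    dia_lobe <- NULL

  structure(list(
    LVLF = rms(fz),
    LVsysLF = rms(fz[sys]),
    LVdiaLF = rms(fz[-sys]),
    LVsysIm = if (is.null(sys_lobe)) NA_real_ else sys_lobe$mean,
    LVs = if (is.null(suction)) NA_real_ else abs(suction$mean),
    LVdiaIm = if (is.null(dia_lobe)) NA_real_ else dia_lobe$mean,
    windows = list(systolic = sys_lobe[c("from", "to")],
                   suction = suction[c("from", "to")],
                   diastolic = dia_lobe[c("from", "to")]),
    n_systole = n_sys, n = n
  ), class = "hdf_parameters")
}

#' @export
print.hdf_parameters <- function(x, ...) {
  v <- unlist(x[c("LVLF", "LVsysLF", "LVsysIm", "LVs", "LVdiaLF", "LVdiaIm")])
  cat("longitudinal HDF parameters [%]:\n")
  print(round(v, 2))
  invisible(x)
}
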