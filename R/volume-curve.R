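#' Volume curve and diastolic filling indices
#'
#' Computes the enclosed-volume time course of a mesh sequence (or of a
#' supplied sampled volume series), its periodic derivative dV/dt, the
#' end-diastolic (max V) and end-systolic (min V) frames, and the diastolic
#' filling structure: the E and A waves are the two largest positive local
#' maxima of dV/dt after end systole, ordered in time, and the E/A ratio is
#' their peak ratio. The E-wave window spans the zero-crossing of dV/dt
#' before the E peak to the E-A local minimum. When only one diastolic
#' filling wave is found the waves are flagged as merged and the A peak and
#' E/A ratio are reported as NA.
#'
#' Internally the sampled volume is interpolated with a periodic cubic spline
#' onto a dense uniform grid and differentiated there, so peak detection does
#' not depend on the (possibly coarse) frame timing.
#'
#' @param x a [mesh_sequence()], or a numeric vector of sample times (s).
#' @param V sampled volumes (mL) when `x` is numeric.
#' @param period cycle period (s) when `x` is numeric.
#' @param n_dense dense grid size for spline resampling.
#' @param min_peak_frac smallest diastolic peak counted as a filling wave,
#'   as a fraction of the tallest diastolic dV/dt peak (suppresses numerical
#'   ripples).
#' @param ... unused.
#' @return object of class `volume_curve`: times, V, dVdt at the input
#'   samples; `i_ED`, `i_ES`, `EDV`, `ESV`, `SV`, `EF` (%); `E_peak`,
#'   `A_peak` (mL/s), `e_a_ratio`, `merged`, `T_E`, `t_E_onset`, `t_EA_min`;
#'   and the dense grid under `$dense`.
#' @export
volume_curve <- function(x, ...) UseMethod("volume_curve")

#' @rdname volume_curve
#' @export
volume_curve.mesh_sequence <- function(x, n_dense = 2048L, ...) {
  V <- mesh_volume(x)
  if (n_frames(x) < 10L)
    warning("fewer than 10 frames per cardiac cycle; filling indices may be unreliable")
  volume_curve.default(x$times, V = V, period = x$period, n_dense = n_dense, ...)
}

#' @rdname volume_curve
#' @export
volume_curve.default <- function(x, V, period, n_dense = 2048L,
                                 min_peak_frac = 0.05, ...) {
  times <- as.numeric(x)
  stopifnot(length(times) == length(V), period > times[length(times)])
  ph <- c(times, period) / period
  td <- (seq_len(n_dense) - 1L) / n_dense
  Vd <- stats::spline(ph, c(V, V[1L]), method = "periodic", xout = td)$y
  h <- period / n_dense
  dVd <- (Vd[c(2:n_dense, 1L)] - Vd[c(n_dense, 1:(n_dense - 1L))]) / (2 * h)
  tdense <- td * period

  i_ED <- which.max(V)
  i_ES <- which.min(V)
  t_es <- tdense[which.min(Vd)]

  # diastole: dense samples after end systole
  dia <- which(tdense > t_es)
  if (length(dia) < 3L) stop("no diastolic window after end systole")
  dd <- dVd[dia]
  loc <- which(dd > 0 &
               dd >= c(-Inf, dd[-length(dd)]) &
               dd > c(dd[-1L], -Inf))
  if (length(loc) == 0L)
    stop("no positive dV/dt lobe found in diastole")
  # ignore numerical ripples: a filling wave must reach a fraction of the
  # tallest diastolic peak
  loc <- loc[dd[loc] >= min_peak_frac * max(dd[loc])]
  # drop sub-peaks: keep the (up to) two largest, then order in time
  keep <- loc[order(dd[loc], decreasing = TRUE)][seq_len(min(2L, length(loc)))]
  keep <- sort(keep)
  iE <- dia[keep[1L]]
  merged <- length(keep) < 2L
  iA <- if (merged) NA_integer_ else dia[keep[2L]]
  E_peak <- dVd[iE]
  A_peak <- if (merged) NA_real_ else dVd[iA]

  # E-wave onset: last non-positive dV/dt before the E peak
  before <- dia[dia < iE]
  neg <- before[dVd[before] <= 0]
  t_on <- if (length(neg)) {
    i0 <- max(neg)
    zero_cross(tdense[i0], tdense[i0 + 1L], dVd[i0], dVd[i0 + 1L])
  } else t_es
  # E-wave end: E-A local minimum, or the zero-crossing after E when merged
  if (!merged) {
    seg <- iE:iA
    t_off <- tdense[seg[which.min(dVd[seg])]]
  } else {
    after <- dia[dia > iE]
    neg <- after[dVd[after] <= 0]
    t_off <- if (length(neg)) {
      i1 <- min(neg)
      zero_cross(tdense[i1 - 1L], tdense[i1], dVd[i1 - 1L], dVd[i1])
    } else period
  }

  dVdt <- stats::approx(tdense, dVd, xout = times, rule = 2)$y
  EDV <- V[i_ED]; ESV <- V[i_ES]
  structure(list(times = times, V = V, dVdt = dVdt,
                 i_ED = i_ED, i_ES = i_ES,
                 EDV = EDV, ESV = ESV, SV = EDV - ESV,
                 EF = 100 * (EDV - ESV) / EDV,
                 E_peak = E_peak, A_peak = A_peak,
                 e_a_ratio = if (merged) NA_real_ else E_peak / A_peak,
                 merged = merged,
                 t_E_peak = tdense[iE],
                 t_A_peak = if (merged) NA_real_ else tdense[iA],
                 t_E_onset = t_on, t_EA_min = t_off, T_E = t_off - t_on,
                 t_ES = t_es, period = period,
                 dense = list(times = tdense, V = Vd, dVdt = dVd)),
            class = "volume_curve")
}

zero_cross <- function(t0, t1, y0, y1) {
  if (y1 == y0) return(t0)
  t0 - y0 * (t1 - t0) / (y1 - y0)
}

#' @export
print.volume_curve <- function(x, ...) {
  cat(sprintf("volume_curve: EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%\n",
              x$EDV, x$ESV, x$SV, x$EF))
  if (x$merged)
    cat("  single (merged) diastolic filling wave; E/A undefined\n")
  else
    cat(sprintf("  E %.0f mL/s, A %.0f mL/s, E/A %.2f, T_E %.3f s\n",
                x$E_peak, x$A_peak, x$e_a_ratio, x$T_E))
  invisible(x)
}

#' @export
plot.volume_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$dense$times, x$dense$V, type = "l",
                 xlab = "time [s]", ylab = "V [mL]", ...)
  graphics::points(x$times, x$V)
  graphics::plot(x$dense$times, x$dense$dVdt, type = "l",
                 xlab = "time [s]", ylab = "dV/dt [mL/s]")
  graphics::abline(h = 0, lty = 3)
  if (!is.na(x$t_E_peak)) graphics::abline(v = x$t_E_peak, col = 2, lty = 2)
  if (!is.na(x$t_A_peak)) graphics::abline(v = x$t_A_peak, col = 4, lty = 2)
  invisible(x)
}
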