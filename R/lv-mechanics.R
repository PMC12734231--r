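#' Full tissue-and-flow analysis of one ventricle
#'
#' The package's central fitting-style function: registers the sequence to
#' the anatomical frame, computes the volume curve and filling indices, the
#' global strain time courses, the dimensionless hemodynamic force series
#' with its six longitudinal parameters, and the vortex formation time from
#' the dV/dt-derived transmitral flow. Returns one classed object carrying
#' every intermediate product; [coef()] extracts the scalar metric vector
#' used by the cohort statistics.
#'
#' @param mesh a [mesh_sequence()].
#' @param lm a [landmarks()] object.
#' @param mv_area effective mitral orifice area (mm^2) for the VFT.
#' @param rho,g fluid density (kg/m^3) and gravitational acceleration
#'   (m/s^2) for the force normalization.
#' @param harmonics optional Fourier truncation of wall velocities before
#'   differencing (useful at low frame counts); NULL keeps all harmonics.
#' @param register register the sequence first (default TRUE).
#' @return object of class `lv_mechanics`.
#' @examples
#' g <- generate_ventricle_sequence(ventricle_spec(90, 36, 76, n_frames = 16),
#'                                  n_theta = 24, n_phi = 12)
#' fit <- lv_mechanics(g$mesh, g$landmarks)
#' coef(fit)[c("EF", "GPS", "VFT")]
#' @export
lv_mechanics <- function(mesh, lm, mv_area = 400, rho = 1060, g = 9.81,
                         harmonics = NULL, register = TRUE) {
  if (register) {
    reg <- register_sequence(mesh, lm)
    mesh <- reg$mesh; lm <- reg$landmarks
    transform <- reg$transform
  } else transform <- diag(4L)
  vc <- volume_curve(mesh)
  strain <- global_strain_series(mesh, ref_frame = vc$i_ED)
  # the spectral force stage needs a uniform grid over the cycle
  uniform <- tryCatch(check_uniform_times(mesh), error = function(e) FALSE)
  if (isTRUE(uniform)) {
    hdf <- hdf_time_series(mesh, rho = rho, g = g, vc = vc)
    pars <- hdf_parameters(hdf, vc)
  } else {
    mesh_u <- resample_cycle(mesh, max(16L, n_frames(mesh)))
    hdf <- hdf_time_series(mesh_u, rho = rho, g = g)
    pars <- hdf_parameters(hdf)
  }
  vft <- vortex_formation_time(transmitral_flow_from_curve(vc, mv_area))
  structure(list(volume = vc, strain = strain, hdf = hdf,
                 hdf_parameters = pars, vft = vft,
                 mesh = mesh, landmarks = lm, transform = transform,
                 mv_area = mv_area),
            class = "lv_mechanics")
}

#' @export
coef.lv_mechanics <- function(object, ...) {
  vc <- object$volume
  st <- object$strain
  es <- vc$i_ES
  p <- object$hdf_parameters
  c(HR = 60 / vc$period,
    EDV = vc$EDV, ESV = vc$ESV, SV = vc$SV, EF = vc$EF,
    GPS = st$GPS[es], GSS = st$GSS[es], GLS = st$GLS[es], GCS = st$GCS[es],
    LVLF = p$LVLF, LVsysLF = p$LVsysLF, LVsysIm = p$LVsysIm, LVs = p$LVs,
    LVdiaLF = p$LVdiaLF, LVdiaIm = p$LVdiaIm,
    VFT = object$vft, E_A = vc$e_a_ratio)
}

#' @export
print.lv_mechanics <- function(x, ...) {
  cat("lv_mechanics fit\n")
  print(x$volume)
  print(x$strain)
  cat(sprintf("  VFT %.2f (%s)\n", x$vft, classify_vft(x$vft)))
  invisible(x)
}

#' @export
summary.lv_mechanics <- function(object, ...) {
  v <- coef(object)
  cat("left-ventricular mechanics summary\n")
  print(round(v, 2))
  invisible(v)
}

#' @export
plot.lv_mechanics <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$volume$dense$times, x$volume$dense$V, type = "l",
                 xlab = "time [s]", ylab = "V [mL]")
  graphics::matplot(x$strain$time,
                    as.matrix(x$strain[, c("GPS", "GSS", "GLS", "GCS")]),
                    type = "l", lty = 1, col = c(4, 2, 3, 6),
                    xlab = "time [s]", ylab = "strain [%]")
  graphics::plot(x$hdf$times, x$hdf$f[, 3L], type = "l",
                 xlab = "time [s]", ylab = "f_z [%]")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
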