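#' Triangulated sphere fixture
#'
#' Latitude/longitude triangulation of a sphere, outward-oriented. Used as an
#' analytic fixture for volume and surface-integral checks.
#'
#' @param radius sphere radius (mm).
#' @param n_theta number of circumferential subdivisions.
#' @param n_phi number of meridional subdivisions (pole to pole).
#' @param center length-3 center (mm).
#' @return list with `vertices` (matrix) and `triangles`.
#' @export
uv_sphere <- function(radius = 1, n_theta = 48L, n_phi = 24L, center = c(0, 0, 0)) {
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  phi <- pi * seq_len(n_phi - 1L) / n_phi
  ring <- function(p) cbind(radius * sin(p) * cos(theta),
                            radius * sin(p) * sin(theta),
                            radius * cos(p))
  V <- rbind(c(0, 0, radius),
             do.call(rbind, lapply(phi, ring)),
             c(0, 0, -radius))
  V <- sweep(V, 2L, center, "+")
  idx <- function(j, i) 1L + (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  tri <- list()
  tri[[1L]] <- cbind(1L, idx(1L, 1:n_theta), idx(1L, 2:(n_theta + 1L)))
  for (j in seq_len(n_phi - 2L)) {
    a <- idx(j, 1:n_theta); b <- idx(j, 2:(n_theta + 1L))
    c_ <- idx(j + 1L, 2:(n_theta + 1L)); d <- idx(j + 1L, 1:n_theta)
    tri[[length(tri) + 1L]] <- cbind(a, c_, b)
    tri[[length(tri) + 1L]] <- cbind(a, d, c_)
  }
  south <- nrow(V)
  tri[[length(tri) + 1L]] <- cbind(south, idx(n_phi - 1L, 2:(n_theta + 1L)),
                                   idx(n_phi - 1L, 1:n_theta))
  list(vertices = V, triangles = do.call(rbind, tri))
}

# Reference (end-diastolic) half-spheroid ventricle: apex at -L, basal plane
# at z = 0 closed by a triangle fan around the annulus centroid, with a
# marked aortic sector of the cap offset toward +x.
ventricle_reference_mesh <- function(EDV, n_theta = 48L, n_phi = 24L,
                                     aspect = 2, aortic_halfangle = pi / 6) {
  R <- (3 * EDV * 1000 / (2 * pi * aspect))^(1 / 3)
  L <- aspect * R
  phi <- (pi / 2) * seq_len(n_phi) / n_phi
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  rings <- lapply(phi, function(p) cbind(R * sin(p) * cos(theta),
                                         R * sin(p) * sin(theta),
                                         -L * cos(p)))
  V <- rbind(c(0, 0, -L), do.call(rbind, rings), c(0, 0, 0))
  cap_center <- nrow(V)
  idx <- function(j, i) 1L + (j - 1L) * n_theta + ((i - 1L) %% n_theta) + 1L
  tri <- list(cbind(1L, idx(1L, 2:(n_theta + 1L)), idx(1L, 1:n_theta)))
  for (j in seq_len(n_phi - 1L)) {
    a <- idx(j, 1:n_theta); b <- idx(j, 2:(n_theta + 1L))
    c_ <- idx(j + 1L, 2:(n_theta + 1L)); d <- idx(j + 1L, 1:n_theta)
    tri[[length(tri) + 1L]] <- cbind(a, b, c_)
    tri[[length(tri) + 1L]] <- cbind(a, c_, d)
  }
  cap <- cbind(cap_center, idx(n_phi, 1:n_theta), idx(n_phi, 2:(n_theta + 1L)))
  triangles <- rbind(do.call(rbind, tri), cap)
  nt <- nrow(triangles)
  cap_flag <- c(rep(FALSE, nt - n_theta), rep(TRUE, n_theta))
  ctr <- triangle_centroids(V, triangles)
  ang <- atan2(ctr[, 2L], ctr[, 1L])
  aortic <- cap_flag & abs(ang) <= aortic_halfangle
  # calibrate so the discrete enclosed volume equals EDV exactly; deformed
  # frames are affine images, so their volumes scale exactly with the target
  v0 <- mesh_volume(V, triangles)
  V <- V * (EDV / v0)^(1 / 3)
  L <- L * (EDV / v0)^(1 / 3)
  list(vertices = V, triangles = triangles, cap = cap_flag, aortic = aortic,
       L = L, R = R * (EDV / v0)^(1 / 3), cap_center = cap_center)
}

#' Generate a synthetic ventricle mesh sequence
#'
#' Builds one cardiac cycle of a closed half-spheroid endocardial surface
#' whose enclosed volume follows a [volume_waveform()]: half-cosine systolic
#' ejection from EDV to ESV, then E-wave, diastasis and A-wave with the
#' spec's peak-dV/dt ratio. The deformation is an axisymmetric material map
#' applied to the end-diastolic reference: with `deformation = "split"`,
#' volumetric shortening is partitioned between a longitudinal scaling and a
#' circumferential scaling by `long_circ_split`, plus an apex-base torsion
#' that grows with contraction; with `deformation = "isotropic"` each frame is
#' a uniform scaling of the reference, so both in-plane surface stretches are
#' spatially uniform and equal to `(V(t)/EDV)^(1/3)` (useful as a strain
#' ground truth). The reference mesh is calibrated so the discrete enclosed
#' volume at end diastole equals EDV exactly; all frames being affine images
#' of it, frame volumes track the waveform exactly up to torsion-induced
#' facet distortion.
#'
#' @param spec a [ventricle_spec()].
#' @param n_theta,n_phi mesh resolution (circumferential x meridional).
#' @param deformation `"split"` (default) or `"isotropic"`.
#' @param aspect long-axis length over basal radius at end diastole.
#' @param waves passed to [volume_waveform()] (`"ea"` or `"merged"`).
#' @return list with `mesh` (a [mesh_sequence()]), `landmarks` (a
#'   [landmarks()] object) and `truth` (times, ground-truth volume and dV/dt,
#'   the waveform object and the spec). Deterministic: identical specs give
#'   bit-identical output.
#' @examples
#' vs <- ventricle_spec(EDV = 90, ESV = 36, HR = 76, n_frames = 16)
#' g <- generate_ventricle_sequence(vs, n_theta = 24, n_phi = 12)
#' range(mesh_volume(g$mesh))
#' @export
generate_ventricle_sequence <- function(spec, n_theta = 48L, n_phi = 24L,
                                        deformation = c("split", "isotropic"),
                                        aspect = 2, waves = "ea") {
  stopifnot(inherits(spec, "ventricle_spec"))
  deformation <- match.arg(deformation)
  wf <- volume_waveform(spec$EDV, spec$ESV, spec$period,
                        spec$systolic_fraction, spec$e_a_ratio, waves = waves)
  ref <- ventricle_reference_mesh(spec$EDV, n_theta, n_phi, aspect)
  nf <- spec$n_frames
  times <- (seq_len(nf) - 1L) * spec$period / nf
  Vt <- wf$V(times)
  s <- Vt / spec$EDV
  s_min <- spec$ESV / spec$EDV
  twist <- spec$twist_deg * pi / 180 * (1 - s) / (1 - s_min)
  depth <- pmax(-ref$vertices[, 3L], 0) / ref$L     # 0 at base, 1 at apex
  lead <- if (is.null(spec$split_lead)) 0 else spec$split_lead
  u_sys <- pmin(pmax(times / (spec$systolic_fraction * spec$period), 0), 1)
  p_t <- spec$long_circ_split - lead * pmax(1 - 2 * u_sys, 0)

  verts <- array(0, dim = c(nrow(ref$vertices), 3L, nf))
  for (f in seq_len(nf)) {
    if (deformation == "split") {
      lam_l <- s[f]^p_t[f]
      lam_c <- s[f]^((1 - p_t[f]) / 2)
    } else {
      lam_l <- lam_c <- s[f]^(1 / 3)
    }
    x <- ref$vertices[, 1L] * lam_c
    y <- ref$vertices[, 2L] * lam_c
    z <- ref$vertices[, 3L] * lam_l
    b <- twist[f] * depth
    verts[, , f] <- cbind(x * cos(b) - y * sin(b),
                          x * sin(b) + y * cos(b), z)
  }
  mesh <- mesh_sequence(verts, ref$triangles, times, spec$period,
                        cap = ref$cap, aortic = ref$aortic)
  apex <- t(verts[1L, , ])
  annulus <- t(verts[ref$cap_center, , ])
  ao <- t(vapply(seq_len(nf), function(f) {
    Vf <- verts[, , f]
    w <- triangle_areas(Vf, ref$triangles)[ref$aortic]
    ctr <- triangle_centroids(Vf, ref$triangles)[ref$aortic, , drop = FALSE]
    colSums(ctr * w) / sum(w)
  }, numeric(3)))
  lm <- landmarks(annulus, ao, apex)
  list(mesh = mesh, landmarks = lm,
       truth = list(times = times, V = Vt, dVdt = wf$dVdt(times),
                    waveform = wf, spec = spec))
}

# truncated-normal draw (+/- 3 SD and hard bounds), by rejection
rtrunc3 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(mean)
  for (i in 1:1000) {
    x <- stats::rnorm(1L, mean, sd)
    if (abs(x - mean) <= 3 * sd && x >= lower && x <= upper) return(x)
  }
  stop("truncated-normal rejection failed")
}

#' Generate a synthetic exercise cohort
#'
#' Draws per-subject, per-phase ventricle specs from truncated normal
#' distributions (phase-wise mean and SD, truncated at three SD and at
#' physiologic bounds) and generates the corresponding mesh sequences.
#' Infeasible joint draws (ESV >= EDV) are redrawn up to `max_retries` times.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param phase_table per-phase parameter table as in [default_phase_table()];
#'   SDs must be non-negative.
#' @param seed master seed; all draws are reproducible from it.
#' @param phases which phases to generate (default: the five exercise phases).
#' @param meshes generate mesh sequences (TRUE) or specs only.
#' @param subject_prefix id prefix (e.g. "S" for exercise, "C" for controls).
#' @param max_retries bound on joint redraws per subject-phase.
#' @inheritParams generate_ventricle_sequence
#' @param twist_deg,long_circ_split deformation parameters shared by all
#'   subjects.
#' @return list of records, each `list(subject, phase, spec, data)` where
#'   `data` is the [generate_ventricle_sequence()] output (or NULL).
#' @export
generate_cohort <- function(n_subjects, phase_table = default_phase_table(),
                            seed = 1L,
                            phases = setdiff(phase_labels, "Control"),
                            n_theta = 40L, n_phi = 20L, meshes = TRUE,
                            subject_prefix = "S", twist_deg = 10,
                            long_circ_split = 0.25, max_retries = 100L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2 (cohort statistics need at least 2)")
  sdcols <- c("HR_sd", "EDV_sd", "ESV_sd")
  if (any(unlist(phase_table[sdcols]) < 0)) stop("SDs must be non-negative")
  if (!all(phases %in% phase_table$phase))
    stop("unknown phase(s): ", paste(setdiff(phases, phase_table$phase), collapse = ", "))
  set.seed(seed)
  out <- list()
  for (k in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", subject_prefix, k)
    for (ph in phases) {
      row <- phase_table[phase_table$phase == ph, ]
      ok <- FALSE
      for (r in seq_len(max_retries)) {
        HR <- rtrunc3(row$HR_mean, row$HR_sd, lower = 30, upper = 250)
        EDV <- rtrunc3(row$EDV_mean, row$EDV_sd, lower = 10)
        ESV <- rtrunc3(row$ESV_mean, row$ESV_sd, lower = 5)
        if (EDV > ESV + 1) { ok <- TRUE; break }
      }
      if (!ok) stop(sprintf("could not draw EDV > ESV for %s/%s", sid, ph))
      sp <- ventricle_spec(EDV, ESV, HR, e_a_ratio = row$e_a_ratio,
                           twist_deg = twist_deg,
                           long_circ_split = long_circ_split,
                           n_frames = row$n_frames, seed = seed)
      rec <- list(subject = sid, phase = ph, spec = sp,
                  data = if (meshes)
                    generate_ventricle_sequence(sp, n_theta, n_phi) else NULL)
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Rigid-translation mesh sequence (force oracle fixture)
#'
#' Translates a base mesh rigidly along an axis with a prescribed periodic
#' acceleration profile. The displacement is recovered by spectral double
#' integration (the profile's cycle mean is removed first), so for a rigid
#' closed surface the hemodynamic-force boundary integral must return
#' F = rho * V * a(t) exactly up to time discretization.
#'
#' @param base list with `vertices` and `triangles` (and optionally `cap`,
#'   `aortic`), e.g. [uv_sphere()] output.
#' @param accel function of time (s) returning acceleration (mm/s^2) along `axis`.
#' @param period cycle period (s).
#' @param n_frames frames per cycle.
#' @param axis unit direction of motion.
#' @return a [mesh_sequence()].
#' @export
rigid_translation_sequence <- function(base, accel, period, n_frames = 32L,
                                       axis = c(0, 0, 1)) {
  n <- as.integer(n_frames)
  times <- (seq_len(n) - 1L) * period / n
  a <- accel(times)
  a <- a - mean(a)
  ah <- stats::fft(a)
  m <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[seq_len(n)]
  w <- 2 * pi * m / period
  dh <- ifelse(w == 0, 0, -ah / w^2)
  d <- Re(stats::fft(dh, inverse = TRUE)) / n
  axis <- axis / sqrt(sum(axis^2))
  nv <- nrow(base$vertices)
  verts <- array(0, dim = c(nv, 3L, n))
  for (f in seq_len(n))
    verts[, , f] <- base$vertices + rep(d[f] * axis, each = nv)
  mesh_sequence(verts, base$triangles, times, period,
                cap = base$cap, aortic = base$aortic)
}
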