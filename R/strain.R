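# Vectorized surface-strain kernel.
#
# For every triangle: express reference and current edge vectors in
# orthonormal tangent frames, form the in-plane deformation gradient
# F = E_cur E_ref^-1, remove rotation by polar decomposition
# (U = sqrt(F'F) via closed-form symmetric 2x2 eigendecomposition) and
# return the Lagrangian strain S = U - I, its eigenvalues
# (lambda_p <= lambda_s) and the principal direction lifted to 3D in the
# reference triangle plane. The first tangent basis vector is the projection
# of the global long axis onto the triangle plane (fallback: longest edge
# when nearly parallel to the normal), so S11 and S22 are the longitudinal
# and circumferential normal strains directly.
strain_core <- function(Vr, Vc, triangles, long_axis = c(0, 0, 1),
                        area_eps = 1e-9) {
  i1 <- triangles[, 1L]; i2 <- triangles[, 2L]; i3 <- triangles[, 3L]
  a1 <- Vr[i2, , drop = FALSE] - Vr[i1, , drop = FALSE]
  a2 <- Vr[i3, , drop = FALSE] - Vr[i1, , drop = FALSE]
  cr <- vcross(a1, a2)
  two_ar <- sqrt(rowSums(cr * cr))
  ref_area <- two_ar / 2
  nhat <- cr / pmax(two_ar, .Machine$double.xmin)

  L <- matrix(long_axis / sqrt(sum(long_axis^2)), nrow(triangles), 3L,
              byrow = TRUE)
  proj <- L - nhat * rowSums(L * nhat)
  pl <- sqrt(rowSums(proj * proj))
  fallback <- pl < 1e-6
  if (any(fallback)) {
    a3 <- Vr[i3[fallback], , drop = FALSE] - Vr[i2[fallback], , drop = FALSE]
    e1 <- a1[fallback, , drop = FALSE]; e2 <- a2[fallback, , drop = FALSE]
    l1 <- rowSums(e1 * e1); l2 <- rowSums(e2 * e2); l3 <- rowSums(a3 * a3)
    pick <- cbind(l1, l2, l3)
    best <- max.col(pick, ties.method = "first")
    eb <- e1; eb[best == 2L, ] <- e2[best == 2L, , drop = FALSE]
    eb[best == 3L, ] <- a3[best == 3L, , drop = FALSE]
    proj[fallback, ] <- eb
    pl[fallback] <- sqrt(rowSums(eb * eb))
  }
  u1 <- proj / pl
  # re-orthogonalize against the normal, then complete the frame
  u1 <- u1 - nhat * rowSums(u1 * nhat)
  u1 <- u1 / sqrt(rowSums(u1 * u1))
  u2 <- vcross(nhat, u1)

  r11 <- rowSums(a1 * u1); r12 <- rowSums(a2 * u1)
  r21 <- rowSums(a1 * u2); r22 <- rowSums(a2 * u2)
  detr <- r11 * r22 - r12 * r21

  b1 <- Vc[i2, , drop = FALSE] - Vc[i1, , drop = FALSE]
  b2 <- Vc[i3, , drop = FALSE] - Vc[i1, , drop = FALSE]
  cc <- vcross(b1, b2)
  two_ac <- sqrt(rowSums(cc * cc))
  nb1 <- sqrt(rowSums(b1 * b1))
  w1 <- b1 / pmax(nb1, .Machine$double.xmin)
  w2 <- vcross(cc / pmax(two_ac, .Machine$double.xmin), w1)
  c11 <- nb1; c12 <- rowSums(b2 * w1); c22 <- rowSums(b2 * w2)

  masked <- ref_area < area_eps | two_ac / 2 < area_eps | abs(detr) < area_eps

  f11 <- (c11 * r22 - c12 * r21) / detr
  f12 <- (c12 * r11 - c11 * r12) / detr
  f21 <- -c22 * r21 / detr
  f22 <- c22 * r11 / detr

  C11 <- f11^2 + f21^2
  C12 <- f11 * f12 + f21 * f22
  C22 <- f12^2 + f22^2
  m <- (C11 + C22) / 2
  r <- sqrt(pmax(((C11 - C22) / 2)^2 + C12^2, 0))
  mu_p <- sqrt(pmax(m - r, 0))
  mu_s <- sqrt(pmax(m + r, 0))

  # eigenvector of C for the smaller eigenvalue, with a longitudinal
  # tie-break when the stretch is isotropic
  v1a <- C12; v2a <- (m - r) - C11
  v1b <- (m - r) - C22; v2b <- C12
  na_ <- sqrt(v1a^2 + v2a^2); nb_ <- sqrt(v1b^2 + v2b^2)
  useb <- nb_ > na_
  q1 <- ifelse(useb, v1b, v1a); q2 <- ifelse(useb, v2b, v2a)
  qn <- sqrt(q1^2 + q2^2)
  tie <- qn < 1e-12 * pmax(mu_s, 1)
  q1 <- ifelse(tie, 1, q1 / pmax(qn, .Machine$double.xmin))
  q2 <- ifelse(tie, 0, q2 / pmax(qn, .Machine$double.xmin))

  U11 <- mu_p * q1^2 + mu_s * q2^2
  U22 <- mu_p * q2^2 + mu_s * q1^2
  U12 <- (mu_p - mu_s) * q1 * q2

  dir3 <- u1 * q1 + u2 * q2
  nd <- sqrt(rowSums(dir3 * dir3))
  dir3 <- dir3 / pmax(nd, .Machine$double.xmin)

  set_na <- function(x) { x[masked] <- NA_real_; x }
  list(lambda_p = set_na(mu_p - 1), lambda_s = set_na(mu_s - 1),
       S11 = set_na(U11 - 1), S22 = set_na(U22 - 1), S12 = set_na(U12),
       dir = dir3, ref_area = ref_area, masked = masked,
       u1 = u1, u2 = u2, nhat = nhat)
}

vcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' In-plane deformation gradient and Lagrangian strain of one triangle
#'
#' Maps reference edge vectors (in an orthonormal tangent frame) to current
#' edge vectors, removes the rotation by polar decomposition and returns the
#' strain S = U - I, where U = sqrt(F'F) is the right stretch tensor.
#'
#' @param ref,cur 3x3 matrices, rows = the triangle's vertices (mm).
#' @param long_axis global direction whose in-plane projection defines the
#'   first local basis vector.
#' @return object of class `triangle_strain`: `F`, `U`, `S` (2x2 matrices in
#'   the local frame), `eigenvalues` (`lambda_p <= lambda_s`), `direction`
#'   (3D principal-strain direction), and the local basis (`u1`, `u2`,
#'   `normal`).
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' triangle_deformation_gradient(tri, 0.7 * tri)$eigenvalues  # both -0.3
#' @export
triangle_deformation_gradient <- function(ref, cur, long_axis = c(0, 0, 1)) {
  stopifnot(is.matrix(ref), is.matrix(cur), dim(ref) == c(3L, 3L),
            dim(cur) == c(3L, 3L))
  k <- strain_core(ref, cur, matrix(1:3, 1L), long_axis)
  if (k$masked[1L]) stop("degenerate triangle (zero area)")
  lam <- c(lambda_p = k$lambda_p[1L], lambda_s = k$lambda_s[1L])
  S <- matrix(c(k$S11[1L], k$S12[1L], k$S12[1L], k$S22[1L]), 2L)
  structure(list(S = S, U = S + diag(2L),
                 eigenvalues = lam, direction = k$dir[1L, ],
                 u1 = k$u1[1L, ], u2 = k$u2[1L, ], normal = k$nhat[1L, ]),
            class = "triangle_strain")
}

#' Normal strain along a tangent direction
#'
#' Evaluates e' S e for a unit direction `e` expressed in the triangle's
#' local tangent frame.
#'
#' @param x a `triangle_strain` (from [triangle_deformation_gradient()]) or a
#'   `surface_strain_field` (from [principal_strain_field()]).
#' @param direction 3D direction; for a single triangle it must be tangent to
#'   the reference plane within `tol` (radians of elevation); for a field it
#'   is projected onto every triangle plane.
#' @param tol tangency tolerance for the single-triangle method.
#' @param ... unused.
#' @return scalar (triangle) or per-triangle vector (field) of normal strain.
#' @export
directional_strain <- function(x, direction, ...) UseMethod("directional_strain")

#' @rdname directional_strain
#' @export
directional_strain.triangle_strain <- function(x, direction, tol = 1e-3, ...) {
  d <- direction / sqrt(sum(direction^2))
  if (abs(sum(d * x$normal)) > tol)
    stop("direction is not tangent to the triangle plane")
  e <- c(sum(d * x$u1), sum(d * x$u2))
  e <- e / sqrt(sum(e^2))
  as.numeric(t(e) %*% x$S %*% e)
}

#' @rdname directional_strain
#' @export
directional_strain.surface_strain_field <- function(x, direction, ...) {
  k <- attr(x, "core")
  d <- direction / sqrt(sum(direction^2))
  e1 <- rowSums(sweep(k$u1, 2L, d, "*"))
  e2 <- rowSums(sweep(k$u2, 2L, d, "*"))
  nn <- sqrt(e1^2 + e2^2)
  e1 <- e1 / nn; e2 <- e2 / nn
  e1^2 * k$S11 + 2 * e1 * e2 * k$S12 + e2^2 * k$S22
}

#' Per-triangle principal strain field at one frame
#'
#' Lagrangian strain of every triangle relative to the end-diastolic
#' reference configuration (the frame of maximum volume, unless overridden).
#'
#' @param mesh a registered [mesh_sequence()].
#' @param frame frame index to evaluate.
#' @param ref_frame reference frame index (default: frame of maximum volume).
#' @param long_axis global longitudinal direction (registered: +z).
#' @param max_masked_area maximum tolerated masked fraction of reference area.
#' @return A data.frame of class `surface_strain_field` with per-triangle
#'   `lambda_p`, `lambda_s` (dimensionless), longitudinal/circumferential
#'   normal strains, the 3D principal direction, reference areas and the
#'   `cap`/`masked` flags. The strain kernel output is attached as attribute
#'   `"core"`.
#' @export
principal_strain_field <- function(mesh, frame, ref_frame = NULL,
                                   long_axis = c(0, 0, 1),
                                   max_masked_area = 0.01) {
  if (is.null(ref_frame)) ref_frame <- which.max(mesh_volume(mesh))
  k <- strain_core(frame_vertices(mesh, ref_frame),
                   frame_vertices(mesh, frame), mesh$triangles, long_axis)
  mfrac <- sum(k$ref_area[k$masked]) / sum(k$ref_area)
  if (mfrac > max_masked_area)
    stop(sprintf("%.1f%% of reference area is degenerate (limit %.1f%%)",
                 100 * mfrac, 100 * max_masked_area))
  out <- data.frame(triangle = seq_len(nrow(mesh$triangles)),
                    lambda_p = k$lambda_p, lambda_s = k$lambda_s,
                    long_strain = k$S11, circ_strain = k$S22,
                    dir_x = k$dir[, 1L], dir_y = k$dir[, 2L],
                    dir_z = k$dir[, 3L],
                    ref_area = k$ref_area, cap = mesh$cap, masked = k$masked)
  attr(out, "core") <- k
  attr(out, "frame") <- frame
  attr(out, "ref_frame") <- ref_frame
  class(out) <- c("surface_strain_field", class(out))
  out
}

#' Global strain time courses (GPS, GSS, GLS, GCS)
#'
#' Reference-area-weighted spatial means of the per-triangle principal
#' (most negative) and secondary strain eigenvalues and of the normal strains
#' along the local longitudinal and circumferential directions, for every
#' frame, relative to the end-diastolic reference. Reported in percent
#' (negative = shortening). Cap triangles (the virtual basal closure, not
#' myocardium) are excluded by default.
#'
#' @inheritParams principal_strain_field
#' @param include_cap include basal-cap triangles in the averages.
#' @return data.frame of class `global_strain_series` with columns `time`,
#'   `frame`, `GPS`, `GSS`, `GLS`, `GCS` (%).
#' @export
global_strain_series <- function(mesh, ref_frame = NULL,
                                 long_axis = c(0, 0, 1), include_cap = FALSE) {
  if (is.null(ref_frame)) ref_frame <- which.max(mesh_volume(mesh))
  Vr <- frame_vertices(mesh, ref_frame)
  nf <- n_frames(mesh)
  keep0 <- if (include_cap) rep(TRUE, nrow(mesh$triangles)) else !mesh$cap
  rows <- lapply(seq_len(nf), function(f) {
    k <- strain_core(Vr, frame_vertices(mesh, f), mesh$triangles, long_axis)
    keep <- keep0 & !k$masked
    w <- k$ref_area[keep]; w <- w / sum(w)
    c(GPS = sum(w * k$lambda_p[keep]), GSS = sum(w * k$lambda_s[keep]),
      GLS = sum(w * k$S11[keep]), GCS = sum(w * k$S22[keep]))
  })
  m <- do.call(rbind, rows) * 100
  out <- data.frame(time = mesh$times, frame = seq_len(nf), m)
  attr(out, "ref_frame") <- ref_frame
  class(out) <- c("global_strain_series", class(out))
  out
}

#' @export
print.global_strain_series <- function(x, ...) {
  es <- which.min(x$GPS)
  cat(sprintf(paste0("global_strain_series: %d frames (reference frame %d)\n",
                     "  at GPS minimum (frame %d): GPS %.1f%%, GSS %.1f%%, ",
                     "GLS %.1f%%, GCS %.1f%%\n"),
              nrow(x), attr(x, "ref_frame"), es,
              x$GPS[es], x$GSS[es], x$GLS[es], x$GCS[es]))
  invisible(x)
}

#' @export
plot.global_strain_series <- function(x, ...) {
  graphics::matplot(x$time, as.matrix(x[, c("GPS", "GSS", "GLS", "GCS")]),
                    type = "l", lty = 1, col = c(4, 2, 3, 6),
                    xlab = "time [s]", ylab = "strain [%]", ...)
  graphics::legend("bottomleft", c("GPS", "GSS", "GLS", "GCS"),
                   col = c(4, 2, 3, 6), lty = 1, bty = "n")
  invisible(x)
}
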