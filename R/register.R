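#' Register a mesh sequence to the anatomical frame
#'
#' Applies one rigid transform (computed at end diastole) to every frame:
#' the area-weighted surface centroid at ED is translated to the origin, the
#' long axis (annulus center to apex at ED) is aligned with -z (apex down,
#' base up), and the roll about z is fixed so the aortic orifice center
#' projects into the +x half-plane. Volume is exactly invariant under the
#' transform.
#'
#' @param mesh a [mesh_sequence()].
#' @param lm a [landmarks()] object with per-frame positions.
#' @return list with the transformed `mesh`, transformed `landmarks`, and
#'   `transform`, a 4x4 row-major rigid transform mapping input to registered
#'   coordinates.
#' @export
register_sequence <- function(mesh, lm) {
  stopifnot(inherits(mesh, "mesh_sequence"), inherits(lm, "landmarks"))
  V <- mesh_volume(mesh)
  ed <- which.max(V)
  ctr <- surface_centroid(frame_vertices(mesh, ed), mesh$triangles)
  axis <- lm$apex[ed, ] - lm$annulus_center[ed, ]
  la <- sqrt(sum(axis^2))
  if (la < 1e-9) stop("degenerate long axis: apex coincides with annulus center")
  axis <- axis / la
  R1 <- rotation_between(axis, c(0, 0, -1))
  ao <- as.numeric(R1 %*% (lm$aortic_center[ed, ] - ctr))
  roll <- atan2(ao[2L], ao[1L])
  Rz <- matrix(c(cos(roll), -sin(roll), 0, sin(roll), cos(roll), 0, 0, 0, 1),
               3L, 3L)
  R <- Rz %*% R1

  nf <- n_frames(mesh)
  verts <- mesh$vertices
  for (f in seq_len(nf))
    verts[, , f] <- sweep(frame_vertices(mesh, f), 2L, ctr) %*% t(R)
  tr <- function(m) sweep(m, 2L, ctr) %*% t(R)
  out_lm <- landmarks(tr(lm$annulus_center), tr(lm$aortic_center), tr(lm$apex))
  Tmat <- rbind(cbind(R, -as.numeric(R %*% ctr)), c(0, 0, 0, 1))
  list(mesh = mesh_sequence(verts, mesh$triangles, mesh$times, mesh$period,
                            cap = mesh$cap, aortic = mesh$aortic,
                            validate = FALSE),
       landmarks = out_lm, transform = Tmat)
}

# minimal rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3L))
    # opposite: rotate pi about any axis orthogonal to a
    w <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- w - sum(w * a) * a; w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3L))
  }
  vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3L) + vx + vx %*% vx / (1 + c_)
}

#' Resample a mesh sequence to uniform phase points
#'
#' Periodic cubic-spline interpolation of every vertex trajectory (and the
#' landmarks) onto `n_out` uniformly spaced phase fractions of the cycle.
#' Used to harmonize frame counts across subjects before averaging and to
#' provide the uniform time grid required by spectral differentiation.
#'
#' @param mesh a [mesh_sequence()].
#' @param n_out number of output frames (>= 10).
#' @param lm optional [landmarks()] to resample alongside.
#' @return a [mesh_sequence()] (or `list(mesh, landmarks)` when `lm` given).
#' @export
resample_cycle <- function(mesh, n_out, lm = NULL) {
  n_out <- as.integer(n_out)
  if (n_out < 10L) stop("n_out must be >= 10 frames per cycle")
  ph_in <- c(mesh$times, mesh$period) / mesh$period
  ph_out <- (seq_len(n_out) - 1L) / n_out
  nv <- dim(mesh$vertices)[1L]
  nf <- n_frames(mesh)
  verts <- array(0, dim = c(nv, 3L, n_out))
  # one periodic spline per vertex coordinate
  flat <- matrix(aperm(mesh$vertices, c(3L, 1L, 2L)), nrow = nf)   # nf x (nv*3)
  res <- apply(flat, 2L, function(y)
    stats::spline(ph_in, c(y, y[1L]), method = "periodic", xout = ph_out)$y)
  verts <- aperm(array(res, dim = c(n_out, nv, 3L)), c(2L, 3L, 1L))
  out <- mesh_sequence(verts, mesh$triangles, ph_out * mesh$period, mesh$period,
                       cap = mesh$cap, aortic = mesh$aortic, validate = FALSE)
  if (is.null(lm)) return(out)
  rs <- function(m) apply(m, 2L, function(y)
    stats::spline(ph_in, c(y, y[1L]), method = "periodic", xout = ph_out)$y)
  list(mesh = out, landmarks = landmarks(rs(lm$annulus_center),
                                         rs(lm$aortic_center), rs(lm$apex)))
}

#' Vertex-wise average of registered mesh sequences
#'
#' All sequences must share the triangle table and frame count (resample
#' first with [resample_cycle()]); frames are identified by phase fraction
#' and averaged vertex-wise, with the period averaged across subjects.
#'
#' @param seqs list of registered [mesh_sequence()] objects.
#' @return a [mesh_sequence()].
#' @export
average_cohort <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  t0 <- seqs[[1L]]$triangles
  nf <- n_frames(seqs[[1L]])
  for (s in seqs) {
    if (!identical(dim(s$triangles), dim(t0)) || !all(s$triangles == t0))
      stop("topology mismatch across sequences")
    if (n_frames(s) != nf)
      stop("frame-count mismatch: resample sequences to a common frame count first")
  }
  acc <- array(0, dim = dim(seqs[[1L]]$vertices))
  for (s in seqs) acc <- acc + s$vertices
  acc <- acc / length(seqs)
  period <- mean(vapply(seqs, `[[`, numeric(1), "period"))
  ph <- seqs[[1L]]$times / seqs[[1L]]$period
  mesh_sequence(acc, t0, ph * period, period,
                cap = seqs[[1L]]$cap, aortic = seqs[[1L]]$aortic,
                validate = FALSE)
}
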