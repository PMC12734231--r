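#' Time-resolved triangulated endocardial surface
#'
#' A `mesh_sequence` holds one cardiac cycle of a closed triangulated surface
#' with fixed connectivity: an `nv x 3 x nf` array of vertex positions (mm),
#' an `nt x 3` integer triangle table (outward-oriented), strictly increasing
#' frame times (s) starting at 0, and the heartbeat period `T` (s). Optional
#' logical per-triangle markers flag the basal cap and the aortic orifice
#' sub-region of the cap.
#'
#' @param vertices numeric array `nv x 3 x nf` (or a list of `nv x 3`
#'   matrices), coordinates in mm.
#' @param triangles integer matrix `nt x 3`, 1-based vertex indices, oriented
#'   so triangle normals point out of the cavity.
#' @param times numeric vector of frame times in seconds; `times[1]` must be 0
#'   and `times[nf] < period`.
#' @param period heartbeat period T in seconds.
#' @param cap optional logical vector of length `nt`: triangles closing the
#'   basal (mitral/aortic) plane.
#' @param aortic optional logical vector of length `nt`: cap triangles that
#'   form the aortic orifice patch.
#' @param validate check watertightness and topology (default TRUE).
#' @return An object of class `mesh_sequence`.
#' @seealso [mesh_volume()], [volume_curve()], [register_sequence()]
#' @export
mesh_sequence <- function(vertices, triangles, times, period,
                          cap = NULL, aortic = NULL, validate = TRUE) {
  if (is.list(vertices)) {
    nv <- nrow(vertices[[1L]])
    vertices <- array(unlist(vertices, use.names = FALSE),
                      dim = c(nv, 3L, length(vertices)))
  }
  stopifnot(is.array(vertices), length(dim(vertices)) == 3L, dim(vertices)[2L] == 3L)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  nf <- dim(vertices)[3L]
  times <- as.numeric(times)
  if (length(times) != nf)
    stop("length(times) must equal the number of frames")
  if (any(diff(times) <= 0) || abs(times[1L]) > 1e-12)
    stop("times must be strictly increasing and start at 0")
  if (!is.numeric(period) || period <= times[nf])
    stop("period must exceed the last frame time")
  nt <- nrow(triangles)
  if (is.null(cap)) cap <- rep(FALSE, nt)
  if (is.null(aortic)) aortic <- rep(FALSE, nt)
  x <- structure(list(vertices = vertices, triangles = triangles,
                      times = times, period = period,
                      cap = as.logical(cap), aortic = as.logical(aortic)),
                 class = "mesh_sequence")
  if (validate) {
    if (max(triangles) > dim(vertices)[1L] || min(triangles) < 1L)
      stop("triangle indices out of range")
    if (!is_watertight(triangles))
      stop("surface is not watertight (every edge must be shared by exactly two triangles with opposite orientation)")
  }
  x
}

#' @export
print.mesh_sequence <- function(x, ...) {
  d <- dim(x$vertices)
  cat(sprintf("mesh_sequence: %d vertices, %d triangles, %d frames, T = %.4g s\n",
              d[1L], nrow(x$triangles), d[3L], x$period))
  v <- vapply(seq_len(d[3L]), function(i) mesh_volume(frame_vertices(x, i), x$triangles),
              numeric(1))
  cat(sprintf("  volume range [%.1f, %.1f] mL\n", min(v), max(v)))
  invisible(x)
}

#' @export
format.mesh_sequence <- function(x, ...) {
  d <- dim(x$vertices)
  sprintf("<mesh_sequence %dv/%dt/%df>", d[1L], nrow(x$triangles), d[3L])
}

n_frames <- function(mesh) dim(mesh$vertices)[3L]

#' Extract the vertex matrix of one frame
#'
#' @param mesh a [mesh_sequence()]
#' @param frame frame index
#' @return `nv x 3` numeric matrix (mm).
#' @export
frame_vertices <- function(mesh, frame) {
  mesh$vertices[, , frame, drop = TRUE]
}

#' Check that a triangle table describes a closed orientable surface
#'
#' Every undirected edge must appear in exactly two triangles, once in each
#' direction (consistent outward orientation).
#'
#' @param triangles `nt x 3` integer matrix.
#' @return logical scalar.
#' @export
is_watertight <- function(triangles) {
  tm <- matrix(as.integer(triangles), ncol = 3L)
  he <- rbind(tm[, c(1L, 2L)], tm[, c(2L, 3L)], tm[, c(3L, 1L)])
  key <- paste(he[, 1L], he[, 2L])          # directed half-edges
  if (anyDuplicated(key) > 0L) return(FALSE)
  rkey <- paste(he[, 2L], he[, 1L])
  all(rkey %in% key)
}

# Cross products of edge vectors: per-triangle area vectors (n * dS, outward).
triangle_area_vectors <- function(V, triangles) {
  a <- V[triangles[, 1L], , drop = FALSE]
  e1 <- V[triangles[, 2L], , drop = FALSE] - a
  e2 <- V[triangles[, 3L], , drop = FALSE] - a
  0.5 * cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

triangle_areas <- function(V, triangles) {
  av <- triangle_area_vectors(V, triangles)
  sqrt(rowSums(av * av))
}

triangle_centroids <- function(V, triangles) {
  (V[triangles[, 1L], , drop = FALSE] +
   V[triangles[, 2L], , drop = FALSE] +
   V[triangles[, 3L], , drop = FALSE]) / 3
}

#' Enclosed volume of a closed triangulated surface
#'
#' Signed divergence-theorem volume, `V = (1/6) * sum det(v1, v2, v3)` over
#' triangles, positive for outward orientation. Input coordinates are in mm;
#' the volume is returned in mL.
#'
#' @param x a vertex matrix (`nv x 3`, mm) or a [mesh_sequence()].
#' @param triangles triangle table when `x` is a matrix; ignored otherwise.
#' @param frame frame index when `x` is a `mesh_sequence` (default all frames).
#' @param orientation `"error"` rejects a negative (inward-oriented) volume;
#'   `"signed"` returns it as-is.
#' @return volume in mL (vector over frames for a sequence).
#' @examples
#' s <- uv_sphere(1, n_theta = 64, n_phi = 32)   # unit sphere, radius in mm
#' mesh_volume(s$vertices, s$triangles) * 1000   # ~ 4*pi/3 mm^3
#' @export
mesh_volume <- function(x, triangles = NULL, frame = NULL,
                        orientation = c("error", "signed")) {
  orientation <- match.arg(orientation)
  if (inherits(x, "mesh_sequence")) {
    idx <- if (is.null(frame)) seq_len(n_frames(x)) else frame
    v <- vapply(idx, function(i)
      mesh_volume(frame_vertices(x, i), x$triangles, orientation = orientation),
      numeric(1))
    return(if (length(v) == 1L) v[[1L]] else v)
  }
  stopifnot(is.matrix(x), ncol(x) == 3L, !is.null(triangles))
  a <- x[triangles[, 1L], , drop = FALSE]
  b <- x[triangles[, 2L], , drop = FALSE]
  c_ <- x[triangles[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
          a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
          a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  vol <- sum(det6) / 6 / 1000                       # mm^3 -> mL
  if (orientation == "error" && vol <= 0)
    stop("negative enclosed volume: surface appears inward-oriented")
  vol
}

#' Area-weighted surface centroid
#'
#' @param V vertex matrix `nv x 3`.
#' @param triangles triangle table.
#' @return length-3 numeric vector.
#' @export
surface_centroid <- function(V, triangles) {
  w <- triangle_areas(V, triangles)
  ctr <- triangle_centroids(V, triangles)
  colSums(ctr * w) / sum(w)
}

#' Anatomical landmark trajectories
#'
#' Per-frame positions (mm) of the mitral annulus center, the aortic orifice
#' center and the apex.
#'
#' @param annulus_center,aortic_center,apex `nf x 3` matrices.
#' @return object of class `landmarks`.
#' @export
landmarks <- function(annulus_center, aortic_center, apex) {
  as_m <- function(m) matrix(as.numeric(m), ncol = 3L)
  x <- list(annulus_center = as_m(annulus_center),
            aortic_center = as_m(aortic_center), apex = as_m(apex))
  if (!all(vapply(x, function(m) all(is.finite(m)), logical(1))))
    stop("landmarks must be finite")
  if (any(sqrt(rowSums((x$apex - x$annulus_center)^2)) < 1e-9))
    stop("apex coincides with annulus center")
  structure(x, class = "landmarks")
}
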