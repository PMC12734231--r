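# minimal ASCII PLY writer/reader for triangle meshes (full double precision,
# so sequences round-trip losslessly)
write_ply <- function(V, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", V[, 1L], V[, 2L], V[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", triangles[, 1L] - 1L,
                     triangles[, 2L] - 1L, triangles[, 3L] - 1L), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "ply") stop("not a PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1L]))
  h <- which(lines == "end_header")[1L]
  vl <- lines[(h + 1L):(h + nv)]
  V <- matrix(scan(text = vl, quiet = TRUE), ncol = 3L, byrow = TRUE)
  fl <- lines[(h + nv + 1L):(h + nv + nf)]
  f <- matrix(scan(text = fl, quiet = TRUE), ncol = 4L, byrow = TRUE)
  if (any(f[, 1L] != 3)) stop("non-triangular face in ", path)
  list(vertices = V, triangles = f[, 2:4, drop = FALSE] + 1L)
}

#' Write a mesh sequence to disk
#'
#' One ASCII PLY file per frame plus a JSON sidecar holding the period,
#' frame times, per-frame landmarks, cap/aortic triangle markers, and any
#' phase / subject / seed / spec metadata. Optionally writes the
#' ground-truth volume waveform as CSV (time, volume, dVdt).
#'
#' @param mesh a [mesh_sequence()].
#' @param lm a [landmarks()] object.
#' @param dir output directory (created if needed).
#' @param truth optional list with `times`, `V`, `dVdt` (and optionally the
#'   generating `spec`) as produced by [generate_ventricle_sequence()].
#' @param phase,subject,seed optional metadata recorded in the sidecar.
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_mesh_sequence <- function(mesh, lm, dir, truth = NULL, phase = NULL,
                                subject = NULL, seed = NULL, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L) {
    if (!force)
      stop("output directory exists and is not empty (use force = TRUE): ", dir)
    unlink(list.files(dir, pattern = "^frame_\\d+\\.ply$", full.names = TRUE))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf <- n_frames(mesh)
  for (f in seq_len(nf))
    write_ply(frame_vertices(mesh, f), mesh$triangles,
              file.path(dir, sprintf("frame_%03d.ply", f)))
  side <- list(format = "lvmech-mesh-sequence-1",
               period = mesh$period, times = mesh$times, n_frames = nf,
               cap = which(mesh$cap), aortic = which(mesh$aortic),
               landmarks = list(annulus_center = lm$annulus_center,
                                aortic_center = lm$aortic_center,
                                apex = lm$apex),
               phase = phase, subject = subject, seed = seed,
               spec = if (!is.null(truth$spec)) unclass(truth$spec) else NULL)
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(truth))
    utils::write.csv(data.frame(time = truth$times, volume = truth$V,
                                dVdt = truth$dVdt),
                     file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a mesh sequence from disk
#'
#' Reads the PLY frames and JSON sidecar written by
#' [write_mesh_sequence()], validating that connectivity is identical
#' across frames and that the surface is watertight. Sequences with fewer
#' than 10 frames per cycle are accepted with a QC warning flag.
#'
#' @param dir directory containing `frame_*.ply` and `sidecar.json`.
#' @return list with `mesh`, `landmarks`, `meta` (phase/subject/seed/spec)
#'   and `qc_warning` (TRUE when the frame count is below 10).
#' @export
read_mesh_sequence <- function(dir) {
  sc_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sc_path)) stop("missing sidecar.json in ", dir)
  side <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.ply$", full.names = TRUE))
  if (length(files) != side$n_frames)
    stop(sprintf("sidecar announces %d frames but %d PLY files found",
                 side$n_frames, length(files)))
  frames <- lapply(files, read_ply)
  t0 <- frames[[1L]]$triangles
  for (i in seq_along(frames)[-1L])
    if (!identical(dim(frames[[i]]$triangles), dim(t0)) ||
        any(frames[[i]]$triangles != t0))
      stop("topology mismatch: frame ", i, " connectivity differs from frame 1")
  nt <- nrow(t0)
  cap <- aortic <- rep(FALSE, nt)
  cap[unlist(side$cap)] <- TRUE
  aortic[unlist(side$aortic)] <- TRUE
  verts <- array(unlist(lapply(frames, `[[`, "vertices")),
                 dim = c(nrow(frames[[1L]]$vertices), 3L, length(frames)))
  mesh <- mesh_sequence(verts, t0, side$times, side$period,
                        cap = cap, aortic = aortic)
  if (is.null(side$landmarks)) stop("missing landmarks in sidecar")
  as_m <- function(m) matrix(unlist(m), ncol = 3L)
  lm <- landmarks(as_m(side$landmarks$annulus_center),
                  as_m(side$landmarks$aortic_center),
                  as_m(side$landmarks$apex))
  qc <- side$n_frames < 10L
  if (qc) warning("sequence has fewer than 10 frames per cardiac cycle")
  list(mesh = mesh, landmarks = lm,
       meta = side[c("phase", "subject", "seed", "spec")], qc_warning = qc)
}
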