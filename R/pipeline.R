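#' Pipeline run configuration
#'
#' Validated configuration for the simulate / analyze / report pipeline.
#' Unknown fields and malformed values are rejected with the offending
#' field named.
#'
#' @param seed master seed for cohort sampling.
#' @param n_subjects exercise-cohort size.
#' @param n_controls size of the resting reference cohort (0 to skip).
#' @param phases exercise phases to simulate.
#' @param phase_table per-phase parameter table ([default_phase_table()]).
#' @param n_theta,n_phi mesh resolution.
#' @param twist_deg,long_circ_split deformation parameters.
#' @param mv_area effective mitral orifice area (mm^2).
#' @param rho,g force-normalization constants.
#' @param harmonics optional Fourier truncation for wall velocities.
#' @return validated list of class `lv_config`.
#' @export
lv_config <- function(seed = 1L, n_subjects = 19L, n_controls = 0L,
                      phases = setdiff(phase_labels, "Control"),
                      phase_table = default_phase_table(),
                      n_theta = 40L, n_phi = 20L,
                      twist_deg = 10, long_circ_split = 0.25,
                      mv_area = 400, rho = 1060, g = 9.81, harmonics = NULL) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              n_controls = as.integer(n_controls), phases = phases,
              phase_table = phase_table, n_theta = as.integer(n_theta),
              n_phi = as.integer(n_phi), twist_deg = twist_deg,
              long_circ_split = long_circ_split, mv_area = mv_area,
              rho = rho, g = g, harmonics = harmonics)
  validate_config(cfg)
  structure(cfg, class = "lv_config")
}

validate_config <- function(cfg) {
  need <- c("seed", "n_subjects", "n_controls", "phases", "phase_table",
            "n_theta", "n_phi", "twist_deg", "long_circ_split", "mv_area",
            "rho", "g")
  for (f in need) if (is.null(cfg[[f]]))
    stop("config field missing: ", f)
  extra <- setdiff(names(cfg), c(need, "harmonics"))
  if (length(extra)) stop("unknown config field(s): ", paste(extra, collapse = ", "))
  if (cfg$n_subjects < 2L) stop("config field n_subjects: must be >= 2")
  bad <- setdiff(cfg$phases, phase_labels)
  if (length(bad)) stop("config field phases: unknown phase(s) ",
                        paste(bad, collapse = ", "))
  needed_cols <- c("phase", "HR_mean", "HR_sd", "EDV_mean", "EDV_sd",
                   "ESV_mean", "ESV_sd", "e_a_ratio", "n_frames")
  miss <- setdiff(needed_cols, names(cfg$phase_table))
  if (length(miss)) stop("config field phase_table: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (cfg$mv_area <= 0) stop("config field mv_area: must be positive")
  invisible(TRUE)
}

#' Simulate a synthetic exercise-study dataset on disk
#'
#' Generates the cohort defined by the config (and optionally a control
#' cohort recorded at Rest-like conditions under the `Control` label),
#' writes every sequence as PLY frames + sidecar + ground-truth CSV under
#' `out_dir/<subject>/<phase>/`, and records a manifest with the seed,
#' config and entry list. Fully reproducible from the seed.
#'
#' @param config an [lv_config()].
#' @param out_dir output dataset directory.
#' @param force overwrite an existing dataset.
#' @return path to the manifest, invisibly.
#' @export
run_simulate <- function(config = lv_config(), out_dir, force = FALSE) {
  validate_config(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("dataset already exists (use force = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- generate_cohort(config$n_subjects, config$phase_table,
                          seed = config$seed, phases = config$phases,
                          n_theta = config$n_theta, n_phi = config$n_phi,
                          twist_deg = config$twist_deg,
                          long_circ_split = config$long_circ_split)
  if (config$n_controls >= 2L) {
    recs <- c(recs, generate_cohort(config$n_controls, config$phase_table,
                                    seed = config$seed + 1L,
                                    phases = "Control",
                                    n_theta = config$n_theta,
                                    n_phi = config$n_phi,
                                    twist_deg = config$twist_deg,
                                    long_circ_split = config$long_circ_split,
                                    subject_prefix = "C"))
  }
  entries <- list()
  for (r in recs) {
    d <- file.path(out_dir, r$subject, r$phase)
    write_mesh_sequence(r$data$mesh, r$data$landmarks, d,
                        truth = r$data$truth, phase = r$phase,
                        subject = r$subject, seed = config$seed,
                        force = force)
    entries[[length(entries) + 1L]] <-
      list(subject = r$subject, phase = r$phase,
           path = file.path(r$subject, r$phase))
  }
  cfg <- unclass(config)
  cfg$phase_table <- NULL
  jsonlite::write_json(list(format = "lvmech-dataset-1", seed = config$seed,
                            config = cfg,
                            phase_table = config$phase_table,
                            entries = entries),
                       manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(manifest_path)
}

#' Analyze a simulated dataset
#'
#' Runs [lv_mechanics()] on every entry of the dataset manifest. Per-subject
#' failures are quarantined (logged with the error message) and the run
#' continues; sequences with fewer than 10 frames are analyzed but flagged.
#'
#' @param data_dir dataset directory containing `manifest.json`.
#' @param out_dir optional directory for per-subject CSV artifacts and the
#'   cohort table.
#' @return list of class `lv_analysis`: `table` (a [cohort_table()]),
#'   `fits` (named list of [lv_mechanics()] objects), `quarantined`,
#'   `qc_flags`, and `manifest_md5`.
#' @export
run_analyze <- function(data_dir, out_dir = NULL) {
  manifest_path <- file.path(data_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("missing manifest.json in ", data_dir)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  rows <- list(); fits <- list(); quarantined <- list(); qc <- character(0)
  for (i in seq_len(nrow(man$entries))) {
    e <- man$entries[i, ]
    key <- paste(e$subject, e$phase, sep = "/")
    res <- tryCatch({
      ds <- withCallingHandlers(
        read_mesh_sequence(file.path(data_dir, e$path)),
        warning = function(w) {
          qc <<- c(qc, key)
          invokeRestart("muffleWarning")
        })
      fit <- suppressWarnings(
        lv_mechanics(ds$mesh, ds$landmarks, mv_area = cfg$mv_area,
                     rho = cfg$rho, g = cfg$g))
      cf <- coef(fit)
      list(fit = fit,
           rows = data.frame(subject = e$subject, phase = e$phase,
                             metric = names(cf), value = unname(cf)))
    }, error = function(err) err)
    if (inherits(res, "error")) {
      quarantined[[key]] <- conditionMessage(res)
    } else {
      fits[[key]] <- res$fit
      rows[[length(rows) + 1L]] <- res$rows
    }
  }
  if (!length(rows)) stop("no analyzable sequences in ", data_dir)
  long <- do.call(rbind, rows)
  long <- long[is.finite(long$value), , drop = FALSE]
  tab <- cohort_table(long$subject, long$phase, long$metric, long$value)
  out <- structure(list(table = tab, fits = fits, quarantined = quarantined,
                        qc_flags = unique(qc),
                        manifest_md5 = unname(tools::md5sum(manifest_path))),
                   class = "lv_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "cohort_table.csv"),
                     row.names = FALSE)
    for (key in names(fits)) {
      f <- fits[[key]]
      base <- gsub("/", "_", key)
      utils::write.csv(data.frame(time = f$volume$times, V = f$volume$V,
                                  dVdt = f$volume$dVdt),
                       file.path(out_dir, paste0(base, "_volume.csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(f$strain),
                       file.path(out_dir, paste0(base, "_strain.csv")),
                       row.names = FALSE)
      utils::write.csv(data.frame(time = f$hdf$times, fx = f$hdf$f[, 1L],
                                  fy = f$hdf$f[, 2L], fz = f$hdf$f[, 3L]),
                       file.path(out_dir, paste0(base, "_hdf.csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' @export
print.lv_analysis <- function(x, ...) {
  cat(sprintf("lv_analysis: %d fits, %d quarantined, %d QC flags (manifest %s)\n",
              length(x$fits), length(x$quarantined), length(x$qc_flags),
              substr(x$manifest_md5, 1, 8)))
  invisible(x)
}

#' Cohort report: summary table, regressions and time-course bands
#'
#' Builds the mean +/- SD summary per metric and phase (with the
#' Control-vs-Rest Welch p-values), heart-rate regressions against the flow
#' metrics (VFT, E/A and, when present, the vorticity peak), and - when the
#' full analysis object is supplied - phase-wise mean +/- SD bands of the
#' strain and longitudinal-force time courses.
#'
#' @param x a [cohort_table()] or the result of [run_analyze()].
#' @param out_dir optional directory for CSV/markdown artifacts.
#' @return list of class `lv_report` with `summary`, `regressions` and
#'   (optionally) `bands`.
#' @export
run_report <- function(x, out_dir = NULL) {
  fits <- NULL
  if (inherits(x, "lv_analysis")) { fits <- x$fits; tab <- x$table }
  else tab <- x
  stopifnot(inherits(tab, "cohort_table"))
  if (nrow(tab) == 0L) stop("empty cohort table")
  summ <- summary_table(tab, phases = intersect(phase_labels, unique(tab$phase)))

  wide <- function(m) tab$value[tab$metric == m][
    match(paste(tab$subject, tab$phase)[tab$metric == "HR"],
          paste(tab$subject, tab$phase)[tab$metric == m])]
  hr <- tab$value[tab$metric == "HR"]
  regressions <- list()
  for (m in intersect(c("VFT", "E_A", "omega_bar_peak"), unique(tab$metric))) {
    y <- wide(m)
    ok <- is.finite(hr) & is.finite(y)
    if (sum(ok) >= 3L && stats::var(y[ok]) > 0)
      regressions[[paste0("HR_vs_", m)]] <-
        c(linear_fit(y[ok], hr[ok]),
          list(data = data.frame(x = y[ok], HR = hr[ok])))
  }

  bands <- NULL
  if (!is.null(fits)) {
    keyphase <- sub("^.*/", "", names(fits))
    bands <- list()
    for (ph in unique(keyphase)) {
      fs <- fits[keyphase == ph]
      nfr <- vapply(fs, function(f) nrow(f$strain), integer(1))
      if (length(unique(nfr)) != 1L) next
      phfrac <- fs[[1L]]$strain$time / fs[[1L]]$volume$period
      agg <- function(get) {
        m <- vapply(fs, get, numeric(nfr[1L]))
        data.frame(phase_fraction = phfrac,
                   mean = rowMeans(m), sd = apply(m, 1L, stats::sd))
      }
      bands[[ph]] <- list(GPS = agg(function(f) f$strain$GPS),
                          GSS = agg(function(f) f$strain$GSS),
                          fz = agg(function(f) f$hdf$f[, 3L]))
    }
  }
  rep <- structure(list(summary = summ, regressions = regressions,
                        bands = bands), class = "lv_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summ$stats, file.path(out_dir, "summary_stats.csv"),
                     row.names = FALSE)
    con <- file(file.path(out_dir, "summary_table.md"), "w")
    sink(con); print(summ); sink(); close(con)
    for (nm in names(regressions))
      utils::write.csv(regressions[[nm]]$data,
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    if (!is.null(bands))
      for (ph in names(bands))
        for (q in names(bands[[ph]]))
          utils::write.csv(bands[[ph]][[q]],
                           file.path(out_dir, sprintf("band_%s_%s.csv", ph, q)),
                           row.names = FALSE)
  }
  rep
}

#' @export
print.lv_report <- function(x, ...) {
  print(x$summary)
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    cat(sprintf("%s: slope %.3g, R^2 %.3f, p %.3g (n = %d)\n",
                nm, r$slope, r$r_squared, r$p_value, r$n))
  }
  invisible(x)
}
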