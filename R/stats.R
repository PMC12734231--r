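#' Normality screen by skewness and kurtosis
#'
#' Sample skewness and excess kurtosis (moment estimators), with a pass flag
#' when both fall inside configurable cut-offs.
#'
#' @param x numeric sample, n >= 3, non-constant.
#' @param skew_max,kurt_max absolute cut-offs for the flag.
#' @return list with `skewness`, `kurtosis` (excess), `normal` flag and `n`.
#' @export
normality_screen <- function(x, skew_max = 2, kurt_max = 4) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("sample is constant: skewness/kurtosis undefined")
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2 - 3
  list(skewness = skew, kurtosis = kurt,
       normal = abs(skew) <= skew_max && abs(kurt) <= kurt_max, n = n)
}

#' Unpaired (Welch) two-sample t-test
#'
#' Two-sided Welch test of equal group means, the comparison used between
#' the control cohort and the exercise cohort at rest.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return object of class `test_result` with `statistic`, `p_value`, `df`,
#'   group sizes and a method tag.
#' @export
unpaired_ttest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # degenerate but well-defined limits
    p <- if (mean(a) == mean(b)) 1 else 0
    tt <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(structure(list(statistic = tt, p_value = p, df = NA_real_,
                          n = c(length(a), length(b)), method = "welch-t"),
                     class = "test_result"))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 df = unname(ht$parameter), n = c(length(a), length(b)),
                 method = "welch-t"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.3g, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$df, x$p_value, x$n[1L], x$n[2L]))
  invisible(x)
}

#' Ordinary least-squares line
#'
#' Simple linear regression `y ~ x` with the coefficient of determination
#' and the two-sided p-value of the slope; used for the heart-rate versus
#' flow-metric correlations.
#'
#' @param x,y numeric vectors, n >= 3; `x` must not be constant.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n` and a
#'   `constant_y` flag (R-squared reported as 0 when y has no variance).
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                p_value = NA_real_, n = length(x), constant_y = TRUE))
  }
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    # exact lines are legitimate inputs here; the p-value is still reported
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L], n = length(x), constant_y = FALSE)
}

#' Long-format cohort metric table
#'
#' One value per (subject, phase, metric); duplicates are rejected.
#'
#' @param subject,phase,metric,value equal-length vectors.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(subject, phase, metric, value) {
  df <- data.frame(subject = as.character(subject),
                   phase = as.character(phase),
                   metric = as.character(metric),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  key <- paste(df$subject, df$phase, df$metric, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, phase, metric) record(s)")
  if (!all(df$phase %in% phase_labels))
    stop("unknown phase label(s): ",
         paste(unique(setdiff(df$phase, phase_labels)), collapse = ", "))
  class(df) <- c("cohort_table", class(df))
  df
}

# canonical row order of the summary report
metric_order <- c("HR", "EDV", "ESV", "SV", "EF", "GPS", "GSS", "GLS", "GCS",
                  "LVLF", "LVsysLF", "LVsysIm", "LVs", "LVdiaLF", "LVdiaIm",
                  "omega_bar_peak", "VFT", "E_A")

#' Cohort summary: mean +/- SD per metric and phase
#'
#' Mean and SD for every metric at every phase, plus the Welch t-test
#' p-value comparing Control against the Rest phase for each metric (when
#' both groups are present). Stroke volume is derived per subject as
#' EDV - ESV before summarizing if not already recorded. Phases with no data
#' are flagged in the `missing_phases` attribute rather than dropped
#' silently.
#'
#' @param tab a [cohort_table()].
#' @param phases phases to report (default all six labels).
#' @return object of class `cohort_summary`: a list with `stats` (long
#'   data.frame metric/phase/mean/sd/n) and `p_control_rest` (per-metric
#'   p-values).
#' @export
summary_table <- function(tab, phases = phase_labels) {
  stopifnot(inherits(tab, "cohort_table"))
  if (nrow(tab) == 0L) stop("empty cohort table")
  have_sv <- "SV" %in% tab$metric
  if (!have_sv && all(c("EDV", "ESV") %in% tab$metric)) {
    wide <- merge(tab[tab$metric == "EDV", c("subject", "phase", "value")],
                  tab[tab$metric == "ESV", c("subject", "phase", "value")],
                  by = c("subject", "phase"), suffixes = c("_edv", "_esv"))
    sv <- cohort_table(wide$subject, wide$phase, "SV",
                       wide$value_edv - wide$value_esv)
    tab <- rbind(tab, sv)
    class(tab) <- c("cohort_table", "data.frame")
  }
  mets <- intersect(metric_order, unique(tab$metric))
  mets <- c(mets, setdiff(unique(tab$metric), mets))
  missing_ph <- setdiff(phases, unique(tab$phase))
  rows <- list()
  pvals <- numeric(0)
  for (m in mets) {
    sub <- tab[tab$metric == m, ]
    for (ph in intersect(phases, unique(sub$phase))) {
      v <- sub$value[sub$phase == ph]
      rows[[length(rows) + 1L]] <-
        data.frame(metric = m, phase = ph, mean = mean(v, na.rm = TRUE),
                   sd = stats::sd(v[is.finite(v)]), n = sum(is.finite(v)))
    }
    a <- sub$value[sub$phase == "Control"]
    b <- sub$value[sub$phase == "Rest"]
    pvals[m] <- if (sum(is.finite(a)) >= 2 && sum(is.finite(b)) >= 2)
      unpaired_ttest(a, b)$p_value else NA_real_
  }
  structure(list(stats = do.call(rbind, rows),
                 p_control_rest = pvals),
            class = "cohort_summary", missing_phases = missing_ph)
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  st <- x$stats
  phases <- intersect(phase_labels, unique(st$phase))
  mets <- unique(st$metric)
  cat(sprintf("%-10s", ""), sprintf("%12s", phases), sprintf("%8s", "p*"),
      "\n", sep = "")
  for (m in mets) {
    cells <- vapply(phases, function(ph) {
      r <- st[st$metric == m & st$phase == ph, ]
      if (nrow(r) == 0L) return("-")
      sprintf("%.*f±%.*f", digits, r$mean, digits, r$sd)
    }, character(1))
    p <- x$p_control_rest[m]
    cat(sprintf("%-10s", m), sprintf("%12s", cells),
        sprintf("%8s", ifelse(is.na(p), "-",
                              ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))),
        "\n", sep = "")
  }
  mp <- attr(x, "missing_phases")
  if (length(mp)) cat("missing phases: ", paste(mp, collapse = ", "), "\n")
  invisible(x)
}
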