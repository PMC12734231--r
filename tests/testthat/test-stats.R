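test_that("normality screen computes moment statistics and flags", {
  ns <- normality_screen(c(-1, 0, 1))
  expect_equal(ns$skewness, 0)
  expect_true(ns$normal)
  expect_error(normality_screen(rep(2, 10)), "constant")
  expect_error(normality_screen(c(1, 2)), "at least 3")
  # heavy skew is flagged
  set.seed(1)
  ns2 <- normality_screen(rexp(500)^3)
  expect_false(ns2$normal)
  # large normal samples pass in at least 95% of seeds
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(rnorm(200))$normal
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("Welch t-test agrees with the closed-form oracle to 1e-10", {
  welch_oracle <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, p = 2 * pt(-abs(t), df))
  }
  a <- c(10, 11, 12, 13); b <- c(14, 15, 16, 17)
  r <- unpaired_ttest(a, b)
  o <- welch_oracle(a, b)
  expect_equal(r$statistic, o$t, tolerance = 1e-10)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(7, sd = 2); b <- rnorm(12, mean = 0.5)
    r <- unpaired_ttest(a, b); o <- welch_oracle(a, b)
    expect_equal(r$statistic, o$t, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-10)
  }
  # symmetry in group order up to the sign of t
  r1 <- unpaired_ttest(a, b); r2 <- unpaired_ttest(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  # identical spread-free groups
  r0 <- unpaired_ttest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # identical groups with spread: t = 0, p = 1
  r3 <- unpaired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
})

test_that("Welch type-I error is nominal under the null", {
  set.seed(20260928)
  reps <- 10000L
  rej <- logical(reps)
  for (i in seq_len(reps))
    rej[i] <- unpaired_ttest(rnorm(19), rnorm(25))$p_value < 0.05
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("linear fit matches the normal-equation oracle and edge cases", {
  x <- c(0, 1, 2, 3, 4)
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # constant y handled with a flag and R^2 = 0
  fc <- linear_fit(x, rep(3, 5))
  expect_equal(fc$r_squared, 0)
  expect_true(fc$constant_y)
  expect_error(linear_fit(rep(1, 5), x), "constant")
  # closed-form oracle
  set.seed(4)
  x <- rnorm(50); y <- 1.5 * x - 2 + rnorm(50)
  f <- linear_fit(x, y)
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(f$slope, b, tolerance = 1e-10)
  expect_equal(f$intercept, a, tolerance = 1e-10)
  expect_equal(f$r_squared, r2, tolerance = 1e-10)
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
  # R^2 invariant under affine rescaling of x
  f2 <- linear_fit(3 * x + 7, y)
  expect_equal(f2$r_squared, f$r_squared, tolerance = 1e-12)
  # slope recovery within 3 SE on a noisy line
  set.seed(8)
  x <- rnorm(100); y <- 0.8 * x + rnorm(100, sd = 0.5)
  f3 <- linear_fit(x, y)
  se <- 0.5 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(f3$slope - 0.8), 3 * se)
})

test_that("summary table derives SV and reports Control-vs-Rest p-values", {
  pt <- default_phase_table()
  subj <- sprintf("S%02d", 1:2)
  recs <- do.call(rbind, lapply(seq_len(nrow(pt)), function(i) {
    expand.grid(subject = subj, phase = pt$phase[i],
                metric = c("EDV", "ESV", "HR"), stringsAsFactors = FALSE)
  }))
  recs$value <- with(recs, {
    v <- numeric(nrow(recs))
    for (i in seq_len(nrow(recs))) {
      row <- pt[pt$phase == recs$phase[i], ]
      v[i] <- switch(recs$metric[i], EDV = row$EDV_mean, ESV = row$ESV_mean,
                     HR = row$HR_mean)
    }
    v
  })
  tab <- cohort_table(recs$subject, recs$phase, recs$metric, recs$value)
  summ <- summary_table(tab)
  sv <- summ$stats[summ$stats$metric == "SV", ]
  expect_equal(sv$mean[match(c("Control", "Rest", "Mid", "Peak", "Recovery10"),
                             sv$phase)], c(54, 54, 54, 45, 49))
  expect_equal(sv$sd, rep(0, nrow(sv)))
  # identical Control and Rest groups give p = 1 for EDV? no: means differ
  expect_equal(unname(summ$p_control_rest["SV"]), 1)   # SV identical: 54 vs 54
  # duplicates rejected
  expect_error(cohort_table(c("S1", "S1"), c("Rest", "Rest"),
                            c("EDV", "EDV"), c(90, 91)), "duplicate")
  expect_error(cohort_table("S1", "Sprint", "EDV", 90), "phase")
  # missing phases are flagged, not dropped
  small <- cohort_table(rep(subj, 2), rep(c("Rest", "Peak"), each = 2),
                        rep("EF", 4), c(59, 60, 68, 69))
  s2 <- summary_table(small)
  expect_true("Mid" %in% attr(s2, "missing_phases"))
})
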