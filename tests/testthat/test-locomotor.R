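# Chi-square periodogram, rhythmicity classification, cohort summaries,
# anticipation index, eduction/actogram.

test_that("Qp matches hand arithmetic on the alternating series", {
  # x = 1,3,1,3,...: at P = 2 bins M_h = (1,3), M = 2, sigma2 = 1, K = 3
  x <- rep(c(1, 3), 1000)
  s <- make_series(x)
  grid_h <- c(2, 3) / 60   # 2- and 3-bin candidate periods
  res <- chi_square_periodogram(s, dd_only = FALSE, period_grid_h = grid_h)
  expect_equal(res$qp[1], length(x) / 2 * 2)       # K * sum = (N/2)*2
  expect_equal(res$qp[2], 0)                        # perfect anti-phase folding

  # the 6-point hand example itself
  res6 <- chi_square_periodogram(make_series(c(1, 3, 1, 3, 1, 3)),
                                 dd_only = FALSE, period_grid_h = 2 / 60)
  expect_equal(res6$qp, 6)
  expect_gt(res6$qp, qchisq(0.95, df = 1))          # 3.841: significant
  expect_true(res6$significant)
})

test_that("grid Qp equals the brute-force two-loop reference", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(500:2000, 1)
    x <- rpois(n, 3) + rep(sin(2 * pi * seq_len(n) / 97)^2, length.out = n)
    grid_bins <- sample(5:200, 12)
    res <- chi_square_periodogram(make_series(round(x)), dd_only = FALSE,
                                  period_grid_h = grid_bins / 60)
    ref <- vapply(grid_bins, function(P) qp_bruteforce(round(x), P), numeric(1))
    expect_equal(res$qp, ref, tolerance = 1e-12)
  }
})

test_that("a constant series is arrhythmic with a degenerate-variance flag", {
  res <- chi_square_periodogram(make_series(rep(2L, 6000)), dd_only = FALSE,
                                period_grid_h = c(10, 20) / 60)
  expect_false(res$significant)
  expect_true(res$degenerate)
  expect_true(is.na(res$tau_h))
  cls <- classify_rhythmic(res)
  expect_false(cls$rhythmic)
})

test_that("DD-only analysis uses bins from the DD start", {
  # rhythmic only in the DD part; with dd_only the peak must be found
  p <- genotype_preset("g", locomotor = list(tau_h = 24))
  coh <- simulate_locomotor(p, 1, days_ld = 2, days_dd = 7, seed = 5)
  full <- chi_square_periodogram(coh[[1]], dd_only = TRUE)
  expect_equal(full$n_bins_used, 7 * 1440)
})

test_that("rhythmicity criteria are inclusive at the printed boundaries", {
  fake <- function(sig, power, width) {
    structure(list(significant = sig, power = power, width_h = width,
                   degenerate = FALSE), class = "periodogram_result")
  }
  crit <- rhythmicity_criteria()  # 20 / 2 / 0.05
  expect_true(classify_rhythmic(fake(TRUE, 20.0, 2.0), crit)$rhythmic)
  r1 <- classify_rhythmic(fake(TRUE, 19.9, 5), crit)
  expect_false(r1$rhythmic); expect_equal(r1$failed, "power")
  r2 <- classify_rhythmic(fake(FALSE, 50, 5), crit)
  expect_false(r2$rhythmic); expect_equal(r2$failed, "significance")
  r3 <- classify_rhythmic(fake(TRUE, 50, 1.9), crit)
  expect_false(r3$rhythmic); expect_equal(r3$failed, "width")
})

test_that("cohort summary reports percent rhythmic and rhythmic-only means", {
  fake <- function(sig, tau = 24, power = 100, width = 4) {
    structure(list(significant = sig, tau_h = if (sig) tau else NA,
                   power = if (sig) power else NA,
                   width_h = if (sig) width else NA, degenerate = FALSE),
              class = "periodogram_result")
  }
  res <- list(fake(TRUE, 24), fake(TRUE, 25), fake(TRUE, 26), fake(FALSE))
  cs <- cohort_summary(res)
  expect_equal(cs$percent_rhythmic, 75)
  expect_equal(cs$tau_mean, 25)
  expect_equal(cs$tau_sem, sd(24:26) / sqrt(3))

  none <- cohort_summary(list(fake(FALSE), fake(FALSE)))
  expect_equal(none$percent_rhythmic, 0)
  expect_true(is.na(none$tau_mean))
})

test_that("anticipation index reproduces its closed forms", {
  # uniform activity: both window means equal, AI = 1 exactly
  u <- make_series(rep(5L, 1440 * 6))
  expect_equal(anticipation_index(u, "morning", n_days = 3)$ai, 1.0)
  expect_equal(anticipation_index(u, "evening", n_days = 3)$ai, 1.0)

  # all activity in the final 3 h before lights-on: AI = 2 exactly
  x <- rep(0L, 1440 * 3)
  for (d in 1:2) x[(d * 1440 - 180 + 1):(d * 1440)] <- 4L
  expect_equal(anticipation_index(make_series(x), "morning", n_days = 2)$ai, 2.0)

  # hourly ramp 1..6 before lights-on: mean3 = 5, mean6 = 3.5, AI = 10/7
  r <- rep(0L, 1440 * 3)
  for (d in 1:2) {
    T <- d * 1440
    for (k in 1:6) r[(T - (7 - k) * 60 + 1):(T - (6 - k) * 60)] <- k
  }
  expect_equal(anticipation_index(make_series(r), "morning", n_days = 2)$ai, 10 / 7)
})

test_that("anticipation excludes zero-activity days and flags all-excluded flies", {
  x <- rep(0L, 1440 * 4)
  x[(2 * 1440 - 180 + 1):(2 * 1440)] <- 2L    # only day 2 has activity
  res <- anticipation_index(make_series(x), "morning", n_days = 3)
  expect_equal(res$days_used, 1)
  expect_equal(res$ai, 2.0)

  dead <- anticipation_index(make_series(rep(0L, 1440 * 4)), "morning", n_days = 3)
  expect_true(dead$all_excluded)
  expect_true(is.na(dead$ai))

  expect_error(anticipation_index(make_series(rep(1L, 1440)), "morning", 5),
               "transitions available")
})

test_that("AI stays within [0, 2] on random nonnegative series", {
  set.seed(8)
  for (i in 1:20) {
    x <- rpois(1440 * 4, runif(1, 0.1, 3))
    ai <- anticipation_index(make_series(x), sample(c("morning", "evening"), 1),
                             n_days = 3)$ai
    expect_gte(ai, 0); expect_lte(ai, 2)
  }
})

test_that("eduction and actogram matrices match hand computation", {
  d1 <- rep(c(0L, 4L), 720)
  d2 <- rep(c(2L, 2L), 720)
  s <- make_series(c(d1, d2))
  expect_equal(eduction(s), (d1 + d2) / 2)
  expect_equal(eduction(make_series(d1)), as.numeric(d1))

  m <- actogram_matrix(s)
  expect_equal(dim(m), c(2, 1440))
  expect_equal(m[1, ], d1)
  md <- actogram_matrix(s, double_plot = TRUE)
  expect_equal(dim(md), c(2, 2880))
  expect_equal(md[1, 1441:2880], d2)
  expect_true(all(is.na(md[2, 1441:2880])))

  expect_warning(actogram_matrix(make_series(c(d1, 1L))), "trimmed")
})

test_that("null exceedance of the chi-square line is near alpha", {
  # iid Poisson series, folded at periods short enough for >= 12 complete
  # cycles (where the chi-square reference distribution is accurate): pooled
  # over series and periods, the supra-threshold fraction should be near
  # alpha (periods are correlated, so the band is wide)
  set.seed(21)
  frac <- mean(unlist(lapply(1:15, function(i) {
    x <- rpois(4320, 2)
    r <- chi_square_periodogram(make_series(x), dd_only = FALSE,
                                period_grid_h = seq(2, 6, by = 0.25))
    r$qp > r$chi2_threshold
  })))
  expect_lt(abs(frac - 0.05), 0.03)
})
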