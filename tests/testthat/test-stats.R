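test_that("WTI is the signed thickness difference and rejects bad input", {
  expect_equal(compute_wti(1.2, 1.5), 0.3)
  expect_equal(compute_wti(1.5, 1.5), 0)
  expect_equal(compute_wti(2.0, 1.4), -0.6)   # plaque regression
  expect_error(compute_wti(0, 1), "positive")
  expect_error(compute_wti(1, -0.2), "positive")
})

test_that("pearson_r_p matches cor.test across sizes and signals", {
  set.seed(31)
  for (n in c(5, 40, 400)) for (b in c(0, 0.4, -1.2)) {
    x <- rnorm(n); y <- b * x + rnorm(n)
    ours <- pearson_r_p(x, y)
    ref <- cor.test(x, y)   # independent oracle
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_r_p(1:5, rep(1, 5)), "zero variance")
  expect_error(pearson_r_p(1:4, 1:5), "equal length")
  y <- 1:10
  expect_equal(pearson_r_p(y, y)$r, 1)
  expect_equal(pearson_r_p(y, y)$p, 0)
})

test_that("p recomputation reproduces published per-case p-values", {
  # values printed in the source study's summary tables
  expect_equal(round(p_from_r(0.082, 800), 3), 0.020)
  expect_equal(round(p_from_r(0.130, 400), 3), 0.009)
  # printed p reflects the unrounded r, so compare within the stated
  # rounding-propagation tolerance
  expect_equal(p_from_r(-0.108, 400), 0.032, tolerance = 0.003 / 0.032)
})

test_that("classification uses strict alpha and handles boundaries", {
  # the published case whose p moved across the threshold between phases
  expect_equal(classify_correlation(-0.077, 0.043), "negative")
  expect_equal(classify_correlation(-0.072, 0.056), "no_significance")
  expect_equal(classify_correlation(0, 0.001), "no_significance")
  expect_equal(classify_correlation(0.5, 0.05), "no_significance")  # strict
  expect_equal(classify_correlation(0.5, 0.049999), "positive")
  expect_equal(correlation_ratio(c("positive")),
               c(positive = 1L, negative = 0L, no_significance = 0L))
  r <- c(0.3, -0.2, 0.01); p <- c(0.001, 0.02, 0.7)
  cnt <- correlation_ratio(classify_correlation(r, p))
  expect_equal(sum(cnt), 3L)
})

test_that("pooled interval is the mean-r Student-t interval", {
  r <- c(0.1, -0.2, 0.35, 0.02, -0.07, 0.4)
  ci <- pooled_ci(r)
  m <- length(r)
  half <- qt(0.975, m - 1) * sd(r) / sqrt(m)
  expect_equal(ci$mean, mean(r))
  expect_equal(ci$lo, mean(r) - half)
  expect_equal(ci$hi, mean(r) + half)
  # degenerate: identical values give a zero-width interval
  expect_equal(unlist(pooled_ci(rep(0.25, 8))),
               c(mean = 0.25, lo = 0.25, hi = 0.25))
  expect_error(pooled_ci(0.1), "at least 2")
})

test_that("build_summary is invariant to point order and respects columns", {
  coh <- suppressWarnings(generate_cohort(small_config(seed = 21)))
  pts <- coh$truth$points
  s1 <- build_summary(pts, "FSS", "baseline", "maxQ")
  s2 <- build_summary(pts[sample.int(nrow(pts)), ], "FSS", "baseline", "maxQ")
  expect_equal(s1$records$r, s2$records$r)
  expect_equal(s1$counts, s2$counts)
  expect_equal(sum(s1$counts), nrow(s1$records))
  expect_error(build_summary(pts, "PWS", "followup", "maxQ"), "no column")
  # a pair with fewer than 3 points is excluded with a warning
  tiny <- rbind(pts, data.frame(pts[1:2, ] , row.names = NULL))
  tiny$pair_id[seq(nrow(pts) + 1, nrow(pts) + 2)] <- 99
  expect_warning(s3 <- build_summary(tiny, "FSS", "baseline", "maxQ"),
                 "fewer than 3")
  expect_equal(nrow(s3$records), nrow(s1$records))
})

test_that("strong positive coupling yields majority positive classifications", {
  cfg <- small_config(seed = 33,
                      coupling = list(beta0 = -0.5, beta_fss = 0.01,
                                      beta_pws = 0, noise_sd = 0.15))
  coh <- suppressWarnings(generate_cohort(cfg))
  s <- build_summary(coh$truth$points, "FSS", "baseline", "maxQ")
  expect_gt(s$counts["positive"], s$counts["negative"])
  expect_gt(s$counts["positive"], s$counts["no_significance"])
})
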