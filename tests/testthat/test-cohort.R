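test_that("generation is deterministic and zero coupling is the identity", {
  cfg0 <- small_config(seed = 3,
                       coupling = list(beta0 = 0, beta_fss = 0,
                                       beta_pws = 0, noise_sd = 0))
  a <- generate_cohort(cfg0)
  b <- generate_cohort(cfg0)
  expect_identical(a, b)
  expect_true(all(a$truth$points$wti == 0))
  for (p in a$pairs)
    for (i in seq_along(p$baseline$slices)) {
      expect_equal(p$follow_up$slices[[i]]$lumen, p$baseline$slices[[i]]$lumen)
      expect_equal(p$follow_up$slices[[i]]$outer, p$baseline$slices[[i]]$outer)
    }
})

test_that("per-pair point counts stay within the slice-range band", {
  coh <- default_cohort()
  counts <- table(coh$truth$points$pair_id)
  expect_equal(length(counts), 32L)
  expect_true(all(counts >= 4 * 100 & counts <= 10 * 100))
})

test_that("ground-truth WTI decomposition sums exactly", {
  coh <- suppressWarnings(generate_cohort(small_config(seed = 13)))
  tp <- coh$truth$points
  expect_equal(tp$wti_base_term + tp$wti_fss_term + tp$wti_pws_term +
                 tp$wti_noise, tp$wti, tolerance = 1e-12)
  # PWS coupling was active, so the stress fields must be populated
  expect_true(all(is.finite(tp$pws_baseline_maxQ)))
  expect_true(all(tp$fss_baseline_maxQ > 0))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(slices_per_pair_range = c(3, 10)), "\\[4, 10\\]")
  expect_error(cohort_config(slices_per_pair_range = c(4, 11)), "\\[4, 10\\]")
  expect_error(cohort_config(points_per_slice = 2))
  expect_error(cohort_config(coupling = list(beta0 = 0, beta_fss = 0,
                                             beta_pws = 0, noise_sd = -1)))
})

test_that("contour-stack round trip is lossless", {
  coh <- suppressWarnings(generate_cohort(small_config(seed = 17)))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$pairs), length(coh$pairs))
  for (j in seq_along(coh$pairs)) {
    expect_equal(back$pairs[[j]]$systolic, coh$pairs[[j]]$systolic)
    for (tp in c("baseline", "follow_up"))
      for (i in seq_along(coh$pairs[[j]][[tp]]$slices)) {
        expect_identical(back$pairs[[j]][[tp]]$slices[[i]]$lumen,
                         coh$pairs[[j]][[tp]]$slices[[i]]$lumen)
        expect_identical(back$pairs[[j]][[tp]]$slices[[i]]$segment,
                         coh$pairs[[j]][[tp]]$slices[[i]]$segment)
      }
  }
  expect_equal(back$truth$points$wti, coh$truth$points$wti, tolerance = 1e-12)
})

test_that("reading validates contours and warns on short pairs", {
  coh <- suppressWarnings(generate_cohort(small_config(seed = 19)))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  # truncate half the lumen rows of one slice -> open contour error
  f <- file.path(dir, "pair01", "baseline", "slice01.csv")
  d <- readLines(f)
  keep <- c(1, 2:22, grep("^outer", d))
  writeLines(d[keep], f)
  expect_error(read_cohort(dir), "open lumen contour.*slice01")

  # a pair reduced to 3 matched slices loads with a warning
  dir2 <- withr::local_tempdir()
  write_cohort(coh, dir2)
  idx <- jsonlite::read_json(file.path(dir2, "index.json"))
  for (tp in c("baseline", "follow_up")) {
    sl <- idx$pairs[[1]][[tp]]$slices
    keep <- vapply(sl, function(s) s$segment, character(1)) %in%
      c("CCA", "ICA")
    sl <- sl[keep][1:3]
    idx$pairs[[1]][[tp]]$slices <- sl
  }
  jsonlite::write_json(idx, file.path(dir2, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_warning(back <- read_cohort(dir2), "only 3 matched slices")
  expect_equal(length(back$pairs), length(coh$pairs))
})

test_that("out-of-band WTI draws are clipped with a warning", {
  cfg <- small_config(seed = 23,
                      coupling = list(beta0 = 3, beta_fss = 0,
                                      beta_pws = 0, noise_sd = 0))
  expect_warning(coh <- generate_cohort(cfg), "clipped")
  tp <- coh$truth$points
  expect_true(all(tp$wti <= 0.3 * tp$rho + 1e-9))
})
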