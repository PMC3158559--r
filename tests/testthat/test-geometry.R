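test_that("equal-arc resampling spaces points uniformly along the polygon", {
  # regular 256-gon: resampled positions must match direct arc-length
  # accumulation, with equal arc spacing of perimeter/100
  for (shape in list(regular_polygon(256),
                     ellipse_polygon(512, a = 2, b = 1))) {
    n <- 100
    rs <- resample_contour(shape, n)
    per <- contour_perimeter(shape)
    # canonical start is the max-x vertex
    i0 <- which.max(shape[, 1])
    s0 <- if (i0 == 1) 0 else
      sum(sqrt(rowSums((shape[2:i0, , drop = FALSE] -
                          shape[1:(i0 - 1), , drop = FALSE])^2)))
    oracle <- arc_interp_oracle(shape, s0 + (0:(n - 1)) * per / n)
    expect_lt(max(abs(rs - oracle)), 1e-9)
    expect_equal(contour_perimeter(rs) / per, 1, tolerance = 1e-3)
  }
})

test_that("resampling a diamond to its corner count returns the corners", {
  sq <- square_polygon(1)
  expect_equal(resample_contour(sq, 4), unname(sq), tolerance = 1e-12)
})

test_that("resampling an equally spaced contour is idempotent", {
  for (n in c(37, 100)) for (ph in c(0, 0.3, 1.1)) {
    poly <- regular_polygon(n, r = 2.5, center = c(0.4, -0.2), phase = ph)
    expect_lt(max(abs(resample_contour(poly, n) -
                        resample_contour(resample_contour(poly, n), n))), 1e-9)
  }
})

test_that("degenerate and invalid contours are rejected", {
  expect_error(resample_contour(matrix(0, 5, 2), 10), "degenerate|distinct")
  expect_error(resample_contour(regular_polygon(8), 2), "n must be")
  expect_error(as_contour(cbind(1:2, 1:2)), ">= 3")
})

test_that("outward normals point away from the enclosed region", {
  rs <- resample_contour(regular_polygon(128, r = 2, center = c(1, 1)), 60)
  nrm <- outward_normals(rs)
  ctr <- contour_centroid(rs)
  radial <- sweep(rs, 2, ctr)
  expect_true(all(rowSums(nrm * radial) > 0))
  expect_equal(rowSums(nrm^2), rep(1, 60), tolerance = 1e-12)
})

test_that("polygon area and perimeter agree with an independent oracle", {
  skip_if_not_installed("pracma")
  for (shape in list(regular_polygon(200, 2.3), ellipse_polygon(300, 2, 1))) {
    x <- c(shape[, 1], shape[1, 1]); y <- c(shape[, 2], shape[1, 2])
    expect_equal(abs(contour_area(shape)), abs(pracma::polyarea(x, y)),
                 tolerance = 1e-12)
    expect_equal(contour_perimeter(shape),
                 sum(sqrt(diff(x)^2 + diff(y)^2)), tolerance = 1e-12)
  }
})

make_scan <- function(idxs, segs, bif, r = 2) {
  slices <- Map(function(i, s)
    contour_slice(regular_polygon(64, r), regular_polygon(64, r + 1), s, i,
                  2 * (i - 1)), idxs, segs)
  plaque_scan(slices, bif)
}

test_that("slice matching pairs by bifurcation offset and drops ECA", {
  segs <- c("CCA", "CCA", "ICA", "ICA", "ECA")
  b <- make_scan(1:5, segs, 3)
  m <- match_slices(b, b)
  expect_equal(nrow(m), 4)              # ECA excluded
  expect_equal(m$baseline_slice, m$followup_slice)
  expect_equal(m$offset, c(-2, -1, 0, 1))

  # follow-up missing two distal ICA slices
  f <- make_scan(1:3, segs[1:3], 3)
  m2 <- match_slices(b, f)
  expect_equal(nrow(m2), nrow(m) - 1)   # only one ICA slice matchable

  # shifted bifurcation index: axial slice i matches axial slice i + 2
  f3 <- make_scan(3:7, segs, 5)
  m3 <- match_slices(b, f3)
  ax <- function(scan, idx) vapply(scan$slices[idx], function(s)
    s$axial_index, integer(1))
  expect_equal(ax(f3, m3$followup_slice), ax(b, m3$baseline_slice) + 2L)

  # symmetry
  m4 <- match_slices(f3, b)
  expect_equal(m4$baseline_slice, m3$followup_slice)
  expect_equal(m4$followup_slice, m3$baseline_slice)

  expect_error(plaque_scan(b$slices, NA), "bifurcation")
})

test_that("equal-step thickness is exact on concentric annuli", {
  lum <- resample_contour(regular_polygon(128, 2), 100)
  th <- wall_thickness(lum, regular_polygon(256, 3))
  expect_true(all(abs(th - 1) < 0.155 / 2))

  # concentric squares, probing an edge midpoint (index 51 of the
  # canonical sampling starts near the max-x corner; use the point
  # closest to the +x edge midpoint of the outer square)
  lum_sq <- resample_contour(axis_square(2), 100)
  th_sq <- wall_thickness(lum_sq, axis_square(3))
  mid <- which.min((lum_sq[, 1] - 2)^2 + lum_sq[, 2]^2)
  expect_lt(abs(th_sq[mid] - 1), 0.155 / 2)
})

test_that("equal-step thickness matches a brute-force path oracle on
           eccentric circles", {
  # outer r = 3 at origin, lumen r = 1.5 at (0.8, 0); probe (2.3, 0)
  lum <- resample_contour(regular_polygon(256, 1.5, center = c(0.8, 0)), 100)
  outer <- regular_polygon(256, 3)
  k <- which.min((lum[, 1] - 2.3)^2 + lum[, 2]^2)
  th <- wall_thickness_equal_step(k, lum, outer)
  # brute-force shortest wall-crossing path: direct enumeration over a
  # dense outer sampling (the wall is locally convex, so the shortest
  # path is the straight segment to the nearest outer point)
  dense <- regular_polygon(4096, 3)
  oracle <- min(sqrt((dense[, 1] - lum[k, 1])^2 + (dense[, 2] - lum[k, 2])^2))
  expect_equal(th, oracle, tolerance = 0.05)
})

test_that("thickness never falls below the nearest outer-wall distance", {
  coh <- suppressWarnings(generate_cohort(small_config(seed = 5)))
  for (p in coh$pairs) for (s in p$baseline$slices[1:2]) {
    lum <- resample_contour(s$lumen, 40)
    th <- wall_thickness(lum, s$outer)
    near <- vapply(seq_len(nrow(lum)), function(i)
      point_polygon_distance(lum[i, ], s$outer), numeric(1))
    expect_true(all(th > 0))
    expect_true(all(th >= near - 1e-9))
  }
})

test_that("shrink-stretch conserves wall mass and reports the 9% axial shrink", {
  spec <- shrink_spec(1.10)
  expect_equal(spec$axial_shrink, 1 - 1 / 1.10, tolerance = 1e-12)
  expect_equal(round(100 * spec$axial_shrink), 9)

  sl <- contour_slice(regular_polygon(128, 2), regular_polygon(128, 3),
                      "CCA", 1, 0)
  sr <- shrink_stretch(sl, spec)
  in_vivo <- abs(contour_area(sl$outer)) - abs(contour_area(sl$lumen))
  expect_equal(sr$no_load_wall_area, 1.10 * in_vivo, tolerance = 1e-6)
  # achieved area of the returned contours matches the reported one
  got <- abs(contour_area(sr$slice$outer)) - abs(contour_area(sr$slice$lumen))
  expect_equal(got, sr$no_load_wall_area, tolerance = 1e-9)
  expect_gte(sr$lumen_shrink, 0.08); expect_lte(sr$lumen_shrink, 0.12)
  expect_gte(sr$outer_shrink, 0.02); expect_lte(sr$outer_shrink, 0.05)

  # identity when nothing is stretched and zero shrink is admissible
  id <- shrink_stretch(sl, shrink_spec(1.0, c(0, 0), c(0, 0)))
  expect_equal(id$slice$lumen, sl$lumen, tolerance = 1e-12)
  expect_equal(id$slice$outer, sl$outer, tolerance = 1e-12)

  # infeasible geometry errors with the achieved bounds
  thin <- contour_slice(regular_polygon(128, 2.9), regular_polygon(128, 3),
                        "CCA", 1, 0)
  expect_error(shrink_stretch(thin, spec), "no shrink solution")
})

test_that("shrink-stretch conserves mass across generator slices", {
  coh <- suppressWarnings(generate_cohort(small_config(seed = 9)))
  for (p in coh$pairs) for (s in p$baseline$slices) {
    if (!s$segment %in% c("CCA", "ICA")) next
    sr <- shrink_stretch(s, shrink_spec(1.10))
    expect_equal(sr$no_load_wall_area / 1.10, sr$in_vivo_wall_area,
                 tolerance = 1e-6)
  }
})

test_that("imaging identities: stenosis conversion and in-plane resolution", {
  expect_equal(area_stenosis(0.5), 0.75)
  expect_equal(area_stenosis(0), 0)
  expect_equal(round(mri_in_plane_resolution(160, 512), 2), 0.31)
})
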