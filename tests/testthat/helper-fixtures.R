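# geometric fixtures built in code

regular_polygon <- function(n, r = 1, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_polygon <- function(n, a = 2, b = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(a * cos(th), b * sin(th))
}

square_polygon <- function(half = 1) {
  # diamond orientation: vertices on the axes, max-x vertex is a corner
  rbind(c(half, 0), c(0, half), c(-half, 0), c(0, -half))
}

axis_square <- function(half = 1) {
  rbind(c(half, -half), c(half, half), c(-half, half), c(-half, -half))
}

# independent arc-length interpolation oracle: positions at arc distances s
# along the implicitly closed polygon, by direct accumulation
arc_interp_oracle <- function(xy, s) {
  m <- nrow(xy)
  e <- xy[c(2:m, 1), ] - xy
  el <- sqrt(rowSums(e^2))
  cum <- c(0, cumsum(el))
  t(vapply(s %% cum[m + 1], function(si) {
    j <- max(which(cum <= si + 1e-15))
    j <- min(j, m)
    xy[j, ] + e[j, ] * (si - cum[j]) / el[j]
  }, numeric(2)))
}

# small fast cohort configuration for unit tests
small_config <- function(seed = 11, ...) {
  cohort_config(n_pairs = 3, n_patients = 2,
                slices_per_pair_range = c(4, 5),
                points_per_slice = 40, seed = seed, ...)
}

# the default-conditions cohort and its full analysis are expensive;
# compute once per test run and share across test files
.cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cache$cohort))
    .cache$cohort <- suppressWarnings(generate_cohort(cohort_config(seed = 42)))
  .cache$cohort
}

default_analysis <- function() {
  if (is.null(.cache$analysis))
    .cache$analysis <- suppressWarnings(
      analyze_cohort(default_cohort(), quiet = TRUE))
  .cache$analysis
}

# exact nearest distance from a point to an implicitly closed polygon
# (projection onto every edge) -- independent oracle for thickness bounds
point_polygon_distance <- function(pt, xy) {
  m <- nrow(xy)
  a <- xy; b <- xy[c(2:m, 1), , drop = FALSE]
  e <- b - a
  w1 <- pt[1] - a[, 1]; w2 <- pt[2] - a[, 2]
  tt <- pmin(pmax((w1 * e[, 1] + w2 * e[, 2]) / rowSums(e^2), 0), 1)
  px <- a[, 1] + tt * e[, 1]; py <- a[, 2] + tt * e[, 2]
  min(sqrt((pt[1] - px)^2 + (pt[2] - py)^2))
}
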