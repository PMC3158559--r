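# Conversion used at all I/O boundaries; mechanics and hemodynamics work in CGS.
MMHG_TO_DYN_CM2 <- 1333.2

#' Convert pressure between mmHg and dyn/cm^2
#'
#' The package works in CGS units internally (1 mmHg = 1333.2 dyn/cm^2).
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
mmHg_to_dyn <- function(x) x * MMHG_TO_DYN_CM2

#' @rdname mmHg_to_dyn
#' @export
dyn_to_mmHg <- function(x) x / MMHG_TO_DYN_CM2

#' In-plane resolution of an MRI acquisition
#'
#' Resolution is field of view divided by (interpolated) matrix size; a
#' 160 mm field of view on a 512 matrix gives 0.3125 mm, reported as
#' 0.31 mm at scanner precision.
#'
#' @param fov_mm field of view in mm.
#' @param matrix_size acquisition matrix size (pixels per side).
#' @return in-plane pixel size in mm.
#' @export
mri_in_plane_resolution <- function(fov_mm = 160, matrix_size = 512) {
  stopifnot(fov_mm > 0, matrix_size > 0)
  fov_mm / matrix_size
}

#' Area stenosis implied by a diameter stenosis
#'
#' For a circular lumen, a fractional diameter reduction d leaves a
#' fraction (1-d)^2 of the area, i.e. area stenosis = 1 - (1-d)^2; 50%
#' by diameter corresponds to 75% by area.
#'
#' @param diameter_stenosis fractional diameter reduction in \[0, 1\].
#' @return fractional area reduction.
#' @export
area_stenosis <- function(diameter_stenosis) {
  stopifnot(all(diameter_stenosis >= 0 & diameter_stenosis <= 1))
  1 - (1 - diameter_stenosis)^2
}

# --- planar closed-polyline primitives ------------------------------------
# Contours are n x 2 matrices of vertices in mm; closure is implicit
# (the edge from the last vertex back to the first belongs to the contour).

as_contour <- function(xy) {
  xy <- as.matrix(xy)
  if (!is.numeric(xy) || ncol(xy) != 2 || nrow(xy) < 3)
    stop("contour must be a numeric matrix with >= 3 rows and 2 columns")
  if (any(!is.finite(xy))) stop("contour contains non-finite vertices")
  # drop an explicitly repeated closing vertex
  n <- nrow(xy)
  if (sqrt(sum((xy[1, ] - xy[n, ])^2)) < 1e-12) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3) stop("contour must have >= 3 distinct vertices")
  unname(xy)
}

contour_edges <- function(xy) {
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  xy[nxt, , drop = FALSE] - xy
}

#' Perimeter, signed area and centroid of a closed contour
#'
#' Shoelace formulas on the implicitly closed vertex polygon. The signed
#' area is positive for counter-clockwise orientation.
#'
#' @param xy n x 2 vertex matrix (closure implicit).
#' @return `contour_perimeter`: total edge length; `contour_area`: signed
#'   area; `contour_centroid`: length-2 centroid of the enclosed region.
#' @export
contour_perimeter <- function(xy) {
  xy <- as_contour(xy)
  sum(sqrt(rowSums(contour_edges(xy)^2)))
}

#' @rdname contour_perimeter
#' @export
contour_area <- function(xy) {
  xy <- as_contour(xy)
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  0.5 * sum(xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2])
}

#' @rdname contour_perimeter
#' @export
contour_centroid <- function(xy) {
  xy <- as_contour(xy)
  nxt <- c(seq_len(nrow(xy))[-1], 1L)
  cr <- xy[, 1] * xy[nxt, 2] - xy[nxt, 1] * xy[, 2]
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-14) return(colMeans(xy))
  c(sum((xy[, 1] + xy[nxt, 1]) * cr), sum((xy[, 2] + xy[nxt, 2]) * cr)) / (6 * a)
}

ensure_ccw <- function(xy) {
  if (contour_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Resample a closed contour at equal arc-length spacing
#'
#' Places `n` points along the (implicitly closed) input polyline at equal
#' arc-length steps of perimeter/n, preserving the perimeter of the
#' traversed path. The canonical start vertex is the input vertex with
#' maximum x coordinate (ties broken by maximum y, then lowest index);
#' with `start = "first"` sampling begins at vertex 1 instead. Output is
#' counter-clockwise. Resampling an already equally spaced n-point
#' contour reproduces it to machine precision, which is what makes the
#' point index a stable shared label between baseline and follow-up
#' contours of the same slice.
#'
#' @param xy n x 2 vertex matrix (closure implicit).
#' @param n number of output points (>= 3).
#' @param start `"canonical"` (max-x vertex) or `"first"`.
#' @return n x 2 matrix of resampled vertices.
#' @export
resample_contour <- function(xy, n, start = c("canonical", "first")) {
  start <- match.arg(start)
  xy <- ensure_ccw(as_contour(xy))
  if (n < 3) stop("n must be >= 3")
  per <- contour_perimeter(xy)
  if (per <= 0) stop("degenerate contour: zero perimeter")
  if (start == "canonical") {
    i0 <- which(xy[, 1] == max(xy[, 1]))
    if (length(i0) > 1) i0 <- i0[which.max(xy[i0, 2])]
    xy <- xy[c(i0:nrow(xy), seq_len(i0 - 1L)), , drop = FALSE]
  }
  m <- nrow(xy)
  edges <- contour_edges(xy)
  elen <- sqrt(rowSums(edges^2))
  cum <- c(0, cumsum(elen))          # length m+1, cum[m+1] = perimeter
  s <- (seq_len(n) - 1) * per / n    # target arc positions from vertex 1
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (s - cum[idx]) / pmax(elen[idx], .Machine$double.xmin)
  xy[idx, , drop = FALSE] + edges[idx, , drop = FALSE] * frac
}

#' Outward unit normals of a counter-clockwise closed contour
#'
#' Central-difference tangents rotated by -90 degrees, so the normals
#' point away from the enclosed region.
#'
#' @param xy n x 2 vertex matrix, counter-clockwise.
#' @return n x 2 matrix of unit normals.
#' @export
outward_normals <- function(xy) {
  xy <- as_contour(xy)
  m <- nrow(xy)
  tg <- xy[c(2:m, 1), , drop = FALSE] - xy[c(m, 1:(m - 1)), , drop = FALSE]
  nrm <- cbind(tg[, 2], -tg[, 1])
  nrm / sqrt(rowSums(nrm^2))
}

# First crossing parameter of segments p -> p + u with any edge of a closed
# contour. p, u are k x 2; returns the smallest t in (0, 1] per row (Inf if
# no crossing).
segment_contour_crossing <- function(p, u, contour) {
  a <- contour
  m <- nrow(a)
  b <- a[c(2:m, 1), , drop = FALSE]
  e <- b - a
  k <- nrow(p)
  tmin <- rep(Inf, k)
  for (j in seq_len(m)) {
    den <- u[, 1] * e[j, 2] - u[, 2] * e[j, 1]
    wx <- a[j, 1] - p[, 1]
    wy <- a[j, 2] - p[, 2]
    tt <- (wx * e[j, 2] - wy * e[j, 1]) / den
    vv <- (wx * u[, 2] - wy * u[, 1]) / den
    ok <- is.finite(tt) & abs(den) > 1e-300 & tt > 1e-12 & tt <= 1 & vv >= 0 & vv < 1
    upd <- ok & tt < tmin
    tmin[upd] <- tt[upd]
  }
  tmin
}
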