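#' Construct an axial cross-section of the vessel wall
#'
#' One imaged slice: a closed lumen contour strictly inside a closed
#' outer-wall contour, both in mm on the image plane, with its carotid
#' segment label and axial position. Contours are stored
#' counter-clockwise.
#'
#' @param lumen,outer n x 2 vertex matrices (mm), closure implicit.
#' @param segment one of `"CCA"`, `"ICA"`, `"ECA"`.
#' @param axial_index integer slice index within the scan.
#' @param axial_position axial position in mm.
#' @return an object of class `contour_slice`.
#' @export
contour_slice <- function(lumen, outer, segment, axial_index, axial_position) {
  segment <- match.arg(segment, c("CCA", "ICA", "ECA"))
  lumen <- ensure_ccw(as_contour(lumen))
  outer <- ensure_ccw(as_contour(outer))
  if (contour_area(lumen) >= contour_area(outer))
    stop("lumen area must be smaller than outer-wall area")
  structure(
    list(lumen = lumen, outer = outer, segment = segment,
         axial_index = as.integer(axial_index),
         axial_position = as.numeric(axial_position)),
    class = "contour_slice")
}

#' Construct a scan (ordered slice stack with bifurcation landmark)
#'
#' @param slices list of [contour_slice()] objects.
#' @param bifurcation_index axial index of the carotid bifurcation slice,
#'   the registration reference for slice matching.
#' @param scan_id identifier string.
#' @return an object of class `plaque_scan`.
#' @export
plaque_scan <- function(slices, bifurcation_index, scan_id = "scan") {
  stopifnot(length(slices) >= 1,
            all(vapply(slices, inherits, logical(1), "contour_slice")))
  if (is.null(bifurcation_index) || is.na(bifurcation_index))
    stop("missing bifurcation landmark index")
  structure(list(slices = slices,
                 bifurcation_index = as.integer(bifurcation_index),
                 scan_id = scan_id),
            class = "plaque_scan")
}

#' Match slices of a baseline and a follow-up scan
#'
#' Slices are paired by their signed axial offset from the bifurcation
#' slice (the registration reference), separately per carotid segment.
#' Only common (CCA) and internal (ICA) carotid slices are retained;
#' external carotid (ECA) slices and unmatched offsets are dropped.
#'
#' @param baseline,follow_up [plaque_scan()] objects.
#' @return data.frame with columns `segment`, `offset`, `baseline_slice`,
#'   `followup_slice` (list indices into each scan's `slices`), ordered
#'   by offset. Attribute `dropped` counts unmatched CCA/ICA slices.
#' @export
match_slices <- function(baseline, follow_up) {
  stopifnot(inherits(baseline, "plaque_scan"), inherits(follow_up, "plaque_scan"))
  key <- function(scan) {
    seg <- vapply(scan$slices, function(s) s$segment, character(1))
    off <- vapply(scan$slices, function(s) s$axial_index, integer(1)) -
      scan$bifurcation_index
    keep <- seg %in% c("CCA", "ICA")
    data.frame(idx = which(keep), segment = seg[keep], offset = off[keep],
               stringsAsFactors = FALSE)
  }
  kb <- key(baseline); kf <- key(follow_up)
  m <- merge(kb, kf, by = c("segment", "offset"),
             suffixes = c("_baseline", "_followup"))
  m <- m[order(m$offset, m$segment), , drop = FALSE]
  out <- data.frame(segment = m$segment, offset = m$offset,
                    baseline_slice = m$idx_baseline,
                    followup_slice = m$idx_followup,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- (nrow(kb) - nrow(out)) + (nrow(kf) - nrow(out))
  out
}

#' Piecewise equal-step wall thickness
#'
#' Wall thickness at each lumen point is the arc length of a marched
#' path from the point to the outer wall: fixed-length steps (default
#' half the in-plane resolution, 0.155 mm) are taken along the direction
#' bisecting the point's outward lumen normal and the direction to the
#' current nearest outer-wall vertex, until the path crosses the outer
#' contour (the final step is trimmed at the crossing). On irregular
#' plaque cross-sections this behaves better than raw normal rays, which
#' can graze or miss the outer wall; the path length is always at least
#' the straight-line nearest distance to the outer contour. This
#' stepping rule is this package's own construction, validated by its
#' exactness on concentric annuli and the nearest-distance lower bound.
#'
#' `wall_thickness()` marches all lumen points simultaneously;
#' `wall_thickness_equal_step()` is the single-point form.
#'
#' @param lumen resampled lumen contour (n x 2 mm, counter-clockwise).
#' @param outer outer-wall contour (mm); internally resampled densely.
#' @param step march step length in mm (default 0.31/2).
#' @param max_steps step budget per point before giving up.
#' @param point_index 1-based lumen point index for the scalar form.
#' @return numeric vector (or scalar) of thicknesses in mm.
#' @export
wall_thickness <- function(lumen, outer, step = 0.155, max_steps = 400) {
  lumen <- as_contour(lumen); outer <- ensure_ccw(as_contour(outer))
  # dense vertex set only steers the march; the stopping crossing is
  # computed against the original outer polygon, so the path ends exactly
  # on it and its length can never undercut the nearest-distance bound
  n_dense <- max(nrow(outer), 200L)
  outer_d <- resample_contour(outer, n_dense, start = "first")
  nrm <- outward_normals(lumen)
  pos <- lumen
  len <- rep(0, nrow(lumen))
  active <- rep(TRUE, nrow(lumen))
  for (it in seq_len(max_steps)) {
    if (!any(active)) break
    p <- pos[active, , drop = FALSE]
    d1 <- nrm[active, , drop = FALSE]
    # nearest outer vertex per active point
    dx <- outer(p[, 1], outer_d[, 1], "-")
    dy <- outer(p[, 2], outer_d[, 2], "-")
    near <- max.col(-(dx * dx + dy * dy), ties.method = "first")
    d2 <- outer_d[near, , drop = FALSE] - p
    nv <- sqrt(rowSums(d2^2))
    small <- nv < 1e-12
    d2[small, ] <- d1[small, , drop = FALSE]
    nv[small] <- 1
    d2 <- d2 / nv
    dir <- d1 + d2
    ndir <- sqrt(rowSums(dir^2))
    deg <- ndir < 1e-8
    dir[deg, ] <- d2[deg, , drop = FALSE]
    ndir[deg] <- 1
    dir <- dir / ndir
    u <- dir * step
    tc <- segment_contour_crossing(p, u, outer)
    hit <- is.finite(tc)
    li <- which(active)
    len[li[hit]] <- len[li[hit]] + tc[hit] * step
    len[li[!hit]] <- len[li[!hit]] + step
    pos[li[!hit], ] <- p[!hit, , drop = FALSE] + u[!hit, , drop = FALSE]
    active[li[hit]] <- FALSE
  }
  if (any(active))
    stop("equal-step march exceeded step budget at lumen point(s) ",
         paste(which(active), collapse = ", "))
  len
}

#' @rdname wall_thickness
#' @export
wall_thickness_equal_step <- function(point_index, lumen, outer,
                                      step = 0.155, max_steps = 400) {
  th <- wall_thickness(lumen, outer, step = step, max_steps = max_steps)
  stopifnot(point_index >= 1, point_index <= length(th))
  th[point_index]
}

#' Shrink-stretch specification
#'
#' Pre-conditioning parameters that take the imaged (pressurized, axially
#' stretched) geometry back to an estimated no-load state: an axial
#' shrink of 1 - 1/axial_stretch (9% for the default 10% stretch) and
#' circumferential shrink factors sought within the stated brackets
#' (about 8-12% for the lumen, 2-5% for the outer wall).
#'
#' @param axial_stretch in-vivo axial stretch ratio (default 1.10).
#' @param lumen_bracket,outer_bracket admissible circumferential shrink
#'   ranges for lumen and outer wall.
#' @return an object of class `shrink_spec`.
#' @export
shrink_spec <- function(axial_stretch = 1.10,
                        lumen_bracket = c(0.08, 0.12),
                        outer_bracket = c(0.02, 0.05)) {
  stopifnot(axial_stretch > 0, length(lumen_bracket) == 2,
            length(outer_bracket) == 2)
  structure(list(axial_stretch = axial_stretch,
                 axial_shrink = 1 - 1 / axial_stretch,
                 lumen_bracket = sort(lumen_bracket),
                 outer_bracket = sort(outer_bracket)),
            class = "shrink_spec")
}

#' Shrink a slice to its estimated no-load geometry
#'
#' Both contours are scaled about the lumen centroid by (1 - shrink)
#' factors chosen so that total vessel mass is conserved: under
#' incompressibility, the no-load wall cross-sectional area must equal
#' the in-vivo wall area times the axial stretch (the no-load vessel is
#' shorter by 1/axial_stretch). Scaling a polygon by k scales its area by
#' exactly k^2, so the conservation equation is solved in closed form:
#' the outer shrink is targeted at the midpoint of its bracket, the lumen
#' shrink follows from area conservation and is clamped to its bracket
#' (re-solving the outer shrink) if needed.
#'
#' @param slice a [contour_slice()].
#' @param spec a [shrink_spec()].
#' @param wall_area_target in-vivo wall cross-sectional area (mm^2);
#'   defaults to the slice's own measured wall area.
#' @return object of class `shrink_result`: the no-load `slice`, the
#'   achieved `lumen_shrink`, `outer_shrink`, `axial_shrink`, and the
#'   conserved `no_load_wall_area` (mm^2).
#' @export
shrink_stretch <- function(slice, spec = shrink_spec(),
                           wall_area_target = NULL) {
  stopifnot(inherits(slice, "contour_slice"), inherits(spec, "shrink_spec"))
  A_l <- abs(contour_area(slice$lumen))
  A_o <- abs(contour_area(slice$outer))
  if (is.null(wall_area_target)) wall_area_target <- A_o - A_l
  stopifnot(wall_area_target > 0)
  target <- wall_area_target * spec$axial_stretch
  lb <- spec$lumen_bracket; ob <- spec$outer_bracket
  if (spec$axial_stretch == 1 && isTRUE(all.equal(wall_area_target, A_o - A_l)) &&
      lb[1] <= 0 && ob[1] <= 0) {
    s_l <- 0; s_o <- 0
  } else {
    s_o <- mean(ob)
    lum_sq <- (A_o * (1 - s_o)^2 - target) / A_l
    s_l <- if (lum_sq > 0) 1 - sqrt(lum_sq) else Inf
    if (s_l < lb[1] || s_l > lb[2]) {
      s_l <- if (s_l < lb[1]) lb[1] else lb[2]
      out_sq <- (target + A_l * (1 - s_l)^2) / A_o
      s_o <- 1 - sqrt(out_sq)
      if (s_o < ob[1] - 1e-12 || s_o > ob[2] + 1e-12)
        stop(sprintf(paste0("no shrink solution in bracket: outer shrink %.4f ",
                            "needed with lumen shrink clamped to %.2f ",
                            "(outer bracket [%.2f, %.2f])"),
                     s_o, s_l, ob[1], ob[2]))
      s_o <- min(max(s_o, ob[1]), ob[2])
    }
  }
  ctr <- contour_centroid(slice$lumen)
  scale_about <- function(xy, k)
    sweep(sweep(xy, 2, ctr, "-") * k, 2, ctr, "+")
  new_slice <- slice
  new_slice$lumen <- scale_about(slice$lumen, 1 - s_l)
  new_slice$outer <- scale_about(slice$outer, 1 - s_o)
  structure(list(slice = new_slice,
                 lumen_shrink = s_l, outer_shrink = s_o,
                 axial_shrink = spec$axial_shrink,
                 axial_stretch = spec$axial_stretch,
                 no_load_wall_area = A_o * (1 - s_o)^2 - A_l * (1 - s_l)^2,
                 in_vivo_wall_area = wall_area_target),
            class = "shrink_result")
}

#' @export
print.shrink_result <- function(x, ...) {
  cat(sprintf(paste0("no-load geometry: lumen shrink %.3f, outer shrink %.3f, ",
                     "axial shrink %.3f\nwall area %.4f mm^2 (in vivo %.4f, ",
                     "ratio %.6f = axial stretch)\n"),
              x$lumen_shrink, x$outer_shrink, x$axial_shrink,
              x$no_load_wall_area, x$in_vivo_wall_area,
              x$no_load_wall_area / x$in_vivo_wall_area))
  invisible(x)
}
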