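#' Wall thickness increase (WTI)
#'
#' Point-wise plaque progression measure: follow-up minus baseline wall
#' thickness. Negative values indicate plaque regression.
#'
#' @param wt_t1,wt_t2 baseline and follow-up wall thickness in mm (> 0).
#' @return WTI in mm (vectorized).
#' @export
compute_wti <- function(wt_t1, wt_t2) {
  if (any(wt_t1 <= 0) || any(wt_t2 <= 0))
    stop("wall thicknesses must be positive")
  wt_t2 - wt_t1
}

#' Pearson correlation with exact t-based two-sided p-value
#'
#' Sample Pearson r and the two-sided p-value from the exact transform
#' t = r sqrt((n - 2) / (1 - r^2)) on Student t with n - 2 degrees of
#' freedom — the p-value of the slope in simple linear regression.
#'
#' @param x,y numeric vectors of equal length n >= 3 with non-zero
#'   variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- min(max(cor(x, y), -1), 1)
  p <- if (abs(r) == 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Two-sided p-value implied by a correlation coefficient
#'
#' @param r Pearson correlation coefficient(s).
#' @param n sample size(s), n >= 3.
#' @return two-sided p-value(s) from the exact t transform.
#' @export
p_from_r <- function(r, n) {
  stopifnot(all(n >= 3), all(abs(r) <= 1))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  ifelse(abs(r) == 1, 0, 2 * pt(-abs(tval), df = n - 2))
}

#' Classify a per-pair correlation
#'
#' Significantly positive (r > 0, p < alpha), significantly negative
#' (r < 0, p < alpha), or no significance otherwise. The inequality is
#' strict: p exactly equal to alpha is not significant, and r = 0 is
#' never classified as a direction.
#'
#' @param r,p correlation coefficients and two-sided p-values.
#' @param alpha significance level (default 0.05).
#' @return character vector in
#'   `c("positive", "negative", "no_significance")`.
#' @export
classify_correlation <- function(r, p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), all(abs(r) <= 1),
            alpha > 0, alpha < 1)
  ifelse(p < alpha & r > 0, "positive",
         ifelse(p < alpha & r < 0, "negative", "no_significance"))
}

#' Count the positive / negative / no-significance classifications
#'
#' @param records data.frame with a `classification` column (or a bare
#'   character vector of classifications).
#' @return named integer vector `(positive, negative, no_significance)`;
#'   the counts always sum to the number of records.
#' @export
correlation_ratio <- function(records) {
  cls <- if (is.data.frame(records)) records$classification else records
  if (length(cls) == 0) stop("no records")
  lv <- c("positive", "negative", "no_significance")
  stopifnot(all(cls %in% lv))
  table(factor(cls, levels = lv))[lv] |> as.vector() |>
    setNames(lv)
}

#' Pooled confidence interval over per-case correlation coefficients
#'
#' Mean of the case-level r values with a Student-t interval:
#' mean +/- t_{1-(1-level)/2, m-1} * SD / sqrt(m), SD the sample
#' standard deviation. Plain (untransformed) averaging is used; it is
#' the convention that reproduces the published summary intervals from
#' their per-case columns.
#'
#' @param r_values per-case Pearson coefficients (m >= 2).
#' @param level coverage (default 0.95).
#' @return list with `mean`, `lo`, `hi`.
#' @export
pooled_ci <- function(r_values, level = 0.95) {
  m <- length(r_values)
  if (m < 2) stop("need at least 2 correlation values")
  stopifnot(level > 0, level < 1)
  mu <- mean(r_values)
  half <- qt(1 - (1 - level) / 2, df = m - 1) * sd(r_values) / sqrt(m)
  list(mean = mu, lo = mu - half, hi = mu + half)
}

.stress_column <- function(stress, timepoint, phase) {
  stress <- match.arg(toupper(stress), c("FSS", "FMSS", "PWS"))
  timepoint <- match.arg(timepoint, c("baseline", "followup"))
  phase <- match.arg(phase, c("maxQ", "minQ"))
  paste(tolower(stress), timepoint, phase, sep = "_")
}

#' Per-pair correlation summary for one stress / time point / flow phase
#'
#' For every scan pair in a per-point table, correlates WTI against the
#' requested stress (FSS, FMSS or PWS, evaluated at the baseline or
#' follow-up scan and at the maximum or minimum flow-rate phase),
#' classifies each pair, and pools the per-pair r values into counts and
#' a confidence interval — one column of the published summary tables.
#'
#' @param points data.frame with columns `pair_id`, `wti`, and the
#'   per-point stress columns named `<stress>_<timepoint>_<phase>`
#'   (e.g. `fss_baseline_maxQ`).
#' @param stress `"FSS"`, `"FMSS"` or `"PWS"`.
#' @param timepoint `"baseline"` or `"followup"`.
#' @param phase `"maxQ"` or `"minQ"`.
#' @param alpha significance level for classification.
#' @param level coverage of the pooled interval.
#' @return object of class `progression_summary`: `records` (one row per
#'   pair: case_id, n_points, r, p, classification), `counts`, `ci`, and
#'   the request metadata.
#' @export
build_summary <- function(points, stress, timepoint, phase,
                          alpha = 0.05, level = 0.95) {
  col <- .stress_column(stress, timepoint, phase)
  if (!col %in% names(points))
    stop("per-point table has no column '", col, "'")
  stopifnot(all(c("pair_id", "wti") %in% names(points)))
  ids <- sort(unique(points$pair_id))
  rec <- lapply(ids, function(id) {
    d <- points[points$pair_id == id, ]
    if (nrow(d) < 3) {
      warning("pair ", id, " has fewer than 3 points; excluded")
      return(NULL)
    }
    ct <- pearson_r_p(d[[col]], d$wti)
    data.frame(case_id = id, n_points = ct$n, r = ct$r, p = ct$p,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  if (is.null(rec) || nrow(rec) == 0) stop("no usable pairs")
  rec$classification <- classify_correlation(rec$r, rec$p, alpha)
  structure(list(records = rec,
                 counts = correlation_ratio(rec),
                 ci = pooled_ci(rec$r, level),
                 stress = toupper(stress), timepoint = timepoint,
                 phase = phase, alpha = alpha, level = level),
            class = "progression_summary")
}

#' @export
print.progression_summary <- function(x, digits = 3, ...) {
  cat(sprintf("WTI vs %s (%s scan, %s): %d pairs\n",
              x$stress, x$timepoint, x$phase, nrow(x$records)))
  cat(sprintf("  positive/negative/no-significance = %d/%d/%d (alpha = %g)\n",
              x$counts["positive"], x$counts["negative"],
              x$counts["no_significance"], x$alpha))
  cat(sprintf("  mean r %.3f, %d%% CI (%.*f, %.*f)\n",
              x$ci$mean, round(100 * x$level),
              digits, x$ci$lo, digits, x$ci$hi))
  invisible(x)
}
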