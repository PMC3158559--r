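#' Read the shipped transcriptions of the published summary tables
#'
#' The package ships plain-CSV transcriptions of the two published
#' per-case correlation tables of the source study this pipeline
#' re-implements (32 scan pairs; WTI vs FSS and WTI vs PWS, at baseline
#' and follow-up and at the maximum and minimum flow-rate phases),
#' together with their printed footers (count triples and pooled 95%
#' intervals). p-value cells printed as censored (e.g. "< .001") are
#' kept as strings.
#'
#' @param dir directory with `table1_fss.csv`, `table2_pws.csv`,
#'   `table_footers.csv`; defaults to the package fixtures.
#' @return list with `table1_fss`, `table2_pws` (data.frames) and
#'   `footers`.
#' @export
read_printed_tables <- function(dir = NULL) {
  dir <- dir %||% system.file("extdata", package = "plaqueprog")
  read1 <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing fixture ", p)
    read.csv(p, stringsAsFactors = FALSE, colClasses = "character",
             check.names = FALSE)
  }
  list(table1_fss = read1("table1_fss.csv"),
       table2_pws = read1("table2_pws.csv"),
       footers = read1("table_footers.csv"))
}

.printed_decimals <- function(s) {
  s <- sub("^[^.]*\\.", "", s)
  nchar(s)
}

#' Verify the published summary statistics from their per-case values
#'
#' Re-derives, from the printed per-case (r, p) columns alone: the
#' positive / negative / no-significance count triples (alpha = 0.05,
#' strict inequality), the pooled 95% confidence intervals (mean-r
#' Student-t interval), and every numerically printed p-value from its
#' (r, n) pair via the exact t transform. A printed p matches when it
#' lies within `tol_p` of the p-interval implied by the 3-dp rounding of
#' the printed r (so rounding of r cannot create spurious mismatches);
#' censored cells ("< .001") are checked one-sided. Confidence-interval
#' bounds are compared at their own printed precision (half an ulp of
#' the printed digits).
#'
#' @param tables a [read_printed_tables()] result (default: the shipped
#'   fixtures).
#' @param alpha significance level used by the classification.
#' @param tol_p p-value tolerance beyond printed-r rounding propagation.
#' @return object of class `table_verification` with data.frames
#'   `counts` (per table x column: recomputed and printed triples,
#'   match flag), `ci` (recomputed and printed bounds, match flags) and
#'   `pvalues` (per numeric or censored cell).
#' @export
verify_printed_tables <- function(tables = read_printed_tables(),
                                  alpha = 0.05, tol_p = 0.003) {
  cols <- c("baseline_maxQ", "baseline_minQ", "followup_maxQ", "followup_minQ")
  counts <- list(); cis <- list(); pvals <- list()
  for (tab in c("table1_fss", "table2_pws")) {
    d <- tables[[tab]]
    n <- as.numeric(d$n)
    for (cl in cols) {
      r <- as.numeric(d[[paste0(cl, "_r")]])
      ps <- d[[paste0(cl, "_p")]]
      cens <- grepl("<", ps)
      pnum <- suppressWarnings(as.numeric(ps))
      if (any(is.na(pnum) & !cens))
        stop("malformed p cell in ", tab, " ", cl)
      # classification counts from the printed values themselves
      sig <- cens | (!is.na(pnum) & pnum < alpha)
      cls <- ifelse(sig & r > 0, "positive",
                    ifelse(sig & r < 0, "negative", "no_significance"))
      cnt <- correlation_ratio(cls)
      f <- tables$footers[tables$footers$table == tab &
                            tables$footers$column == cl, ]
      counts[[paste(tab, cl)]] <- data.frame(
        table = tab, column = cl,
        positive = cnt["positive"], negative = cnt["negative"],
        no_significance = cnt["no_significance"],
        printed_positive = as.integer(f$positive),
        printed_negative = as.integer(f$negative),
        printed_no_significance = as.integer(f$no_significance),
        match = cnt["positive"] == as.integer(f$positive) &&
          cnt["negative"] == as.integer(f$negative) &&
          cnt["no_significance"] == as.integer(f$no_significance),
        row.names = NULL)
      # pooled interval vs printed footer, at the footer's own precision
      ci <- pooled_ci(r, 0.95)
      tol_lo <- 0.5 * 10^-.printed_decimals(f$ci_lo) + 1e-12
      tol_hi <- 0.5 * 10^-.printed_decimals(f$ci_hi) + 1e-12
      cis[[paste(tab, cl)]] <- data.frame(
        table = tab, column = cl, mean_r = ci$mean,
        lo = ci$lo, hi = ci$hi,
        printed_lo = as.numeric(f$ci_lo), printed_hi = as.numeric(f$ci_hi),
        match_lo = abs(ci$lo - as.numeric(f$ci_lo)) <= tol_lo,
        match_hi = abs(ci$hi - as.numeric(f$ci_hi)) <= tol_hi,
        row.names = NULL)
      # p-value recomputation from (r, n), propagating printed-r rounding
      p_at <- function(rr, nn) p_from_r(pmin(abs(rr), 1), nn)
      p_lo <- p_at(abs(r) + 0.0005, n)   # smallest p compatible with r
      p_hi <- p_at(pmax(abs(r) - 0.0005, 0), n)
      p_point <- p_at(r, n)
      thr <- suppressWarnings(as.numeric(sub("<", "", ps)))
      thr[cens & (is.na(thr) | thr <= 0)] <- 0.001
      delta <- ifelse(cens, NA,
                      pmax(0, p_lo - pnum, pnum - p_hi))
      match <- ifelse(cens, p_lo < thr, delta <= tol_p)
      pvals[[paste(tab, cl)]] <- data.frame(
        table = tab, column = cl, case = d$case, n = n, r = r,
        printed_p = ps, recomputed_p = p_point,
        delta = delta, censored = cens, match = match,
        row.names = NULL)
    }
  }
  structure(list(counts = do.call(rbind, counts),
                 ci = do.call(rbind, cis),
                 pvalues = do.call(rbind, pvals),
                 alpha = alpha, tol_p = tol_p),
            class = "table_verification")
}

#' @export
print.table_verification <- function(x, ...) {
  cat(sprintf("published-table verification (alpha = %g):\n", x$alpha))
  cat(sprintf("  count triples: %d/%d columns match exactly\n",
              sum(x$counts$match), nrow(x$counts)))
  cat(sprintf("  95%% CIs: %d/%d bounds match at printed precision\n",
              sum(x$ci$match_lo) + sum(x$ci$match_hi), 2L * nrow(x$ci)))
  cat(sprintf("  p-values: %d/%d cells consistent (tol %g beyond r-rounding)\n",
              sum(x$pvalues$match), nrow(x$pvalues), x$tol_p))
  bad_ci <- x$ci[!(x$ci$match_lo & x$ci$match_hi), , drop = FALSE]
  if (nrow(bad_ci) > 0)
    for (i in seq_len(nrow(bad_ci)))
      cat(sprintf(paste0("  mismatch: %s %s printed (%g, %g) vs recomputed ",
                         "(%.4f, %.4f)\n"),
                  bad_ci$table[i], bad_ci$column[i], bad_ci$printed_lo[i],
                  bad_ci$printed_hi[i], bad_ci$lo[i], bad_ci$hi[i]))
  bad_p <- x$pvalues[!x$pvalues$match, , drop = FALSE]
  if (nrow(bad_p) > 0)
    for (i in seq_len(nrow(bad_p)))
      cat(sprintf("  p mismatch: %s %s %s printed %s recomputed %.4f\n",
                  bad_p$table[i], bad_p$column[i], bad_p$case[i],
                  bad_p$printed_p[i], bad_p$recomputed_p[i]))
  invisible(x)
}
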