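# Per-point measurement of one scan pair: matched slices, canonical
# 100-point lumen sampling, equal-step thickness at both time points,
# shear and wall stress at both phases on each scan's own geometry.
.pair_points <- function(pair, config, stresses, step) {
  m <- match_slices(pair$baseline, pair$follow_up)
  if (nrow(m) == 0) {
    warning("pair ", pair$pair_id, ": no matched CCA/ICA slices; skipped")
    return(NULL)
  }
  npt <- config$points_per_slice
  flow <- config$flow
  mech <- config$mechanics
  need_pws <- "PWS" %in% stresses
  need_fss <- any(c("FSS", "FMSS") %in% stresses)

  per_scan <- function(scan, slice_idx) {
    sl <- scan$slices[slice_idx]
    lum <- lapply(sl, function(s) resample_contour(s$lumen, npt))
    th <- lapply(seq_along(sl), function(i)
      wall_thickness(lum[[i]], sl[[i]]$outer, step = step))
    out <- list(lumen = lum, thickness = th)
    if (need_fss || need_pws) {
      wf <- build_waveform(pair$systolic, pair$diastolic,
                           n_time = flow$n_time,
                           drop_fraction = flow$drop_fraction)
      a_min <- min(vapply(lum, function(l)
        sqrt(abs(contour_area(l)) / pi), numeric(1))) / 10
      fr <- flow_rate_series(wf, a_min, flow$segment_length, mu = flow$mu)
      out$phases <- fr
    }
    if (need_fss) {
      out$fss <- lapply(c(maxQ = "maxQ", minQ = "minQ"), function(ph)
        lapply(lum, function(l)
          fss_slice(l, out$phases[[ph]]$Q, out$phases[[ph]]$p_lumen,
                    mu = flow$mu, gamma = flow$gamma, bounds = flow$bounds)))
    }
    if (need_pws) {
      noload <- lapply(seq_along(sl), function(i) {
        sr <- shrink_stretch(sl[[i]], shrink_spec(mech$lambda_z))
        ctr <- contour_centroid(lum[[i]])
        rho <- sqrt((lum[[i]][, 1] - ctr[1])^2 + (lum[[i]][, 2] - ctr[2])^2)
        list(Ri = (1 - sr$lumen_shrink) * rho / 10,
             h = ((1 - sr$outer_shrink) * (rho + th[[i]]) -
                    (1 - sr$lumen_shrink) * rho) / 10)
      })
      out$pws <- lapply(c(maxQ = "maxQ", minQ = "minQ"), function(ph) {
        p_ph <- out$phases[[ph]]$p_lumen
        lapply(noload, function(nl)
          pws_at_point(nl$Ri, nl$h, p_ph, lambda_z = mech$lambda_z,
                       params = mech$params, n_grid = mech$n_grid))
      })
    }
    out
  }

  t1 <- per_scan(pair$baseline, m$baseline_slice)
  t2 <- per_scan(pair$follow_up, m$followup_slice)

  rows <- lapply(seq_len(nrow(m)), function(i) {
    wti <- compute_wti(t1$thickness[[i]], t2$thickness[[i]])
    d <- data.frame(pair_id = pair$pair_id, patient_id = pair$patient_id,
                    segment = m$segment[i], offset = m$offset[i],
                    point = seq_len(npt),
                    thickness_baseline = t1$thickness[[i]],
                    thickness_followup = t2$thickness[[i]],
                    wti = wti, stringsAsFactors = FALSE)
    if (need_fss) for (ph in c("maxQ", "minQ")) {
      d[[paste0("fss_baseline_", ph)]] <- t1$fss[[ph]][[i]]$fss
      d[[paste0("fss_followup_", ph)]] <- t2$fss[[ph]][[i]]$fss
      d[[paste0("fmss_baseline_", ph)]] <- t1$fss[[ph]][[i]]$fmss
      d[[paste0("fmss_followup_", ph)]] <- t2$fss[[ph]][[i]]$fmss
    }
    if (need_pws) for (ph in c("maxQ", "minQ")) {
      d[[paste0("pws_baseline_", ph)]] <- t1$pws[[ph]][[i]]
      d[[paste0("pws_followup_", ph)]] <- t2$pws[[ph]][[i]]
    }
    d
  })
  do.call(rbind, rows)
}

#' Run the full point-wise progression analysis on a cohort
#'
#' For every scan pair: matches slices on the bifurcation landmark
#' (CCA/ICA only), samples 100 evenly spaced lumen points per slice with
#' a shared canonical start, measures wall thickness at both time points
#' with the piecewise equal-step method, computes WTI, evaluates FSS and
#' FMSS (Poiseuille surrogate with traction projection) and PWS
#' (equivalent-cylinder Mooney-Rivlin inflation on the shrink-stretched
#' no-load geometry) at the maximum and minimum flow-rate phases on each
#' scan's own geometry, and builds the per-pair correlation summaries
#' for every requested stress x time point x phase combination.
#'
#' @param cohort a [generate_cohort()] or [read_cohort()] result.
#' @param stresses subset of `c("FSS", "FMSS", "PWS")`.
#' @param alpha significance level for classification.
#' @param level pooled-interval coverage.
#' @param config analysis parameters; defaults to the cohort's own
#'   config (required for cohorts read from files without one).
#' @param quiet suppress per-pair progress messages.
#' @return object of class `progression_analysis`: `points` (per-point
#'   table), `summaries` (named list of [build_summary()] results),
#'   `alpha`, `stresses`.
#' @export
analyze_cohort <- function(cohort, stresses = c("FSS", "FMSS", "PWS"),
                           alpha = 0.05, level = 0.95, config = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(cohort, "plaque_cohort"))
  stresses <- match.arg(toupper(stresses), c("FSS", "FMSS", "PWS"),
                        several.ok = TRUE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  config <- config %||% cohort$config
  if (is.null(config)) config <- cohort_config()
  step <- config$in_plane_resolution / 2
  band <- config$points_per_slice * c(4, 10)
  pts <- vector("list", length(cohort$pairs))
  for (k in seq_along(cohort$pairs)) {
    pts[[k]] <- .pair_points(cohort$pairs[[k]], config, stresses, step)
    if (!is.null(pts[[k]])) {
      n_here <- nrow(pts[[k]])
      if (!quiet)
        message(sprintf("pair %d: %d data points", cohort$pairs[[k]]$pair_id,
                        n_here))
      if (n_here < band[1] || n_here > band[2])
        warning(sprintf("pair %d has %d data points, outside the usual %d-%d",
                        cohort$pairs[[k]]$pair_id, n_here, band[1], band[2]))
    }
  }
  points <- do.call(rbind, pts)
  combos <- expand.grid(stress = stresses,
                        timepoint = c("baseline", "followup"),
                        phase = c("maxQ", "minQ"),
                        stringsAsFactors = FALSE)
  summaries <- lapply(seq_len(nrow(combos)), function(i)
    build_summary(points, combos$stress[i], combos$timepoint[i],
                  combos$phase[i], alpha = alpha, level = level))
  names(summaries) <- apply(combos, 1, paste, collapse = "_")
  structure(list(points = points, summaries = summaries,
                 alpha = alpha, stresses = stresses),
            class = "progression_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.progression_analysis <- function(x, ...) {
  cat(sprintf("progression analysis: %d pairs, %d points, stresses %s\n",
              length(unique(x$points$pair_id)), nrow(x$points),
              paste(x$stresses, collapse = "/")))
  for (s in x$summaries) print(s)
  invisible(x)
}

#' @export
summary.progression_analysis <- function(object, ...) {
  do.call(rbind, lapply(object$summaries, function(s)
    data.frame(stress = s$stress, timepoint = s$timepoint, phase = s$phase,
               positive = s$counts["positive"], negative = s$counts["negative"],
               no_significance = s$counts["no_significance"],
               mean_r = s$ci$mean, ci_lo = s$ci$lo, ci_hi = s$ci$hi,
               row.names = NULL)))
}

#' Compare FSS and FMSS correlation results
#'
#' Side-by-side count triples and pooled intervals for the traditional
#' longitudinal wall shear (FSS) and the all-tangential-direction
#' maximum shear (FMSS) on the same cohort.
#'
#' @param analysis a [analyze_cohort()] result containing both stresses.
#' @return data.frame, one row per stress x timepoint x phase.
#' @export
fss_fmss_comparison <- function(analysis) {
  stopifnot(inherits(analysis, "progression_analysis"),
            all(c("FSS", "FMSS") %in% analysis$stresses))
  s <- summary(analysis)
  s[s$stress %in% c("FSS", "FMSS"), , drop = FALSE]
}

#' Run the end-to-end pipeline and write its artifacts
#'
#' Generates (or accepts) a cohort, runs [analyze_cohort()], and writes
#' plain CSV/JSON artifacts to `out`: the per-point table, one summary
#' CSV per stress x time point x phase (records plus count/CI footer),
#' the FSS/FMSS comparison, and a run manifest (config hash, seed,
#' package version, per-stage row counts). Outputs are deterministic:
#' the same config and seed reproduce identical files.
#'
#' @param config a [cohort_config()]; ignored if `cohort` is supplied.
#' @param out output directory (created if missing).
#' @param seed optional seed overriding `config$seed`.
#' @param cohort optional pre-built cohort.
#' @param stresses,alpha,level passed to [analyze_cohort()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly, with the analysis attached as
#'   attribute `"analysis"`.
#' @export
run_pipeline <- function(config = cohort_config(), out, seed = NULL,
                         cohort = NULL, stresses = c("FSS", "FMSS", "PWS"),
                         alpha = 0.05, level = 0.95, quiet = TRUE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  analysis <- analyze_cohort(cohort, stresses = stresses, alpha = alpha,
                             level = level, config = cohort$config %||% config,
                             quiet = quiet)
  write_det_csv <- function(d, f) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) sprintf("%.12g", x))
    write.csv(d, file.path(out, f), row.names = FALSE, quote = FALSE)
  }
  write_det_csv(analysis$points, "points.csv")
  for (nm in names(analysis$summaries)) {
    s <- analysis$summaries[[nm]]
    rec <- s$records
    footer <- data.frame(case_id = c("positive", "negative",
                                     "no_significance", "ci_lo", "ci_hi"),
                         n_points = NA, r = NA,
                         p = c(s$counts, s$ci$lo, s$ci$hi),
                         classification = "", stringsAsFactors = FALSE)
    write_det_csv(rbind(rec, footer), paste0("summary_", nm, ".csv"))
  }
  if (all(c("FSS", "FMSS") %in% stresses))
    write_det_csv(fss_fmss_comparison(analysis), "comparison_fss_fmss.csv")
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  manifest <- list(
    package = "plaqueprog",
    version = as.character(packageVersion("plaqueprog")),
    seed = config$seed, config_hash = cfg_hash,
    alpha = alpha, level = level, stresses = stresses,
    n_pairs = length(cohort$pairs), n_points = nrow(analysis$points),
    n_summaries = length(analysis$summaries),
    files = sort(c("points.csv", paste0("summary_",
                                        names(analysis$summaries), ".csv"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(manifest, analysis = analysis))
}
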