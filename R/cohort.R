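#' Configuration for the synthetic serial-contour cohort generator
#'
#' Describes the study conditions being emulated: serial carotid
#' vessel-wall scans forming baseline/follow-up pairs (default 32 pairs
#' from 14 patients, 4-10 matched slices per pair at 2 mm spacing, 100
#' lumen points per slice on a 0.31 mm image plane, patient-specific
#' systolic/diastolic arm pressures) and a controllable ground-truth
#' coupling between point-wise wall thickness increase and the baseline
#' stress fields:
#' WTI = beta0 + beta_fss * FSS + beta_pws * PWS + Normal(0, noise_sd).
#'
#' @param n_patients number of patients (pairs are assigned round-robin).
#' @param n_pairs number of scan pairs.
#' @param slices_per_pair_range integer range of matched slices per pair,
#'   within \[4, 10\].
#' @param points_per_slice lumen points sampled per slice (>= 3).
#' @param slice_thickness axial slice spacing in mm.
#' @param in_plane_resolution image-plane resolution in mm.
#' @param pressure_range list with `systolic` and `diastolic` uniform
#'   ranges in mmHg.
#' @param coupling list with `beta0` (mm), `beta_fss` (mm per dyn/cm^2),
#'   `beta_pws` (mm per dyn/cm^2), `noise_sd` (mm, >= 0).
#' @param lumen_radius_range per-pair mean lumen radius range (mm).
#' @param wall_thickness_ratio_range per-pair mean wall thickness as a
#'   fraction of the lumen radius. The default range keeps every slice's
#'   lumen/outer area ratio inside the band for which the circumferential
#'   shrink brackets of [shrink_spec()] admit an exact mass-conserving
#'   no-load state.
#' @param stenosis_severity_range fractional lumen-radius reduction at
#'   the stenosis throat (same feasibility consideration).
#' @param harmonic_amplitude bound on the Fourier perturbation of the
#'   lumen (harmonics 2-4), as a fraction of the local radius.
#' @param eca_slice include an external-carotid slice per scan (it is
#'   generated but excluded from analysis, as in practice).
#' @param flow list: `mu` (poise), `segment_length` (cm),
#'   `drop_fraction`, `n_time`, `gamma`, `bounds` (see [fss_slice()]).
#' @param mechanics list: `lambda_z`, `n_grid`, and a
#'   [material_params()] under `params`.
#' @param seed integer root seed for the single random stream.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 14,
                          n_pairs = 32,
                          slices_per_pair_range = c(4, 10),
                          points_per_slice = 100,
                          slice_thickness = 2.0,
                          in_plane_resolution = 0.31,
                          pressure_range = list(systolic = c(110, 160),
                                                diastolic = c(65, 95)),
                          coupling = list(beta0 = 0.08, beta_fss = 0.0015,
                                          beta_pws = -8e-8, noise_sd = 0.15),
                          lumen_radius_range = c(2.4, 3.6),
                          wall_thickness_ratio_range = c(0.17, 0.21),
                          stenosis_severity_range = c(0.12, 0.22),
                          harmonic_amplitude = 0.05,
                          eca_slice = TRUE,
                          flow = list(mu = 0.04, segment_length = 5,
                                      drop_fraction = 0.02, n_time = 200,
                                      gamma = 1, bounds = c(0.5, 2)),
                          mechanics = list(lambda_z = 1.10, n_grid = 200,
                                           params = material_params()),
                          seed = 1L) {
  spr <- as.integer(slices_per_pair_range)
  if (length(spr) != 2 || spr[1] > spr[2] || spr[1] < 4 || spr[2] > 10)
    stop("slices_per_pair_range must lie within [4, 10]")
  stopifnot(n_patients >= 1, n_pairs >= 1, points_per_slice >= 3,
            slice_thickness > 0, in_plane_resolution > 0,
            coupling$noise_sd >= 0,
            all(lumen_radius_range > 0), all(wall_thickness_ratio_range > 0))
  cfg <- list(n_patients = as.integer(n_patients),
              n_pairs = as.integer(n_pairs),
              slices_per_pair_range = spr,
              points_per_slice = as.integer(points_per_slice),
              slice_thickness = slice_thickness,
              in_plane_resolution = in_plane_resolution,
              pressure_range = pressure_range,
              coupling = coupling,
              lumen_radius_range = lumen_radius_range,
              wall_thickness_ratio_range = wall_thickness_ratio_range,
              stenosis_severity_range = stenosis_severity_range,
              harmonic_amplitude = harmonic_amplitude,
              eca_slice = isTRUE(eca_slice),
              flow = flow, mechanics = mechanics,
              seed = as.integer(seed))
  structure(cfg, class = "cohort_config")
}

# Closed-form slice geometry shared by the generator and its truth table.
# r_lum(theta) = R0 (1 + sum a_m cos(m theta + phi_m)); thickness
# h(theta) = h0 (1 + 0.25 e cos(theta - psi)) + (Rbase - R0) *
# (0.5 + 0.5 cos(theta - psi)), so lumen loss at the stenosis goes into
# the wall on the plaque side.
.slice_geometry <- function(theta, pars) {
  mods <- rep(1, length(theta))
  for (j in seq_along(pars$harm_m))
    mods <- mods + pars$harm_a[j] * cos(pars$harm_m[j] * theta + pars$harm_phi[j])
  r_lum <- pars$R0 * mods
  h <- pars$h0 * (1 + 0.25 * pars$ecc * cos(theta - pars$psi)) +
    (pars$Rbase - pars$R0) * (0.5 + 0.5 * cos(theta - pars$psi))
  list(r_lum = r_lum, h = h)
}

.make_slice_pars <- function(pair_pars, z) {
  R0 <- pair_pars$Rbase *
    (1 - pair_pars$sev * exp(-((z - pair_pars$z_s) / pair_pars$w)^2))
  c(pair_pars[c("Rbase", "h0", "ecc", "psi", "harm_m", "harm_a", "harm_phi")],
    list(R0 = R0))
}

.slice_from_pars <- function(pars, center, segment, axial_index, z,
                             n_gen = 128) {
  theta <- 2 * pi * (seq_len(n_gen) - 1) / n_gen
  g <- .slice_geometry(theta, pars)
  lum <- cbind(center[1] + g$r_lum * cos(theta),
               center[2] + g$r_lum * sin(theta))
  out <- cbind(center[1] + (g$r_lum + g$h) * cos(theta),
               center[2] + (g$r_lum + g$h) * sin(theta))
  contour_slice(lum, out, segment, axial_index, z)
}

#' Generate a synthetic serial cohort with known ground truth
#'
#' Builds baseline scans of Fourier-perturbed eccentric lumens inside an
#' outer wall, with a stenosis throat near the bifurcation; computes the
#' baseline flow shear stress (always) and plaque wall stress (when
#' `beta_pws != 0`) with the package's own hemodynamics and wall
#' mechanics modules; draws the point-wise wall thickness increase
#' WTI = beta0 + beta_fss FSS + beta_pws PWS + noise; and displaces the
#' follow-up lumen inward by WTI along the outward normal (the outer
#' wall is kept, so thickening grows into the lumen). WTI values that
#' would close the lumen or cross the outer wall are clipped with a
#' warning. The stored ground truth decomposes every point's WTI into
#' its baseline, FSS, PWS and noise terms, which sum to the stored WTI
#' exactly.
#'
#' @param config a [cohort_config()].
#' @return object of class `plaque_cohort`: `pairs` (list of scan pairs,
#'   each with `baseline`/`follow_up` [plaque_scan()]s, pressures and
#'   ids), `truth` (`points` data.frame and the `coupling` used), and
#'   the `config`. Deterministic given `config$seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cp <- config$coupling
  need_pws <- cp$beta_pws != 0
  pairs <- vector("list", config$n_pairs)
  truth <- vector("list", config$n_pairs)
  n_clipped <- 0L
  for (j in seq_len(config$n_pairs)) {
    patient <- ((j - 1L) %% config$n_patients) + 1L
    sys <- runif(1, config$pressure_range$systolic[1],
                 config$pressure_range$systolic[2])
    dia <- runif(1, config$pressure_range$diastolic[1],
                 config$pressure_range$diastolic[2])
    n_sl <- if (diff(config$slices_per_pair_range) == 0)
      config$slices_per_pair_range[1] else
        sample(config$slices_per_pair_range[1]:config$slices_per_pair_range[2], 1)
    bif <- as.integer(ceiling(n_sl / 2))
    zs <- (seq_len(n_sl) - 1) * config$slice_thickness
    pair_pars <- list(
      Rbase = runif(1, config$lumen_radius_range[1], config$lumen_radius_range[2]),
      h0_ratio = runif(1, config$wall_thickness_ratio_range[1],
                       config$wall_thickness_ratio_range[2]),
      sev = runif(1, config$stenosis_severity_range[1],
                  config$stenosis_severity_range[2]),
      z_s = zs[bif] + runif(1, -config$slice_thickness, config$slice_thickness),
      w = runif(1, 2, 6),
      psi = runif(1, 0, 2 * pi),
      ecc = runif(1, 0, 1),
      harm_m = 2:4,
      harm_a = runif(3, 0, config$harmonic_amplitude),
      harm_phi = runif(3, 0, 2 * pi))
    pair_pars$h0 <- pair_pars$h0_ratio * pair_pars$Rbase
    centers <- matrix(runif(2 * n_sl, -0.3, 0.3), ncol = 2)

    base_slices <- vector("list", n_sl)
    slice_pars <- vector("list", n_sl)
    lum100 <- vector("list", n_sl)
    for (i in seq_len(n_sl)) {
      seg <- if (i < bif) "CCA" else "ICA"
      slice_pars[[i]] <- .make_slice_pars(pair_pars, zs[i])
      sl <- .slice_from_pars(slice_pars[[i]], centers[i, ], seg, i, zs[i])
      # store the lumen at analysis resolution so baseline and follow-up
      # share the point labeling exactly
      sl$lumen <- resample_contour(sl$lumen, config$points_per_slice)
      base_slices[[i]] <- sl
      lum100[[i]] <- sl$lumen
    }

    # hemodynamics on the baseline geometry
    wf <- build_waveform(sys, dia, n_time = config$flow$n_time,
                         drop_fraction = config$flow$drop_fraction)
    a_min <- min(vapply(lum100, function(l) sqrt(abs(contour_area(l)) / pi),
                        numeric(1))) / 10
    fr <- flow_rate_series(wf, a_min, config$flow$segment_length,
                           mu = config$flow$mu)

    pair_truth <- vector("list", n_sl)
    fup_slices <- base_slices
    for (i in seq_len(n_sl)) {
      lum <- lum100[[i]]
      ctr <- contour_centroid(lum)
      rho <- sqrt((lum[, 1] - ctr[1])^2 + (lum[, 2] - ctr[2])^2)
      nrm <- outward_normals(lum)
      cgen <- centers[i, ]
      th_gen <- atan2(lum[, 2] - cgen[2], lum[, 1] - cgen[1])
      h_true <- .slice_geometry(th_gen, slice_pars[[i]])$h
      f_max <- fss_slice(lum, fr$maxQ$Q, fr$maxQ$p_lumen, mu = config$flow$mu,
                         gamma = config$flow$gamma, bounds = config$flow$bounds)
      f_min <- fss_slice(lum, fr$minQ$Q, fr$minQ$p_lumen, mu = config$flow$mu,
                         gamma = config$flow$gamma, bounds = config$flow$bounds)
      pws_max <- rep(NA_real_, nrow(lum))
      if (need_pws) {
        sr <- shrink_stretch(base_slices[[i]],
                             shrink_spec(config$mechanics$lambda_z))
        Ri_nl <- (1 - sr$lumen_shrink) * rho / 10
        h_nl <- ((1 - sr$outer_shrink) * (rho + h_true) -
                   (1 - sr$lumen_shrink) * rho) / 10
        pws_max <- pws_at_point(Ri_nl, h_nl, fr$maxQ$p_lumen,
                                lambda_z = config$mechanics$lambda_z,
                                params = config$mechanics$params,
                                n_grid = config$mechanics$n_grid)
      }
      eps <- rnorm(nrow(lum), 0, cp$noise_sd)
      term_fss <- cp$beta_fss * f_max$fss
      term_pws <- if (need_pws) cp$beta_pws * pws_max else rep(0, nrow(lum))
      wti <- cp$beta0 + term_fss + term_pws + eps
      lim_lo <- -0.5 * h_true
      lim_hi <- 0.3 * rho
      clip <- wti < lim_lo | wti > lim_hi
      n_clipped <- n_clipped + sum(clip)
      wti <- pmin(pmax(wti, lim_lo), lim_hi)
      # keep the follow-up lumen/outer area ratio inside the band for
      # which the shrink-stretch brackets admit a mass-conserving
      # no-load state; if a slice drifts outside, shift its WTI field
      # uniformly to the nearest band edge (counts as clipping)
      A_o <- abs(contour_area(base_slices[[i]]$outer))
      ratio_of <- function(delta)
        abs(contour_area(lum - (wti + delta) * nrm)) / A_o
      band <- c(0.45, 0.77)
      r0 <- ratio_of(0)
      if (r0 < band[1] || r0 > band[2]) {
        tgt <- if (r0 < band[1]) band[1] else band[2]
        delta <- tryCatch(
          stats::uniroot(function(d) ratio_of(d) - tgt, c(-1.5, 1.5),
                         tol = 1e-10)$root,
          error = function(e) 0)
        wti <- wti + delta
        n_clipped <- n_clipped + nrow(lum)
      }
      fup <- base_slices[[i]]
      fup$lumen <- lum - wti * nrm
      fup_slices[[i]] <- fup
      pair_truth[[i]] <- data.frame(
        pair_id = j, patient_id = patient,
        segment = base_slices[[i]]$segment, offset = i - bif,
        point = seq_len(nrow(lum)),
        x = lum[, 1], y = lum[, 2], rho = rho,
        thickness_t1 = h_true,
        fss_baseline_maxQ = f_max$fss, fss_baseline_minQ = f_min$fss,
        pws_baseline_maxQ = pws_max,
        wti_base_term = cp$beta0, wti_fss_term = term_fss,
        wti_pws_term = term_pws, wti_noise = eps + (wti - (cp$beta0 +
          term_fss + term_pws + eps)),
        wti = wti, stringsAsFactors = FALSE)
    }

    if (config$eca_slice) {
      eca_pars <- slice_pars[[bif]]
      eca_pars$R0 <- 0.6 * eca_pars$R0
      eca_pars$Rbase <- 0.6 * eca_pars$Rbase
      eca <- .slice_from_pars(eca_pars, c(2.5 * pair_pars$Rbase, 0), "ECA",
                              bif, zs[bif])
      base_slices <- c(base_slices, list(eca))
      fup_slices <- c(fup_slices, list(eca))
    }

    pairs[[j]] <- structure(list(
      pair_id = j, patient_id = patient,
      systolic = sys, diastolic = dia,
      baseline = plaque_scan(base_slices, bif, sprintf("P%02d_T1", j)),
      follow_up = plaque_scan(fup_slices, bif, sprintf("P%02d_T2", j))),
      class = "scan_pair")
    truth[[j]] <- do.call(rbind, pair_truth)
  }
  if (n_clipped > 0)
    warning(n_clipped, " WTI value(s) clipped to keep contours valid")
  structure(list(pairs = pairs,
                 truth = list(points = do.call(rbind, truth), coupling = cp),
                 config = config),
            class = "plaque_cohort")
}

#' @export
print.plaque_cohort <- function(x, ...) {
  np <- vapply(x$pairs, function(p)
    sum(vapply(p$baseline$slices, function(s)
      s$segment %in% c("CCA", "ICA"), logical(1))), numeric(1))
  cat(sprintf(paste0("synthetic serial cohort: %d scan pairs (%d patients), ",
                     "%d-%d matched slices/pair, %d points/slice\n"),
              length(x$pairs), x$config$n_patients, min(np), max(np),
              x$config$points_per_slice))
  cat(sprintf("coupling: beta0 %g mm, beta_fss %g, beta_pws %g, noise sd %g mm\n",
              x$truth$coupling$beta0, x$truth$coupling$beta_fss,
              x$truth$coupling$beta_pws, x$truth$coupling$noise_sd))
  invisible(x)
}

# --- contour-stack serialization ------------------------------------------

.write_slice_csv <- function(slice, path) {
  fmt <- function(xy, type) sprintf("%s,%d,%.17g,%.17g", type,
                                    seq_len(nrow(xy)), xy[, 1], xy[, 2])
  writeLines(c("contour_type,vertex_index,x_mm,y_mm",
               fmt(slice$lumen, "lumen"), fmt(slice$outer, "outer")), path)
}

.read_slice_csv <- function(path, meta, where) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("contour_type", "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(d)))
    stop("malformed slice file ", where, ": missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "))
  get <- function(type) {
    dd <- d[d$contour_type == type, ]
    if (nrow(dd) < 3)
      stop("malformed slice file ", where, ": ", type,
           " contour has fewer than 3 vertices")
    dd <- dd[order(dd$vertex_index), ]
    xy <- cbind(dd$x_mm, dd$y_mm)
    # an open (truncated) contour shows up as an oversized closing edge
    el <- sqrt(rowSums((xy[c(2:nrow(xy), 1), ] - xy)^2))
    if (el[length(el)] > 5 * stats::median(el[-length(el)]))
      stop("open ", type, " contour in slice ", where,
           ": closing gap exceeds 5x the median edge length")
    xy
  }
  contour_slice(get("lumen"), get("outer"), meta$segment,
                meta$axial_index, meta$axial_position)
}

#' Write / read a cohort as a contour-stack directory
#'
#' Plain-text exchange format: an `index.json` with patient/pair ids,
#' pressures (mmHg), bifurcation slice indices, resolution and slice
#' thickness, plus one CSV per slice (columns `contour_type` in
#' lumen/outer, `vertex_index`, `x_mm`, `y_mm`). The ground-truth point
#' table, if present, is stored as `truth.csv`. The round trip is
#' lossless (vertices are written at full precision). Reading validates
#' contours and errors naming the offending slice; pairs with fewer than
#' 4 matched slices load with a warning.
#'
#' @param cohort a [generate_cohort()] result (or a compatible structure).
#' @param path directory to create/read.
#' @return `write_cohort`: `path`, invisibly. `read_cohort`: a
#'   `plaque_cohort` (without config if none was stored).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "plaque_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  idx <- list(format = "plaqueprog-contour-stack", version = 1L,
              in_plane_resolution = cohort$config$in_plane_resolution,
              slice_thickness = cohort$config$slice_thickness,
              seed = cohort$config$seed,
              coupling = cohort$truth$coupling,
              pairs = list())
  for (p in cohort$pairs) {
    pdir <- sprintf("pair%02d", p$pair_id)
    entry <- list(pair_id = p$pair_id, patient_id = p$patient_id,
                  systolic = p$systolic, diastolic = p$diastolic)
    for (tp in c("baseline", "follow_up")) {
      scan <- p[[tp]]
      sdir <- file.path(path, pdir, tp)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      slices <- lapply(seq_along(scan$slices), function(i) {
        s <- scan$slices[[i]]
        f <- sprintf("slice%02d.csv", i)
        .write_slice_csv(s, file.path(sdir, f))
        list(file = file.path(pdir, tp, f), segment = s$segment,
             axial_index = s$axial_index, axial_position = s$axial_position)
      })
      entry[[tp]] <- list(scan_id = scan$scan_id,
                          bifurcation_index = scan$bifurcation_index,
                          slices = slices)
    }
    idx$pairs[[length(idx$pairs) + 1L]] <- entry
  }
  jsonlite::write_json(idx, file.path(path, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cohort$truth$points))
    write.csv(cohort$truth$points, file.path(path, "truth.csv"),
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  idx_file <- file.path(path, "index.json")
  if (!file.exists(idx_file)) stop("no index.json under ", path)
  idx <- jsonlite::read_json(idx_file)
  pairs <- lapply(idx$pairs, function(entry) {
    scans <- lapply(c("baseline", "follow_up"), function(tp) {
      sc <- entry[[tp]]
      slices <- lapply(sc$slices, function(m)
        .read_slice_csv(file.path(path, m$file), m,
                        sprintf("pair %s %s %s", entry$pair_id, tp, m$file)))
      plaque_scan(slices, sc$bifurcation_index, sc$scan_id)
    })
    n_matched <- sum(vapply(scans[[1]]$slices, function(s)
      s$segment %in% c("CCA", "ICA"), logical(1)))
    if (n_matched < 4)
      warning("pair ", entry$pair_id, " has only ", n_matched,
              " matched slices (fewer than the usual minimum of 4)")
    structure(list(pair_id = entry$pair_id, patient_id = entry$patient_id,
                   systolic = entry$systolic, diastolic = entry$diastolic,
                   baseline = scans[[1]], follow_up = scans[[2]]),
              class = "scan_pair")
  })
  truth <- NULL
  if (file.exists(file.path(path, "truth.csv")))
    truth <- list(points = read.csv(file.path(path, "truth.csv"),
                                    stringsAsFactors = FALSE),
                  coupling = idx$coupling)
  structure(list(pairs = pairs, truth = truth,
                 config = NULL,
                 in_plane_resolution = idx$in_plane_resolution,
                 slice_thickness = idx$slice_thickness),
            class = "plaque_cohort")
}
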