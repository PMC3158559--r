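#' Normalized pressure pulse template
#'
#' Parametric single-cycle pressure shape used when no measured waveform
#' is supplied: a squared-sinusoid systolic pulse peaking at 30% of the
#' cycle with a small dicrotic bump during early diastole, normalized on
#' the evaluation grid to exactly \[0, 1\]. All reported statistics use
#' only the extreme flow phases, so they are insensitive to the template
#' shape between the extremes.
#'
#' @param t times as fractions of the cycle in \[0, 1).
#' @return numeric vector in \[0, 1\] (0 and 1 attained on the grid).
#' @export
waveform_template <- function(t) {
  stopifnot(all(t >= 0 & t < 1))
  raw <- ifelse(t < 0.6, sin(pi * t / 0.6)^2, 0) +
    0.12 * exp(-((t - 0.7) / 0.06)^2)
  (raw - min(raw)) / (max(raw) - min(raw))
}

#' Build a patient-specific pulsatile pressure waveform
#'
#' The normalized template is rescaled affinely so the inlet pressure
#' spans exactly \[diastolic, systolic\] (the patient's arm-cuff
#' pressures). The outlet profile equals the inlet minus a pressure drop
#' kept proportional to the instantaneous inlet pressure
#' (`drop_fraction`, default 2%), so the drop scales with each patient's
#' arm pressures and the flow surrogate retains a systolic maximum and a
#' diastolic minimum.
#'
#' @param systolic,diastolic arm pressures in mmHg (systolic > diastolic > 0).
#' @param n_time number of uniform time samples over one cycle.
#' @param period cycle duration in seconds.
#' @param drop_fraction inlet-to-outlet pressure drop as a fraction of
#'   the instantaneous inlet pressure.
#' @param template function mapping cycle fraction to \[0, 1\] shape.
#' @return object of class `pressure_waveform` with fields `time` (s),
#'   `inlet`, `outlet` (dyn/cm^2), `systolic`, `diastolic` (mmHg).
#' @export
build_waveform <- function(systolic, diastolic, n_time = 200, period = 1,
                           drop_fraction = 0.02,
                           template = waveform_template) {
  if (!(systolic > diastolic))
    stop("systolic pressure must exceed diastolic pressure")
  stopifnot(diastolic > 0, n_time >= 8, drop_fraction >= 0, drop_fraction < 1)
  frac <- (seq_len(n_time) - 1) / n_time
  s <- template(frac)
  if (abs(min(s)) > 1e-9 || abs(max(s) - 1) > 1e-9)
    stop("template must span [0, 1] on the time grid")
  inlet <- mmHg_to_dyn(diastolic + (systolic - diastolic) * s)
  structure(list(time = frac * period, inlet = inlet,
                 outlet = inlet * (1 - drop_fraction),
                 systolic = systolic, diastolic = diastolic,
                 period = period, drop_fraction = drop_fraction),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf(paste0("pressure waveform: %d samples over %.2f s, inlet ",
                     "%.0f-%.0f dyn/cm^2 (%g/%g mmHg), drop %.1f%%\n"),
              length(x$time), x$period, min(x$inlet), max(x$inlet),
              x$diastolic, x$systolic, 100 * x$drop_fraction))
  invisible(x)
}

#' Flow-rate series and extreme flow phases
#'
#' Poiseuille resistance of the equivalent tube converts the
#' inlet-outlet pressure drop into a volumetric flow-rate series,
#' Q(t) = dp(t) pi a^4 / (8 mu L). The radius `lumen_radius` should be
#' the minimum lumen equivalent radius across the analyzed slices so
#' that stenosis severity limits the flow. The maximum and minimum
#' flow-rate instants in the cycle (ties broken by the earliest time
#' index) are returned as the two extraction phases, carrying the inlet
#' pressure at that instant as the lumen pressure.
#'
#' @param waveform a [build_waveform()] result.
#' @param lumen_radius equivalent tube radius in cm.
#' @param segment_length tube length in cm.
#' @param mu dynamic viscosity in poise.
#' @return list with `Q` (cm^3/s series), `maxQ` and `minQ` phase lists
#'   (`label`, `time_index`, `Q`, `p_lumen` in dyn/cm^2).
#' @export
flow_rate_series <- function(waveform, lumen_radius, segment_length, mu = 0.04) {
  stopifnot(inherits(waveform, "pressure_waveform"),
            lumen_radius > 0, segment_length > 0, mu > 0)
  dp <- waveform$inlet - waveform$outlet
  Q <- dp * pi * lumen_radius^4 / (8 * mu * segment_length)
  phase <- function(label, idx)
    list(label = label, time_index = idx, Q = Q[idx],
         p_lumen = waveform$inlet[idx])
  list(Q = Q,
       maxQ = phase("maxQ", which.max(Q)),
       minQ = phase("minQ", which.min(Q)))
}

.check_unit <- function(v, name) {
  if (length(v) != 3 || abs(sqrt(sum(v^2)) - 1) > 1e-8)
    stop(name, " must be a unit 3-vector")
  v
}

#' Fluid traction and shear projections at a lumen point
#'
#' Generic operators on the fluid stress tensor
#' sigma = -p I + mu (grad u + grad u^T) at a lumen surface point:
#' `traction_vector` returns the stress vector sigma . n acting on the
#' tangential surface with unit normal n; `longitudinal_fss` projects it
#' onto the unit longitudinal tangent t, giving the traditional wall
#' flow shear stress; `fmss` returns the magnitude of the full
#' tangential component of sigma . n, the maximum shear over all
#' tangential directions, which always dominates |FSS|. For the traction
#' exerted by the blood on the wall, `n` is the lumen-surface normal
#' directed into the flow.
#'
#' @param sigma symmetric 3 x 3 stress tensor (dyn/cm^2).
#' @param n unit normal to the lumen surface.
#' @param t_long unit longitudinal tangent, orthogonal to `n`.
#' @return `traction_vector`: length-3 stress vector; `longitudinal_fss`
#'   and `fmss`: scalars in dyn/cm^2.
#' @export
traction_vector <- function(sigma, n) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == c(3, 3)))
  if (max(abs(sigma - t(sigma))) > 1e-12 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  n <- .check_unit(n, "n")
  as.vector(sigma %*% n)
}

#' @rdname traction_vector
#' @export
longitudinal_fss <- function(sigma, n, t_long) {
  t_long <- .check_unit(t_long, "t_long")
  n <- .check_unit(n, "n")
  if (abs(sum(n * t_long)) > 1e-8)
    stop("t_long must be orthogonal to n")
  sum(traction_vector(sigma, n) * t_long)
}

#' @rdname traction_vector
#' @export
fmss <- function(sigma, n) {
  tr <- traction_vector(sigma, n)
  tang <- tr - sum(tr * n) * n
  sqrt(sum(tang^2))
}

#' Poiseuille stress tensor at the wall of a straight tube
#'
#' Fluid stress tensor of fully developed Poiseuille flow of rate `Q`
#' along `axis` in a tube of radius `a`, evaluated at the wall point in
#' radial direction `e_r` (unit, orthogonal to the axis):
#' sigma = -p I + mu gamma (e_r x axis + axis x e_r) with wall shear rate
#' gamma = -4 Q / (pi a^3).
#'
#' @param Q flow rate in cm^3/s.
#' @param a tube radius in cm.
#' @param mu viscosity in poise.
#' @param p local pressure in dyn/cm^2.
#' @param e_r unit radial direction at the wall point.
#' @param axis unit flow axis.
#' @return 3 x 3 stress tensor in dyn/cm^2.
#' @export
poiseuille_stress_tensor <- function(Q, a, mu = 0.04, p = 0,
                                     e_r = c(1, 0, 0), axis = c(0, 0, 1)) {
  stopifnot(a > 0, mu > 0)
  e_r <- .check_unit(e_r, "e_r"); axis <- .check_unit(axis, "axis")
  if (abs(sum(e_r * axis)) > 1e-8) stop("e_r must be orthogonal to axis")
  gam <- -4 * Q / (pi * a^3)          # du_z/dr at the wall
  -p * diag(3) + mu * gam * (outer(e_r, axis) + outer(axis, e_r))
}

# Per-point effective tube radius on a slice: the slice equivalent radius
# modulated by local narrowing (distance of the lumen point from the lumen
# centroid relative to its mean), clamped to bounds x the slice radius.
# Points on inward-bulging plaque have a smaller effective radius, hence
# higher shear.
.effective_radius <- function(lumen, gamma = 1, bounds = c(0.5, 2)) {
  ctr <- contour_centroid(lumen)
  rho <- sqrt((lumen[, 1] - ctr[1])^2 + (lumen[, 2] - ctr[2])^2)
  a_slice <- sqrt(abs(contour_area(lumen)) / pi)
  ratio <- pmin(pmax((rho / mean(rho))^gamma, bounds[1]), bounds[2])
  list(a_eff = a_slice * ratio, a_slice = a_slice, rho = rho)
}

#' Wall shear stress at the lumen points of a slice
#'
#' Desk-scale surrogate for the lumen shear field of one slice: the
#' Poiseuille stress tensor for flow `Q` is assembled per point with the
#' slice equivalent radius modulated by local lumen narrowing (exponent
#' `gamma`, clamped to `bounds` times the slice radius), and the generic
#' traction/projection operators are applied with the point's surface
#' normal and longitudinal tangent. On a circular slice every point gets
#' the classical value 4 mu Q / (pi a^3); FSS is linear in both Q and
#' mu, and FMSS >= |FSS| everywhere.
#'
#' @param lumen resampled lumen contour (n x 2, mm, counter-clockwise).
#' @param Q flow rate (cm^3/s) of the phase.
#' @param p_lumen lumen pressure (dyn/cm^2) of the phase.
#' @param mu blood viscosity in poise (default 0.04).
#' @param gamma narrowing-modulation exponent.
#' @param bounds clamp for the effective-radius ratio.
#' @return data.frame with `fss` and `fmss` (dyn/cm^2) per lumen point,
#'   plus the `a_eff` used (cm).
#' @export
fss_slice <- function(lumen, Q, p_lumen = 0, mu = 0.04, gamma = 1,
                      bounds = c(0.5, 2)) {
  lumen <- as_contour(lumen)
  eff <- .effective_radius(lumen, gamma = gamma, bounds = bounds)
  a_eff_cm <- eff$a_eff / 10          # contours are in mm, flow in CGS
  if (any(a_eff_cm <= 0)) stop("non-positive effective radius")
  fss <- 4 * mu * Q / (pi * a_eff_cm^3)
  data.frame(fss = fss, fmss = abs(fss), a_eff = a_eff_cm)
}

#' Shear stresses at one lumen point via the projection operators
#'
#' Single-point form of [fss_slice()]: assembles the local Poiseuille
#' stress tensor for the given effective radius and applies
#' [longitudinal_fss()] and [fmss()]. `normal` is the in-plane outward
#' lumen normal (pointing into the wall); the traction on the wall is
#' taken with the flow-side normal, so forward flow yields positive FSS
#' along `t_long`.
#'
#' @param a_eff local effective tube radius in cm.
#' @param Q flow rate in cm^3/s.
#' @param p_lumen local pressure in dyn/cm^2.
#' @param mu viscosity in poise.
#' @param normal in-plane outward unit normal (length 2 or 3).
#' @param t_long unit longitudinal tangent (default the tube axis).
#' @return list with `fss`, `fmss`, and the traction vector.
#' @export
fss_at_point <- function(a_eff, Q, p_lumen = 0, mu = 0.04,
                         normal = c(1, 0), t_long = c(0, 0, 1)) {
  if (a_eff <= 0) stop("non-positive effective radius")
  if (length(normal) == 2) normal <- c(normal, 0)
  normal <- .check_unit(normal, "normal")
  axis <- c(0, 0, 1)
  e_r <- normal - sum(normal * axis) * axis
  e_r <- e_r / sqrt(sum(e_r^2))
  sig <- poiseuille_stress_tensor(Q, a_eff, mu = mu, p = p_lumen,
                                  e_r = e_r, axis = axis)
  n_flow <- -normal                   # lumen-surface normal into the blood
  t_use <- t_long - sum(t_long * n_flow) * n_flow
  t_use <- t_use / sqrt(sum(t_use^2))
  list(fss = longitudinal_fss(sig, n_flow, t_use),
       fmss = fmss(sig, n_flow),
       traction = traction_vector(sig, n_flow))
}
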