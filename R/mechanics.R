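#' Modified Mooney-Rivlin material parameters for the vessel wall
#'
#' Isotropic incompressible hyperelastic law with a linear and an
#' exponential term in the first strain invariant:
#' W = c1 (I1 - 3) + c2 (I2 - 3) + D1 (exp(D2 (I1 - 3)) - 1).
#' Defaults are literature values for advanced carotid plaque tissue
#' (c1 = 368000 dyn/cm^2, c2 = 0, D1 = 144000 dyn/cm^2, D2 = 2.0).
#'
#' @param c1,c2 linear coefficients (dyn/cm^2), c1 > 0, c2 >= 0.
#' @param D1 exponential amplitude (dyn/cm^2), > 0.
#' @param D2 exponential rate (dimensionless), > 0.
#' @return object of class `material_params`.
#' @export
material_params <- function(c1 = 368000, c2 = 0, D1 = 144000, D2 = 2.0) {
  stopifnot(c1 > 0, c2 >= 0, D1 > 0, D2 > 0)
  structure(list(c1 = c1, c2 = c2, D1 = D1, D2 = D2),
            class = "material_params")
}

#' Strain energy density of the modified Mooney-Rivlin law
#'
#' @param I1,I2 first and second invariants of the right Cauchy-Green
#'   deformation tensor (3 at the undeformed reference).
#' @param params a [material_params()].
#' @return strain energy density in dyn/cm^2 (erg/cm^3); 0 at I1 = I2 = 3.
#' @export
strain_energy <- function(I1, I2 = 3, params = material_params()) {
  stopifnot(inherits(params, "material_params"))
  params$c1 * (I1 - 3) + params$c2 * (I2 - 3) +
    params$D1 * (exp(params$D2 * (I1 - 3)) - 1)
}

# dW/dI1 at given I1 (dW/dI2 is just c2).
.dW_dI1 <- function(I1, params)
  params$c1 + params$D1 * params$D2 * exp(params$D2 * (I1 - 3))

# Equilibrium residual of the inflated incompressible tube, vectorized over
# points. For inner deformed radius ri the incompressibility map is
# r(R) = sqrt(ri^2 + (R^2 - Ri^2)/lambda_z), and radial equilibrium
# d(sigma_rr)/dr = (sigma_tt - sigma_rr)/r integrates to
# p = int_ri^ro (sigma_tt - sigma_rr)/r dr. Returns that integral minus p
# (monotone increasing in ri), using trapezoidal quadrature on n_grid
# points uniform in the reference radius.
.tube_residual <- function(ri, Ri, Ro, p, lambda_z, params, n_grid) {
  u <- seq(0, 1, length.out = n_grid)
  R <- Ri + (Ro - Ri) %o% u                      # k x G, reference radii
  r2 <- ri^2 + (R^2 - Ri^2) / lambda_z           # deformed radii squared
  lt2 <- r2 / R^2                                # lambda_theta^2
  lr2 <- 1 / (lt2 * lambda_z^2)                  # lambda_r^2 (det F = 1)
  I1 <- lr2 + lt2 + lambda_z^2
  dsig <- 2 * .dW_dI1(I1, params) * (lt2 - lr2) -
    2 * params$c2 * (1 / lt2 - 1 / lr2)
  r <- sqrt(r2)
  f <- dsig / r
  G <- n_grid
  rowSums((f[, -1, drop = FALSE] + f[, -G, drop = FALSE]) / 2 *
            (r[, -1, drop = FALSE] - r[, -G, drop = FALSE])) - p
}

# Vectorized shooting (bisection on ri) for the inflated tube. Returns the
# converged inner deformed radii.
.tube_solve_ri <- function(Ri, Ro, p, lambda_z, params,
                           n_grid = 200, tol = 1e-10, max_iter = 200) {
  k <- length(Ri)
  lo <- Ri / sqrt(lambda_z)           # residual = -p <= 0 here
  hi <- lo * 1.05
  for (i in seq_len(60)) {
    res <- .tube_residual(hi, Ri, Ro, p, lambda_z, params, n_grid)
    if (all(res >= 0)) break
    hi[res < 0] <- lo[res < 0] + (hi[res < 0] - lo[res < 0]) * 2
  }
  if (any(.tube_residual(hi, Ri, Ro, p, lambda_z, params, n_grid) < 0))
    stop("tube inflation: failed to bracket the equilibrium radius")
  it <- 0
  while (max((hi - lo) / lo) > tol && it < max_iter) {
    mid <- (lo + hi) / 2
    res <- .tube_residual(mid, Ri, Ro, p, lambda_z, params, n_grid)
    neg <- res < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
    it <- it + 1
  }
  if (it >= max_iter) {
    res <- .tube_residual((lo + hi) / 2, Ri, Ro, p, lambda_z, params, n_grid)
    stop(sprintf("tube inflation did not converge: max residual %.3e dyn/cm^2",
                 max(abs(res))))
  }
  (lo + hi) / 2
}

# Principal Cauchy stresses at the deformed inner radius given converged ri.
.tube_inner_stress <- function(ri, Ri, p, lambda_z, params) {
  lt2 <- ri^2 / Ri^2
  lr2 <- 1 / (lt2 * lambda_z^2)
  I1 <- lr2 + lt2 + lambda_z^2
  W1 <- .dW_dI1(I1, params)
  s_tt <- -p + 2 * W1 * (lt2 - lr2) - 2 * params$c2 * (1 / lt2 - 1 / lr2)
  s_zz <- -p + 2 * W1 * (lambda_z^2 - lr2) -
    2 * params$c2 * (1 / lambda_z^2 - 1 / lr2)
  cbind(sigma_rr = -p, sigma_tt = s_tt, sigma_zz = s_zz)
}

#' Inflate an incompressible thick-walled cylinder
#'
#' Solves finite-strain radial equilibrium for an axisymmetric,
#' incompressible, modified Mooney-Rivlin tube with reference radii
#' (Ri, Ro), lumen pressure `p_lumen` on the inner face, traction-free
#' outer face, and fixed axial stretch. The incompressibility map
#' r(R) = sqrt(ri^2 + (R^2 - Ri^2)/lambda_z) reduces the problem to one
#' unknown, the deformed inner radius ri, found by bisection (shooting on
#' the outer traction condition) to 1e-10 relative tolerance on a
#' 200-point radial grid.
#'
#' This per-slice equivalent cylinder is the package's structural
#' surrogate for a full 3D fluid-structure-interaction wall model: it
#' retains the load bearing that drives wall stress (pressure, local
#' radius, local thickness).
#'
#' @param Ri,Ro reference (no-load) inner and outer radii in cm.
#' @param p_lumen lumen pressure in dyn/cm^2 (>= 0).
#' @param lambda_z axial stretch ratio (default 1.10).
#' @param params a [material_params()].
#' @param n_grid radial grid size.
#' @return object of class `tube_state`: deformed radii `ri`, `ro`, the
#'   radial `grid` (data.frame with R, r, sigma_rr, sigma_tt, sigma_zz in
#'   dyn/cm^2), the outer-boundary `residual`, and `pws`, the maximum
#'   principal stress at the lumen surface.
#' @export
inflate_tube <- function(Ri, Ro, p_lumen, lambda_z = 1.10,
                         params = material_params(), n_grid = 200) {
  stopifnot(length(Ri) == 1, length(Ro) == 1, Ri > 0, Ro > Ri,
            p_lumen >= 0, lambda_z > 0)
  ri <- .tube_solve_ri(Ri, Ro, p_lumen, lambda_z, params, n_grid = n_grid)
  u <- seq(0, 1, length.out = n_grid)
  R <- Ri + (Ro - Ri) * u
  r <- sqrt(ri^2 + (R^2 - Ri^2) / lambda_z)
  lt2 <- r^2 / R^2
  lr2 <- 1 / (lt2 * lambda_z^2)
  I1 <- lr2 + lt2 + lambda_z^2
  W1 <- .dW_dI1(I1, params)
  dsig <- 2 * W1 * (lt2 - lr2) - 2 * params$c2 * (1 / lt2 - 1 / lr2)
  f <- dsig / r
  dr <- diff(r)
  s_rr <- -p_lumen + c(0, cumsum((f[-1] + f[-n_grid]) / 2 * dr))
  s_tt <- s_rr + dsig
  s_zz <- s_rr + 2 * W1 * (lambda_z^2 - lr2) -
    2 * params$c2 * (1 / lambda_z^2 - 1 / lr2)
  structure(list(
    Ri = Ri, Ro = Ro, ri = ri, ro = r[n_grid], lambda_z = lambda_z,
    p_lumen = p_lumen, params = params,
    grid = data.frame(R = R, r = r, sigma_rr = s_rr, sigma_tt = s_tt,
                      sigma_zz = s_zz),
    residual = s_rr[n_grid],
    pws = max(s_tt[1], s_zz[1], -p_lumen)),
    class = "tube_state")
}

#' @export
print.tube_state <- function(x, ...) {
  cat(sprintf(paste0("inflated tube: Ri %.4f -> ri %.4f cm, Ro %.4f -> ro %.4f cm",
                     " (lambda_z %.2f)\n"),
              x$Ri, x$ri, x$Ro, x$ro, x$lambda_z),
      sprintf("lumen pressure %.0f dyn/cm^2 (%.1f mmHg); outer residual %.2e\n",
              x$p_lumen, dyn_to_mmHg(x$p_lumen), x$residual),
      sprintf("PWS (max principal stress at lumen) %.0f dyn/cm^2\n", x$pws))
  invisible(x)
}

#' Plaque wall stress at lumen points via equivalent cylinders
#'
#' For each point, the local no-load lumen radius and wall thickness
#' define an equivalent thick-walled cylinder that is inflated (see
#' [inflate_tube()]) to the lumen pressure of the requested cardiac
#' phase; PWS is the maximum principal Cauchy stress at the deformed
#' lumen surface. All arguments are vectorized over points; the same
#' shooting solver and radial grid as `inflate_tube` are used, so the
#' two agree to solver tolerance.
#'
#' @param Ri local no-load lumen radius in cm (vector).
#' @param thickness local no-load wall thickness in cm (vector).
#' @param p_lumen lumen pressure(s) in dyn/cm^2.
#' @param lambda_z axial stretch ratio.
#' @param params a [material_params()].
#' @param n_grid radial grid size.
#' @param chunk points solved per block (memory control).
#' @return numeric vector of PWS in dyn/cm^2.
#' @export
pws_at_point <- function(Ri, thickness, p_lumen, lambda_z = 1.10,
                         params = material_params(), n_grid = 200,
                         chunk = 4000L) {
  k <- max(length(Ri), length(thickness), length(p_lumen))
  Ri <- rep_len(Ri, k); h <- rep_len(thickness, k)
  p <- rep_len(p_lumen, k)
  stopifnot(all(Ri > 0), all(h > 0), all(p >= 0), lambda_z > 0)
  out <- numeric(k)
  for (start in seq(1, k, by = chunk)) {
    ii <- start:min(start + chunk - 1L, k)
    ri <- .tube_solve_ri(Ri[ii], Ri[ii] + h[ii], p[ii], lambda_z, params,
                         n_grid = n_grid)
    s <- .tube_inner_stress(ri, Ri[ii], p[ii], lambda_z, params)
    out[ii] <- pmax(s[, "sigma_tt"], s[, "sigma_zz"], -p[ii])
  }
  out
}
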