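---
title: "Methods: correlating serial plaque progression with flow shear and wall stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating serial plaque progression with flow shear and wall stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the measurement model

Advanced carotid plaques progress (or regress) over months to years.
On serial vessel-wall MRI, progression at a lumen point is quantified
as the **wall thickness increase** between a baseline and a follow-up
scan,

$$\mathrm{WTI} = \mathrm{WT}_{T2} - \mathrm{WT}_{T1},$$

with negative values meaning regression. The scientific question this
package operationalizes is whether point-wise WTI correlates with two
mechanical fields on the lumen at the two extreme flow phases of the
cardiac cycle: the **flow shear stress** (FSS, the fluid traction
projected on the longitudinal tangent; its all-tangential-direction
maximum is FMSS) and the **plaque wall stress** (PWS, the maximum
principal structural stress at the lumen surface). The analysis unit is
a *scan pair*; per pair, Pearson correlation between WTI and a stress
over 400-1000 points is classified as significantly positive,
significantly negative, or not significant at $\alpha = 0.05$ (strict
inequality), and per-table count triples and pooled mean-$r$
Student-$t$ confidence intervals summarize 32 pairs.

Because the patient MRI data behind the published tables are not
public, the package has two complementary surfaces:

1. **Table verification** — `verify_printed_tables()` re-derives every
   re-derivable number in the published summary tables (shipped as CSV
   transcriptions) from the printed per-case values: classification
   counts, pooled intervals, and each printed $p$ from its $(r, n)$.
2. **Synthetic cohorts** — `generate_cohort()` builds serial contour
   cohorts with the same structure and a controllable ground-truth
   coupling, so that the full measurement chain (geometry, mechanics,
   hemodynamics, statistics) can be exercised end to end with known
   truth.

## Geometry processing

Contours are closed planar polylines in mm on the 0.31 mm image plane,
2 mm slice spacing. Baseline and follow-up slices are matched by their
signed axial offset from the bifurcation slice, per carotid segment;
only CCA and ICA slices are analyzed.

**Canonical 100-point sampling.** Each lumen is resampled at 100 equal
arc-length steps starting from the vertex of maximum $x$ (ties by
maximum $y$). A vertex-anchored start keeps resampling exactly
idempotent, which is what makes the point index a stable shared label
between the two time points of a slice; the small residual start-point
drift between baseline and follow-up contours behaves as measurement
noise. Whether the original analysis matched points by angular index or
nearest distance is not derivable from the published tables; angular
index is used and documented as an interpretation.

**Piecewise equal-step thickness.** Wall thickness at a lumen point is
the arc length of a marched path: fixed steps of half the in-plane
resolution (0.155 mm) taken along the bisector of the point's outward
lumen normal and the direction to the nearest outer-wall vertex, until
the path crosses the outer contour (the final step is trimmed at the
exact crossing). Plain normal rays misbehave on irregular plaque
cross-sections; the bisector rule follows the wall. The exact published
construction of the equal-step method is not restated in the source
study, so this stepping rule is this package's own definition,
validated by its stated invariants: exactness on concentric annuli and
parallel walls, and a hard lower bound at the nearest-distance to the
outer contour (guaranteed because the path ends exactly on the outer
polygon).

**Shrink-stretch pre-conditioning.** Imaged geometry is pressurized and
axially stretched; mechanics needs a no-load reference. Contours are
scaled about the lumen centroid so that no-load wall area equals
in-vivo wall area times the 1.10 axial stretch (incompressible mass
conservation; the axial shrink is $1 - 1/1.10 \approx 9\%$). Scaling a
polygon by $k$ scales area by exactly $k^2$, so the conservation
equation is solved in closed form: the outer shrink is targeted at the
midpoint of its 2-5% bracket and the lumen shrink follows, clamped to
its 8-12% bracket (re-solving the outer shrink) when needed; geometry
for which no bracket solution exists is an error. These brackets imply
a feasible band of lumen/outer area ratios (about 0.43-0.78), which the
synthetic generator respects by construction.

## Wall mechanics surrogate

The published stress fields came from a 3D fluid-structure-interaction
finite-element model; reproducing that solver is out of scope here. The
package's structural surrogate is a **per-point equivalent cylinder**:
the local no-load lumen radius and wall thickness define an
incompressible, isotropic, modified Mooney-Rivlin thick-walled tube,

$$W = c_1 (I_1 - 3) + c_2 (I_2 - 3) + D_1 \left(e^{D_2 (I_1 - 3)} - 1\right),$$

with $c_1 = 3.68\times10^5$, $c_2 = 0$, $D_1 = 1.44\times10^5$
dyn/cm$^2$, $D_2 = 2.0$, inflated at fixed 10% axial stretch to the
lumen pressure of the requested phase. The incompressibility map
$r(R) = \sqrt{r_i^2 + (R^2 - R_i^2)/\lambda_z}$ reduces equilibrium to
one unknown, the deformed inner radius, found by bisection on the outer
traction-free condition ($10^{-10}$ relative, 200-point radial grid).
PWS is the maximum principal Cauchy stress at the deformed lumen. This
preserves what drives wall stress — pressure, local radius, local
thickness — at desk scale; it does not capture 3D stress concentration
around plaque components (which the published models also excluded) or
anisotropy. The solver is validated against the thin-wall Laplace limit
$\sigma_\theta \to p\,r_i/h$, exact incompressibility, both traction
boundary conditions, and a stiffness-pressure scaling identity.

Pressure at the maximum-flow phase is the patient's systolic arm
pressure; at the minimum-flow phase, the diastolic. PWS at the two
phases differs only through this pressure, and although the material is
nonlinear, the induced monotone map leaves per-pair correlation signs
and significance unchanged — the pipeline computes both phases
independently and the phase-invariance of PWS classifications is a
tested, emergent property rather than a baked-in shortcut.

## Hemodynamics surrogate

The pressure pulse is a normalized template (squared-sinusoid systolic
pulse peaking at 30% of the cycle with a small dicrotic bump) rescaled
affinely to each patient's diastolic-systolic range. The inlet-outlet
pressure drop is kept proportional to the instantaneous inlet pressure
(default 2%), so the drop scales with each patient's arm pressures. A
constant 2% of a 120/80 inlet over a 5 cm equivalent segment yields
flows of roughly 5-25 cm$^3$/s through stenotic lumens — the
physiologic carotid range; a drop proportional to pulse pressure alone
would freeze the flow waveform shape and erase the distinction between
the two extreme phases, so it was rejected. Flow rate follows
Poiseuille resistance, $Q(t) = \Delta p(t)\,\pi a^4 / (8 \mu L)$ with
$\mu = 0.04$ P and $a$ the minimum lumen equivalent radius across the
analyzed slices (stenosis limits flow). Only the extreme phases
$\max_t Q$ and $\min_t Q$ (earliest index on ties) enter any reported
statistic, so results are insensitive to the template shape between the
extremes.

At a lumen point, the fluid stress tensor
$\sigma = -p I + \mu(\nabla u + \nabla u^\top)$ of Poiseuille flow in a
tube of *effective local radius* is assembled and the generic operators
are applied: traction $\sigma \cdot n$, longitudinal shear
$(\sigma\cdot n)\cdot t$, and FMSS, the magnitude of the tangential
traction component (hence FMSS $\ge |$FSS$|$ identically). The
effective radius is the slice equivalent radius modulated by the
point's distance from the lumen centroid (exponent 1, clamped to 0.5-2
times the slice radius): points on inward-bulging plaque sit closer to
the centroid, get a smaller effective radius, and therefore higher
shear. A signed boundary-curvature modulation was considered and
rejected: for low-harmonic eccentric lumens the boundary is *flatter*
at inward bulges, which would push shear in the unphysical direction.
This modulation is the package's mechanism for spatial shear variation
— the published fields came from full 3D flow — and its exponent and
bounds are configuration values.

## The synthetic cohort generator

Defaults emulate the published study conditions: 32 scan pairs from 14
patients, 4-10 matched slices per pair, 100 points per slice (so
400-1000 points per pair), 2 mm slices, 0.31 mm in-plane resolution,
per-patient uniform systolic (110-160 mmHg) and diastolic (65-95 mmHg)
pressures. Lumens are Fourier-perturbed circles (harmonics 2-4, bounded
amplitude 5%) with per-pair mean radius 2.4-3.6 mm, eccentric wall
thickness, and a Gaussian-profile stenosis throat near the bifurcation
whose lumen loss is added to the wall on the plaque side. One ECA slice
per scan is generated and excluded downstream, as in practice.

Ground-truth progression is injected point-wise on the baseline
geometry:

$$\mathrm{WTI} = \beta_0 + \beta_{\mathrm{FSS}}\,\mathrm{FSS} +
\beta_{\mathrm{PWS}}\,\mathrm{PWS} + \varepsilon,\quad
\varepsilon \sim N(0, \sigma^2),$$

with FSS and PWS computed by the package's own surrogates at the
maximum-flow phase. The follow-up lumen is the baseline lumen displaced
inward by WTI along the outward normal (the outer wall is retained, so
thickening grows into the lumen). Defaults
($\beta_0 = 0.08$ mm, $\beta_{\mathrm{FSS}} = 1.5\times10^{-3}$,
$\beta_{\mathrm{PWS}} = -8\times10^{-8}$ mm per dyn/cm$^2$,
$\sigma = 0.15$ mm) were chosen once to produce weak per-pair
correlations of the magnitude seen in the published tables
($|r| \sim 0.1$-$0.4$) with WTI of order 0.1 mm over the scan interval;
the source study reports no WTI or lumen-size distributions to
calibrate against, so these are plausibility choices. Draws that would
close the lumen or cross the outer wall are clipped (with a warning),
and a slice whose follow-up lumen/outer area ratio would leave the
shrink-feasibility band is shifted uniformly back to the band edge,
also counted as clipping. Wall thickness (14-21% of lumen radius) and
stenosis severity (12-22% radius reduction) are kept inside the
shrink-bracket feasibility band; real advanced plaques are thicker
and more stenosed than this, a deliberate desk-scale compromise that
affects absolute stress levels, not the correlation machinery.

**What passing synthetic tests does and does not show.** The generator
emulates data *structure* (serial contours, matched slices, point
counts, pressures) and a known coupling; it does not emulate MRI pixel
noise, segmentation error, registration misalignment beyond the
bifurcation index, plaque components, or 3D flow features (secondary
flow, oscillatory shear). Recovery and calibration results therefore
validate the pipeline's statistics and surrogates, not the clinical
conclusions. Note also that measured follow-up FSS correlates with WTI
partly through geometry itself — progression narrows the lumen and
raises local shear — so follow-up correlations on synthetic cohorts are
systematically stronger than baseline ones, an effect the published
study also discusses.

## Statistics

Per pair, the sample Pearson $r$ between WTI and the requested stress
(at the requested time point's own geometry and the requested phase) is
converted to a two-sided $p$ via the exact transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom — identical
to the slope test of simple linear regression, which is how the
published tables describe their analysis. Classification is strict:
$p < 0.05$ and the sign of $r$; $p = 0.05$ exactly is not significant
(fixed by the published case whose $p$ moved from 0.043 to 0.056 and
was re-classified). The pooled interval is the plain (untransformed)
mean of case-level $r$ with a Student-$t$ half-width,
$\bar r \pm t_{0.975, m-1}\,s/\sqrt{m}$: this convention was confirmed
by recomputation to be the unique one (against Fisher-$z$ and normal
variants) that reproduces the printed intervals from the printed
per-case columns. Points within a pair are treated as independent,
replicating the published analysis rather than improving on it (no
autocorrelation correction, no multiple-testing adjustment).

Verification tolerances: a printed $p$ matches if it lies within 0.003
of the $p$-interval implied by the $\pm0.0005$ rounding of its printed
$r$; censored cells ("< .001") are checked one-sided; interval bounds
are compared at half an ulp of their own printed precision. One printed
bound (the follow-up Min-Q lower CI bound of the shear table, 0.01) is
inconsistent with its own printed per-case column, which implies
$-0.0005$ (essentially zero) under the convention that reproduces the
other fifteen bounds; the verification report flags it rather than
reproducing it.

## Numerical choices and degenerate inputs

* CGS units internally (dyn/cm$^2$, cm); 1 mmHg = 1333.2 dyn/cm$^2$ at
  boundaries; contours in mm.
* Tube inflation: bisection to $10^{-10}$ relative on the inner radius,
  trapezoidal quadrature on a 200-point radial grid; the unpressurized
  tube returns the exact identity map.
* Thickness marching: step 0.155 mm, budget 400 steps, error naming the
  point if the outer wall is never reached; degenerate bisector
  directions fall back to the nearest-outer direction.
* Resampling requires $\ge 3$ distinct vertices and non-zero perimeter;
  zero-variance series are an error in correlation (undefined), and
  pairs with fewer than 3 points are excluded from summaries with a
  warning; cohort files with fewer than 4 matched slices load with a
  warning so partial real-world data remain usable.
* Ties in flow extremes resolve to the earliest time index.
* All randomness flows from one integer seed through R's default
  generator; identical config and seed give byte-identical artifacts.

## Problem sizes

The shipped analyses run at the study's own scale: 32 pairs with 4-10
slices of 100 points (about 22,000 points), one full
stress-and-thickness measurement pass per time point, and 200
replicates of the 32-pair null cohort for calibration. On a single
core this is roughly a minute for a full cohort analysis and two
minutes for the null calibration.

## Known limitations

Decoupled per-point surrogates cannot reproduce absolute published
stress magnitudes or per-case $r$ values, only the machinery and its
qualitative behavior; the equal-step thickness rule is an
interpretation of an incompletely published construction; synthetic
severities and wall thicknesses are milder than advanced clinical
disease (shrink-bracket feasibility); and baseline-time-point
correlation patterns in synthetic cohorts reflect the injected
coupling, not the distinct biological mechanisms that the published
baseline tables may contain.
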