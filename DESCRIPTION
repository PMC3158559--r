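Package: plaqueprog
Title: Serial Carotid Plaque Progression Versus Flow Shear and Wall Stress
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Desk-scale analysis of advanced carotid plaque progression
    against mechanical stresses on serial vessel-wall contour data.
    Point-wise wall thickness increase (WTI) between baseline and
    follow-up scans is correlated with flow shear stress (FSS, with its
    all-tangential-direction maximum FMSS) and plaque wall stress (PWS)
    at the maximum and minimum flow-rate phases of the cardiac cycle.
    Includes a synthetic serial-cohort generator with controllable
    ground-truth coupling, piecewise equal-step wall thickness
    measurement, shrink-stretch pre-conditioning, incompressible
    modified Mooney-Rivlin thick-walled tube inflation for PWS, a
    locally Poiseuille wall-shear surrogate with generic traction
    projection operators, per-pair Pearson correlation classification
    with pooled confidence intervals, and a verification mode that
    re-derives published summary-table statistics from their printed
    per-case values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
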