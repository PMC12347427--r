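Package: stemshield
Title: Plane-Stress Finite-Element Prediction of Periprosthetic Bone
    Remodeling Around Short Femoral Stems
Version: 0.1.0
Authors@R: person("stemshield", "developers", role = c("aut", "cre"),
    email = "maintainers@stemshield.dev")
Description: Patient-specific 2D frontal-plane biomechanical analysis of the
    proximal femur after short-stem hip arthroplasty. Builds parametric femur
    and stem geometries, meshes the multi-material domain with a constrained
    Delaunay triangulation, solves plane-stress linear elasticity under
    physiological hip loading (joint contact force plus abductor reaction),
    converts strain energy density at the bone-implant interface into a
    mechanical remodeling stimulus, classifies per-Gruen-zone remodeling with
    a Frost mechanostat (lazy zone between lower and upper setpoints),
    calibrates the upper setpoint by exhaustive grid search against observed
    zone labels, and sweeps varus/neutral/valgus stem malposition to flag
    cortical overload. Includes a synthetic-cohort generator for closed-loop
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
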