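## Physiological load case for single-leg stance: joint contact force at the
## femoral head centre (2.38 x body weight, tilted by the patient's Pauwels
## angle), abductor reaction at the greater trochanter, full fixation of the
## distal cut. Forces in N, g = 9.81 m/s^2.

GRAVITY <- 9.81

#' Hip joint contact force
#'
#' Magnitude `factor * body_weight * g` (peak force during normal walking;
#' default factor 2.38), directed distally and tilted `pauwels_angle`
#' degrees from the vertical towards medial — compressive on the head.
#'
#' @param body_weight kg, > 0.
#' @param pauwels_angle degrees in [0, 45].
#' @param factor dimensionless joint-force factor, > 0 (default 2.38).
#' @param location point of application (the femoral head centre).
#' @return `point_load`: list with `location`, `force` (N, length-2).
#' @export
joint_force <- function(body_weight, pauwels_angle, factor = 2.38,
                        location = c(0, 0)) {
  if (body_weight <= 0) stemshield_stop("body weight must be > 0", "domain_error")
  if (pauwels_angle < 0 || pauwels_angle > 45)
    stemshield_stop("Pauwels angle outside [0, 45] degrees", "domain_error")
  if (factor <= 0) stemshield_stop("joint force factor must be > 0", "domain_error")
  mag <- factor * body_weight * GRAVITY
  th <- pauwels_angle * pi / 180
  structure(list(location = location, force = mag * c(-sin(th), -cos(th))),
            class = "point_load")
}

#' Abductor muscle reaction at the greater trochanter
#'
#' Two conventions:
#' \describe{
#'   \item{`"equilibrium"` (default)}{the abductor closes the frontal-plane
#'     force balance of joint load plus the stance-phase partial body weight
#'     `W_partial = (5/6) BW g` acting in -y:
#'     `F_A = -(F_joint + W_partial)`.}
#'   \item{`"fixed"`}{classic fixed-ratio pull: magnitude `c_A * BW * g` at
#'     `alpha_A` degrees from +y (defaults 1.6 and 21).}
#' }
#'
#' @param body_weight kg.
#' @param joint_load `point_load` from [joint_force()].
#' @param mode `"equilibrium"` or `"fixed"`.
#' @param c_A,alpha_A fixed-mode magnitude ratio and angle from +y (degrees).
#' @param location point of application (the trochanter apex).
#' @return `point_load`.
#' @export
abductor_force <- function(body_weight, joint_load, mode = "equilibrium",
                           c_A = 1.6, alpha_A = 21, location = c(0, 0)) {
  if (mode == "equilibrium") {
    w_partial <- c(0, -(5 / 6) * body_weight * GRAVITY)
    f <- -(joint_load$force + w_partial)
  } else if (mode == "fixed") {
    a <- alpha_A * pi / 180
    f <- c_A * body_weight * GRAVITY * c(-sin(a), cos(a))
  } else {
    stemshield_stop(paste("unknown abductor mode:", mode), "invalid_parameter")
  }
  structure(list(location = location, force = f), class = "point_load")
}

#' Assemble the load case for a patient and femur
#'
#' Joint contact force at the head-centre landmark, abductor reaction at the
#' trochanter apex, and full displacement fixation of the distal cut edge.
#'
#' @param patient `patient_record` (uses `body_weight`, `pauwels_angle`).
#' @param femur `femur_geometry` (supplies the load locations).
#' @param joint_force_factor dimensionless, default 2.38.
#' @param abductor_mode passed to [abductor_force()].
#' @param joint_attach `"implant_top"` (default): the joint load is carried
#'   by the implant neck onto the stem-shoulder node set with a
#'   force-and-moment-equivalent distribution; `"nearest"`: plain
#'   barycentric attachment at the head-centre location (only sensible when
#'   the head centre lies inside the meshed domain).
#' @param thickness plane-stress slab thickness, mm (default 35). The main
#'   absolute-calibration knob of the model: stresses scale with
#'   1/thickness and SED with 1/thickness^2. The default matches the 2D
#'   diaphyseal cortical section (two 6 mm walls x thickness) to a
#'   literature-typical 3D cortical cross-section of about 400 mm^2, so 2D
#'   stresses sit at the physiological scale.
#' @return `load_case`: `loads` (list of `point_load`), `fixed_boundary`
#'   (function selecting fixed nodes), `body_weight`, `pauwels_angle`,
#'   `joint_force_factor`, `thickness`.
#' @export
build_load_case <- function(patient, femur, joint_force_factor = 2.38,
                            abductor_mode = "equilibrium", thickness = 35,
                            joint_attach = "implant_top") {
  jl <- joint_force(patient$body_weight, patient$pauwels_angle,
                    factor = joint_force_factor,
                    location = femur$head_center)
  ## the head centre lies above the resection; the implant neck carries the
  ## joint load rigidly onto the stem shoulder (force + moment preserved)
  jl$attach <- joint_attach
  ab <- abductor_force(patient$body_weight, jl, mode = abductor_mode,
                       location = femur$trochanter_apex)
  fixed_sel <- function(nodes) which(nodes[, 2] < 1e-6)
  structure(list(loads = list(joint = jl, abductor = ab),
                 fixed_boundary = fixed_sel,
                 body_weight = patient$body_weight,
                 pauwels_angle = patient$pauwels_angle,
                 joint_force_factor = joint_force_factor,
                 gravity = GRAVITY, thickness = thickness),
            class = "load_case")
}
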