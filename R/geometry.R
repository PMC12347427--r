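## Parametric frontal-plane geometry of a resected proximal femur and three
## short-stem archetypes, stem placement in varus/neutral/valgus alignment,
## and the modified Gruen-zone partition of the peri-implant bone.
##
## Frame convention: right femur, +x lateral, +y proximal, lengths in mm.
## The femoral head is resected; the head centre is kept as a landmark above
## the resection plane (it carries the joint load, which is transferred onto
## the implant shoulder by the load-application code).

stemshield_stop <- function(msg, class) {
  stop(structure(list(message = msg, call = NULL),
                 class = c(class, "stemshield_error", "error", "condition")))
}

## Chord-length cubic-spline smoothing of an open polyline through control
## points; scale-equivariant (scaling the control points scales the curve).
smooth_polyline <- function(ctrl, n_out) {
  d <- sqrt(rowSums(diff(ctrl)^2))
  t <- c(0, cumsum(d))
  tq <- seq(0, t[length(t)], length.out = n_out)
  cbind(stats::spline(t, ctrl[, 1], xout = tq, method = "natural")$y,
        stats::spline(t, ctrl[, 2], xout = tq, method = "natural")$y)
}

#' Default femur geometry parameters
#'
#' All entries except `ccd_angle` are lengths in mm; scaling every length by
#' a common factor produces a geometrically similar femur. Signed x-type
#' entries locate landmarks in the frame (+x lateral, +y proximal).
#'
#' @return named list of parameters.
#' @export
femur_params <- function() {
  list(
    shaft_length   = 90,   # straight diaphyseal segment above the distal cut
    shaft_width    = 28,   # outer (periosteal) shaft width
    cortical_shaft = 6,    # diaphyseal cortical wall thickness
    cortical_prox  = 3,    # metaphyseal cortical thickness
    flare_med      = 9,    # medial (calcar) metaphyseal flare
    flare_lat      = 6,    # lateral metaphyseal flare
    res_x          = -6,   # neck resection centre, x
    res_y          = 150,  # neck resection centre, y
    res_halfwidth  = 15,   # half-length of the resection cut
    neck_length    = 35,   # resection centre -> head centre distance
    troch_x        = 17,   # greater trochanter apex, x
    troch_y        = 165,  # greater trochanter apex, y
    endo_floor     = 4,    # distal closure height of the medullary cavity
    ccd_angle      = 130   # caput-collum-diaphysis angle, degrees
  )
}

neck_dirs <- function(ccd_angle) {
  a <- (180 - ccd_angle) * pi / 180
  u <- c(-sin(a), cos(a))          # along neck, towards the head (medial-prox)
  w <- c(cos(a), sin(a))           # along the resection cut (lateral-prox)
  list(u = u, w = w)
}

#' Build a parametric frontal-plane femur geometry
#'
#' Constructs periosteal and endosteal contours (cortical shell around a
#' cancellous interior) for a resected right proximal femur, plus the
#' anatomical landmarks that the loading model needs.
#'
#' @param params parameter list as from [femur_params()]; entries can be
#'   overridden.
#' @return object of class `femur_geometry` with elements `periosteal`,
#'   `endosteal` (CCW polygon matrices), `head_center`, `trochanter_apex`,
#'   `resection_point`, `neck_axis`, `shaft_axis`, `neck_axis_angle`,
#'   `params`.
#' @export
build_femur_contour <- function(params = femur_params()) {
  p <- utils::modifyList(femur_params(), params)
  lens <- p[setdiff(names(p), "ccd_angle")]
  if (any(!vapply(lens, is.finite, TRUE)))
    stemshield_stop("non-finite femur parameter", "invalid_parameter")
  if (p$shaft_length <= 0 || p$shaft_width <= 0 || p$cortical_shaft <= 0 ||
      p$cortical_prox <= 0 || p$res_halfwidth <= 0 || p$neck_length <= 0)
    stemshield_stop("femur lengths must be positive", "invalid_parameter")
  if (p$ccd_angle < 110 || p$ccd_angle > 150)
    stemshield_stop("CCD angle outside [110, 150] degrees", "invalid_parameter")
  if (2 * p$cortical_shaft >= p$shaft_width)
    stemshield_stop("cortical wall swallows the medullary canal",
                    "invalid_parameter")

  nd <- neck_dirs(p$ccd_angle)
  rc <- c(p$res_x, p$res_y)
  hw <- p$shaft_width / 2
  res_med <- rc - p$res_halfwidth * nd$w   # medial (calcar) cut corner
  res_lat <- rc + p$res_halfwidth * nd$w   # lateral cut corner

  ## periosteal outline: distal cut -> medial shaft -> calcar flare ->
  ## resection cut -> trochanter -> lateral shaft -> distal cut
  med_ctrl <- rbind(
    c(-hw, 0),
    c(-hw, p$shaft_length),
    c(-hw - 0.45 * p$flare_med, p$shaft_length + 0.30 * (p$res_y - p$shaft_length)),
    c(-hw - p$flare_med, p$shaft_length + 0.72 * (p$res_y - p$shaft_length)),
    res_med)
  lat_ctrl <- rbind(
    res_lat,
    c(p$troch_x, p$troch_y),
    c(hw + p$flare_lat, p$shaft_length + 0.55 * (p$res_y - p$shaft_length)),
    c(hw, p$shaft_length),
    c(hw, 0))
  peri <- rbind(smooth_polyline(med_ctrl, 40),
                res_lat,
                smooth_polyline(lat_ctrl, 40)[-1, ],
                c(0.25 * hw, 0))  # midpoint of distal cut keeps ring open
  peri <- orient_ccw(unique(round(peri, 9)))

  ## endosteal outline: inset by the cortical thicknesses
  cs <- p$cortical_shaft; cp <- p$cortical_prox
  e_res_med <- rc - (p$res_halfwidth - cp) * nd$w - cp * nd$u
  e_res_lat <- rc + (p$res_halfwidth - cp) * nd$w - cp * nd$u
  ehw <- hw - cs
  emed_ctrl <- rbind(
    c(-ehw, p$endo_floor),
    c(-ehw, p$shaft_length),
    c(-ehw - 0.45 * (p$flare_med - cp + cs),
      p$shaft_length + 0.30 * (p$res_y - p$shaft_length)),
    c(-hw - p$flare_med + cp, p$shaft_length + 0.72 * (p$res_y - p$shaft_length)),
    e_res_med)
  elat_ctrl <- rbind(
    e_res_lat,
    c(p$troch_x - cp, p$troch_y - 1.6 * cp),
    c(hw + p$flare_lat - cp, p$shaft_length + 0.55 * (p$res_y - p$shaft_length)),
    c(ehw, p$shaft_length),
    c(ehw, p$endo_floor))
  endo <- rbind(smooth_polyline(emed_ctrl, 36),
                e_res_lat,
                smooth_polyline(elat_ctrl, 36)[-1, ],
                c(0.25 * ehw, p$endo_floor))
  endo <- orient_ccw(unique(round(endo, 9)))

  validate_contour(peri, "periosteal contour")
  validate_contour(endo, "endosteal contour")
  if (!polygon_inside(endo, peri))
    stemshield_stop("endosteal contour not inside periosteal contour",
                    "invalid_parameter")

  head_center <- rc + p$neck_length * nd$u
  troch <- c(p$troch_x, p$troch_y)
  if (head_center[2] <= troch[2])
    stemshield_stop("head centre must lie above the trochanter apex",
                    "invalid_parameter")

  structure(list(periosteal = peri, endosteal = endo,
                 head_center = head_center, trochanter_apex = troch,
                 neck_axis_angle = p$ccd_angle, neck_axis = nd$u,
                 resection_cut_dir = nd$w,
                 shaft_axis = c(0, 1), resection_point = rc, params = p),
            class = "femur_geometry")
}

#' Default stem geometry parameters per archetype
#'
#' Three short-stem archetypes: `PROXIMA` (shortest, pronounced lateral
#' shoulder flare), `COLLO_MIS` (curved neck-sparing body), `MINIMA`
#' (longest, triple-taper). All lengths in mm, in the canonical stem frame
#' (shoulder centre at the origin, body descending).
#'
#' @param stem_type one of `"PROXIMA"`, `"COLLO_MIS"`, `"MINIMA"`.
#' @return named list of shape parameters.
#' @export
stem_params <- function(stem_type) {
  switch(stem_type,
    PROXIMA = list(length = 62, tip_x = -7, bow = 0,
                   hw_top_med = 8, hw_top_lat = 9.5, hw_tip = 3,
                   flare = 4.0, taper = 1, nominal_ccd = 130),
    COLLO_MIS = list(length = 82, tip_x = -7.5, bow = 3.5,
                     hw_top_med = 7, hw_top_lat = 7.5, hw_tip = 2.5,
                     flare = 0, taper = 1, nominal_ccd = 130),
    MINIMA = list(length = 100, tip_x = -8, bow = 0,
                  hw_top_med = 7.5, hw_top_lat = 8, hw_tip = 2,
                  flare = 0, taper = 1, nominal_ccd = 130),
    stemshield_stop(paste("unknown stem type:", stem_type), "invalid_parameter"))
}

#' Build a short-stem implant contour
#'
#' The stem is generated around a quadratic-Bezier centreline running from
#' the shoulder centre (origin) to the tip, offset medially/laterally by
#' linearly tapering half-width profiles; `PROXIMA` adds a Gaussian lateral
#' flare at the shoulder, `COLLO_MIS` a lateral bow (neck-sparing curve).
#'
#' @param stem_type archetype name, see [stem_params()].
#' @param params overrides merged into the archetype defaults.
#' @return object of class `stem_geometry` with `contour` (CCW polygon),
#'   `stem_axis` (unit, tip -> shoulder), `tip`, `shoulder_center`,
#'   `length`, `stem_type`, `params`.
#' @export
build_stem_contour <- function(stem_type, params = list()) {
  p <- utils::modifyList(stem_params(stem_type), params)
  if (p$length <= 0 || p$hw_tip <= 0 || p$hw_top_med <= 0 || p$hw_top_lat <= 0)
    stemshield_stop("stem lengths must be positive", "invalid_parameter")
  if (p$taper <= 0)
    stemshield_stop("taper parameter must be positive", "invalid_parameter")

  nd <- neck_dirs(p$nominal_ccd)
  tip <- c(p$tip_x, -p$length)
  ## Bezier control: blend of neck-axis departure and vertical arrival,
  ## bowed laterally for curved designs.
  ctrl <- c(p$tip_x / 2, -0.35 * p$length) + c(p$bow, 0)
  d <- seq(0, 1, length.out = 28)
  bez <- function(t) {
    cbind((1 - t)^2 * 0 + 2 * (1 - t) * t * ctrl[1] + t^2 * tip[1],
          (1 - t)^2 * 0 + 2 * (1 - t) * t * ctrl[2] + t^2 * tip[2])
  }
  cl <- bez(d)
  ## unit tangents and left normals of the centreline
  tg <- rbind(cl[2, ] - cl[1, ], (cl[-1, ] - cl[-nrow(cl), ]))
  tg <- tg / sqrt(rowSums(tg^2))
  nl <- cbind(-tg[, 2], tg[, 1])   # lateral side (tangent points distal)
  dt <- d^p$taper
  hw_lat <- p$hw_top_lat * (1 - dt) + p$hw_tip * dt + p$flare * exp(-(d / 0.22)^2)
  hw_med <- p$hw_top_med * (1 - dt) + p$hw_tip * dt
  lat_side <- cl + nl * hw_lat
  med_side <- cl - nl * hw_med
  ## shoulder top edge follows the resection-cut direction
  top_med <- -p$hw_top_med * nd$w
  top_lat <- p$hw_top_lat * nd$w
  contour <- rbind(top_lat + c(0, 0),
                   lat_side[-1, ],
                   tip + c(0, -0.6 * p$hw_tip),   # rounded-ish tip apex
                   med_side[rev(seq_len(nrow(med_side))[-1]), ],
                   top_med)
  contour <- orient_ccw(unique(round(contour, 9)))
  validate_contour(contour, paste(stem_type, "stem contour"))

  shoulder <- c(0, 0)
  axis <- (shoulder - tip) / sqrt(sum((shoulder - tip)^2))
  structure(list(stem_type = stem_type, contour = contour,
                 stem_axis = axis, tip = tip, shoulder_center = shoulder,
                 length = p$length, params = p),
            class = "stem_geometry")
}

#' Seat a stem in a femur at a given alignment
#'
#' The stem contour is rotated by `alignment_angle` about the femur's neck
#' resection centre (positive = varus: the tip swings laterally), then
#' translated stepwise into the bone along the femoral neck axis until every
#' stem vertex clears the periosteal contour by `margin` and the tip lies in
#' the endosteal (cancellous) region. The stem may locally penetrate the
#' endosteal boundary into the cortical wall (cortical contact), which is
#' exactly the malposition mechanism of interest.
#'
#' @param femur `femur_geometry`.
#' @param stem `stem_geometry`.
#' @param alignment_angle degrees, |angle| <= 10; 0 = neutral.
#' @param margin minimal clearance from the periosteal contour, mm.
#' @param step seating-depth increment, mm.
#' @return object of class `placed_stem`: `stem` (with transformed contour,
#'   tip, axis), `alignment` (`"VARUS"`, `"NEUTRAL"`, `"VALGUS"`),
#'   `alignment_angle`, `pivot`, `seating_depth`.
#' @export
place_stem <- function(femur, stem, alignment_angle = 0,
                       margin = 0.8, step = 0.5) {
  if (abs(alignment_angle) > 10)
    stemshield_stop("alignment angle beyond +/-10 degrees", "invalid_parameter")
  pivot <- femur$resection_point
  ctr0 <- translate_points(stem$contour, pivot)
  ctr0 <- rotate_points(ctr0, alignment_angle, center = pivot)
  tip0 <- rotate_points(matrix(pivot + stem$tip, ncol = 2),
                        alignment_angle, center = pivot)[1, ]
  sh0 <- rotate_points(matrix(pivot + stem$shoulder_center, ncol = 2),
                       alignment_angle, center = pivot)[1, ]
  axis0 <- rotate_vec(stem$stem_axis, alignment_angle)
  insert_dir <- -femur$neck_axis   # into the bone
  peri_segs <- polygon_segments(femur$periosteal)

  feasible <- function(ctr0, tip0, s) {
    ctr <- translate_points(ctr0, s * insert_dir)
    tip <- tip0 + s * insert_dir
    all(points_in_polygon(ctr, femur$periosteal)) &&
      min(.cpp_min_dist_to_segments(ctr, peri_segs)) >= margin &&
      !.cpp_segments_intersect(polygon_segments(ctr), peri_segs, 1e-12) &&
      points_in_polygon(tip, femur$endosteal)
  }
  min_depth <- function(ctr0, tip0, from = 0) {
    for (s in seq(from, 2.2 * femur$params$neck_length, by = step))
      if (feasible(ctr0, tip0, s)) return(s)
    NA_real_
  }
  ## surgical seating depth is set by the neutral (planned) position; a
  ## malaligned stem is seated at least that deep, so tilting is not
  ## cancelled by the stem riding up the cavity
  nominal <- min_depth(translate_points(stem$contour, pivot),
                       pivot + stem$tip)
  if (is.na(nominal))
    stemshield_stop("no seating depth keeps the stem inside the bone",
                    "placement_failure")
  seated <- min_depth(ctr0, tip0, from = nominal)
  if (is.na(seated))
    stemshield_stop("no seating depth keeps the stem inside the bone",
                    "placement_failure")

  shift <- seated * insert_dir
  placed_stem <- stem
  placed_stem$contour <- translate_points(ctr0, shift)
  placed_stem$tip <- tip0 + shift
  placed_stem$shoulder_center <- sh0 + shift
  placed_stem$stem_axis <- axis0
  alignment <- if (alignment_angle == 0) "NEUTRAL"
               else if (alignment_angle > 0) "VARUS" else "VALGUS"
  structure(list(stem = placed_stem, alignment = alignment,
                 alignment_angle = alignment_angle, pivot = pivot,
                 seating_depth = seated),
            class = "placed_stem")
}

#' Partition the peri-implant bone into seven modified Gruen zones
#'
#' Zones are defined in the placed stem's own frame: the stem axis line
#' splits lateral (zones 1-3, proximal to distal thirds of the stem length)
#' from medial (zones 7-6-5), and zone 4 is the band of bone within one
#' local stem width distal to the tip. The zone map is a deterministic point
#' classifier, so disjointness and coverage hold by construction.
#'
#' @param femur `femur_geometry`.
#' @param placed `placed_stem`.
#' @return object of class `zone_map` with fields `origin`, `axis_distal`,
#'   `lateral`, `stem_length`, `tip_band` and the classifier
#'   [zone_of_points()] applies.
#' @export
partition_gruen_zones <- function(femur, placed) {
  st <- placed$stem
  a <- (st$tip - st$shoulder_center)
  L <- sqrt(sum(a^2)); a <- a / L
  n <- c(-a[2], a[1])
  if (n[1] < 0) n <- -n            # ensure n points laterally
  ## local stem width near the tip: contour extent across the axis in the
  ## distal fifth of the stem
  rel <- sweep(st$contour, 2, st$shoulder_center)
  s <- rel %*% a; t <- rel %*% n
  near_tip <- s > 0.8 * L
  tip_band <- if (any(near_tip)) max(t[near_tip]) - min(t[near_tip]) else 2 * L / 10
  structure(list(origin = st$shoulder_center, axis_distal = a, lateral = n,
                 stem_length = L, tip_band = tip_band),
            class = "zone_map")
}

#' Classify points into Gruen zones
#'
#' @param pts n x 2 matrix of points (mm).
#' @param zm `zone_map` from [partition_gruen_zones()].
#' @return integer vector: 1..7 zone id, 0 for bone outside the zoned band.
#' @export
zone_of_points <- function(pts, zm) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  rel <- sweep(pts, 2, zm$origin)
  s <- as.numeric(rel %*% zm$axis_distal)
  t <- as.numeric(rel %*% zm$lateral)
  L <- zm$stem_length
  zone <- integer(nrow(pts))
  third <- pmin(3L, 1L + as.integer(3 * pmax(s, 0) / L))
  ## bone slightly proximal to the shoulder centre (calcar cut, trochanter
  ## base) belongs to the proximal zones; beyond 0.15 L it is non-zoned
  beside <- s >= -0.15 * L & s <= L
  zone[beside & t > 0] <- third[beside & t > 0]            # 1,2,3 lateral
  zone[beside & t <= 0] <- 8L - third[beside & t <= 0]     # 7,6,5 medial
  zone[s > L & s <= L + zm$tip_band] <- 4L
  zone
}

#' Schematic zone polygons for export/debugging
#'
#' Rectangles in the stem frame clipped to a transverse half-width; the
#' authoritative zone assignment is [zone_of_points()].
#'
#' @param zm `zone_map`.
#' @param half_width transverse extent of the schematic rectangles, mm.
#' @return named list of 7 polygon matrices.
#' @export
zone_polygons <- function(zm, half_width = 40) {
  L <- zm$stem_length; a <- zm$axis_distal; n <- zm$lateral; o <- zm$origin
  rect <- function(s0, s1, t0, t1) {
    corners <- rbind(c(s0, t0), c(s1, t0), c(s1, t1), c(s0, t1))
    orient_ccw(t(apply(corners, 1, function(q) o + q[1] * a + q[2] * n)))
  }
  out <- list(
    `1` = rect(0, L / 3, 0, half_width),
    `2` = rect(L / 3, 2 * L / 3, 0, half_width),
    `3` = rect(2 * L / 3, L, 0, half_width),
    `4` = rect(L, L + zm$tip_band, -half_width, half_width),
    `5` = rect(2 * L / 3, L, -half_width, 0),
    `6` = rect(L / 3, 2 * L / 3, -half_width, 0),
    `7` = rect(0, L / 3, -half_width, 0))
  out
}
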