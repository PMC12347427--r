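## Frost-mechanostat remodeling prediction. Strain energy density at the
## bone-implant interface is converted to a mass-specific mechanical
## stimulus (J/kg); each Gruen zone is classified by its area-weighted
## median stimulus against a lower (resorption) and upper (apposition)
## setpoint, with the "lazy zone" in between. The upper setpoint can be
## calibrated by exhaustive grid search against observed zone labels; the
## lower setpoint is the first quartile of stimuli in zones with observed
## resorption.

#' Mechanostat threshold pair
#'
#' Defaults are the lazy-zone setpoints used throughout: resorption below
#' 2 J/kg, apposition above 12 J/kg.
#'
#' @param t_low,t_high lower and upper stimulus thresholds, J/kg.
#' @return `threshold_pair` list.
#' @export
threshold_pair <- function(t_low = 2, t_high = 12) {
  if (t_low < 0 || t_low >= t_high)
    stemshield_stop("need 0 <= t_low < t_high", "invalid_parameter")
  structure(list(t_low = t_low, t_high = t_high), class = "threshold_pair")
}

#' Mass-specific mechanical stimulus from strain energy density
#'
#' `stimulus = SED[MPa] * 1e6 / density[kg/m^3]` in J/kg — the explicit unit
#' conversion is MPa = 10^6 J/m^3, divided by an apparent bone density.
#'
#' @param sed SED in MPa, >= 0 (vectorized).
#' @param density apparent density in kg/m^3, > 0.
#' @return stimulus in J/kg.
#' @export
mechanical_stimulus <- function(sed, density) {
  if (any(density <= 0)) stemshield_stop("density must be > 0", "domain_error")
  if (any(sed < 0)) stemshield_stop("SED must be >= 0", "domain_error")
  sed * 1e6 / density
}

#' Classify a stimulus with the mechanostat
#'
#' Strictly above the upper threshold: `APPOSITION`; strictly below the
#' lower: `RESORPTION`; thresholds themselves belong to the lazy zone
#' (`NO_ACTIVITY`).
#'
#' @param S stimulus in J/kg (vectorized), >= 0.
#' @param t `threshold_pair`.
#' @return character vector of remodeling classes.
#' @export
classify_stimulus <- function(S, t = threshold_pair()) {
  out <- rep("NO_ACTIVITY", length(S))
  out[S > t$t_high] <- "APPOSITION"
  out[S < t$t_low] <- "RESORPTION"
  names(out) <- names(S)
  out
}

#' Area-weighted median
#'
#' Smallest value whose cumulative weight strictly exceeds half the total
#' (upper weighted median) — robust to mesh-density variation when weights
#' are element areas. With equal weights and an odd count this is the
#' ordinary sample median.
#'
#' @param x values.
#' @param w non-negative weights.
#' @return scalar weighted median.
#' @export
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw > sum(w) / 2)[1]]
}

#' Per-zone median stimulus over the interface band
#'
#' @param stimulus per-element stimulus (J/kg) for the band elements.
#' @param areas element areas (mm^2), same length.
#' @param zones integer zone ids (1..7; 0 = non-zoned, ignored).
#' @param weighted use the area-weighted median (default) or the plain
#'   element median.
#' @return named numeric vector of 7 medians (`"1"`..`"7"`).
#' @export
zone_median_stimulus <- function(stimulus, areas, zones, weighted = TRUE) {
  med <- stats::setNames(rep(NA_real_, 7), as.character(1:7))
  for (z in 1:7) {
    sel <- zones == z
    if (!any(sel))
      stemshield_stop(sprintf("zone %d contains no interface-band elements", z),
                      "empty_zone")
    med[as.character(z)] <- if (weighted)
      weighted_median(stimulus[sel], areas[sel])
    else stats::median(stimulus[sel])
  }
  med
}

#' Predict per-zone remodeling classes
#'
#' @param medians named vector of 7 zone median stimuli (J/kg).
#' @param t `threshold_pair`.
#' @return data frame with `zone_id`, `median_stimulus`, `predicted`.
#' @export
predict_zone_remodeling <- function(medians, t = threshold_pair()) {
  data.frame(zone_id = as.integer(names(medians)),
             median_stimulus = as.numeric(medians),
             predicted = unname(classify_stimulus(as.numeric(medians), t)),
             stringsAsFactors = FALSE)
}

#' Lower threshold from resorption-zone stimuli
#'
#' First quartile of the stimuli observed in zones radiographically labelled
#' as resorption, by sorted-order linear interpolation at position
#' `1 + 0.25 (n - 1)` (quantile type 7).
#'
#' @param resorption_zone_stimuli numeric vector, length >= 4.
#' @return Q1 in J/kg.
#' @export
lower_threshold_from_iqr <- function(resorption_zone_stimuli) {
  n <- length(resorption_zone_stimuli)
  if (n < 4)
    stemshield_stop("need >= 4 resorption-zone stimuli for the IQR bound",
                    "insufficient_data")
  s <- sort(resorption_zone_stimuli)
  pos <- 1 + 0.25 * (n - 1)
  lo <- floor(pos); frac <- pos - lo
  s[lo] * (1 - frac) + s[min(lo + 1, n)] * frac
}

#' Classification accuracy
#'
#' @param predicted,observed equal-length class vectors.
#' @return fraction of agreeing entries.
#' @export
classification_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stemshield_stop("predicted and observed lengths differ", "invalid_parameter")
  mean(predicted == observed)
}

#' Brute-force calibration of the upper mechanostat threshold
#'
#' Evaluates every candidate on a regular grid: for each `t`, zones are
#' classified with `(T_low, t)` and scored against the observed labels.
#' The calibrated threshold is the midpoint of the contiguous plateau of
#' accuracy-maximizing grid values containing the first maximizer
#' (documented tie-break).
#'
#' @param zone_medians numeric vector of zone median stimuli (J/kg).
#' @param observed character vector of observed labels, same length.
#' @param t_low lower threshold (J/kg), fixed during the search.
#' @param grid `c(lo, hi, step)` in J/kg; default `c(3, 25, 0.25)`.
#' @param objective `"three_class"` (default) scores all three classes;
#'   `"apposition"` scores apposition-vs-rest only.
#' @return `calibration_result`: `t_high_star`, `accuracy`, `plateau`
#'   (`c(lo, hi)`), `grid_step`, `grid`, `accuracy_curve`.
#' @export
calibrate_upper_threshold <- function(zone_medians, observed, t_low = 2,
                                      grid = c(3, 25, 0.25),
                                      objective = "three_class") {
  if (length(zone_medians) != length(observed))
    stemshield_stop("medians and labels differ in length", "invalid_parameter")
  if (grid[1] <= t_low)
    stemshield_stop("grid must start above t_low", "invalid_parameter")
  if (grid[3] <= 0) stemshield_stop("grid step must be > 0", "invalid_parameter")
  cand <- seq(grid[1], grid[2], by = grid[3])
  if (!length(cand)) stemshield_stop("empty grid", "invalid_parameter")
  acc <- vapply(cand, function(t) {
    pred <- classify_stimulus(zone_medians, threshold_pair(t_low, t))
    if (objective == "apposition")
      mean((pred == "APPOSITION") == (observed == "APPOSITION"))
    else mean(pred == observed)
  }, numeric(1))
  best <- max(acc)
  is_best <- abs(acc - best) < 1e-12
  ## contiguous plateau containing the first maximizer
  first <- which(is_best)[1]
  lo <- first; hi <- first
  while (lo > 1 && is_best[lo - 1]) lo <- lo - 1
  while (hi < length(cand) && is_best[hi + 1]) hi <- hi + 1
  plateau <- c(cand[lo], cand[hi])
  structure(list(t_high_star = mean(plateau), accuracy = best,
                 plateau = plateau, grid_step = grid[3], grid = grid,
                 accuracy_curve = data.frame(t = cand, accuracy = acc)),
            class = "calibration_result")
}

#' Cortical overload diagnostic
#'
#' Fraction of cortical-tagged interface-band area whose stimulus exceeds
#' the upper threshold, plus the maximum cortical stimulus — the quantity
#' that flags stem-malposition overload.
#'
#' @param stimulus per-element stimulus for the band elements (J/kg).
#' @param areas element areas (mm^2).
#' @param tags element region tags.
#' @param t_high upper threshold (J/kg).
#' @return list with `overload_fraction` and `max_cortical_stimulus`.
#' @export
cortical_overload <- function(stimulus, areas, tags, t_high = 12) {
  cort <- tags == "CORTICAL"
  if (!any(cort))
    return(list(overload_fraction = 0, max_cortical_stimulus = 0))
  over <- cort & stimulus > t_high
  list(overload_fraction = sum(areas[over]) / sum(areas[cort]),
       max_cortical_stimulus = max(stimulus[cort]))
}

#' Element stimulus field from an SED field
#'
#' In `"literal"` mode (default) every bone element uses the cancellous
#' apparent density, mirroring the convention of dividing interface SED by
#' cancellous bone density; `"regional"` mode uses each element's own
#' region density.
#'
#' @param sed_field `sed_field` from [strain_energy_density()].
#' @param materials material table.
#' @param density_mode `"literal"` or `"regional"`.
#' @return numeric vector of per-element stimuli (J/kg; implant elements NA).
#' @export
stimulus_field <- function(sed_field, materials = default_materials(),
                           density_mode = "literal") {
  rho <- switch(density_mode,
    literal = rep(materials$CANCELLOUS$density, nrow(sed_field)),
    regional = unname(vapply(materials, `[[`, 0, "density")[sed_field$region_tag]),
    stemshield_stop("density_mode must be 'literal' or 'regional'",
                    "invalid_parameter"))
  out <- mechanical_stimulus(pmax(sed_field$sed, 0), rho)
  out[sed_field$region_tag == "IMPLANT"] <- NA_real_
  out
}
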