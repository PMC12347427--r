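## Synthetic cohort generator. Emulates the statistical structure of the
## study population (15 patients, 5 per stem design, median body weight
## 70 kg) plus per-zone "observed" remodeling labels produced by a
## ground-truth mechanostat with optional reading noise, enabling
## closed-loop (parameter-recovery) testing without patient data.

remodeling_classes <- c("RESORPTION", "NO_ACTIVITY", "APPOSITION")

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate one synthetic patient record
#'
#' Body weight ~ Normal(70, 12) kg truncated to [45, 110] (cohort median
#' 70 kg); Pauwels angle of the joint load ~ Normal(16, 3) degrees clipped
#' to [5, 30]; femur geometry parameters jittered uniformly +/-10% around
#' the defaults. Fully reproducible from the seed.
#'
#' @param seed non-negative integer seed.
#' @param stem_type one of `"PROXIMA"`, `"COLLO_MIS"`, `"MINIMA"`.
#' @param alignment_angle stem alignment in degrees (default 0, neutral).
#' @return list of class `patient_record`.
#' @export
generate_patient <- function(seed, stem_type = "MINIMA", alignment_angle = 0) {
  if (seed < 0) stemshield_stop("seed must be >= 0", "invalid_parameter")
  stem_params(stem_type) # validates the type
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  bw <- rtruncnorm1(1, 70, 12, 45, 110)
  height <- rtruncnorm1(1, 168, 9, 145, 195)
  pauwels <- min(30, max(5, stats::rnorm(1, 16, 3)))
  gp <- femur_params()
  ## anatomical variability: a global similarity scale plus independent
  ## shape jitter on parameters that cannot break the landmark invariants
  ## (head centre above trochanter, contours nested)
  scale <- stats::runif(1, 0.92, 1.08)
  for (k in setdiff(names(gp), "ccd_angle")) gp[[k]] <- gp[[k]] * scale
  shape <- c("shaft_width", "cortical_shaft", "cortical_prox", "flare_med",
             "flare_lat", "res_halfwidth", "neck_length", "res_x",
             "troch_x", "endo_floor")
  for (k in shape) gp[[k]] <- gp[[k]] * stats::runif(1, 0.92, 1.08)
  gp$ccd_angle <- min(139, max(121, stats::rnorm(1, 130, 3)))
  structure(list(patient_id = sprintf("P%06d", seed),
                 body_weight = bw, height = height,
                 pauwels_angle = pauwels, stem_type = stem_type,
                 alignment_angle = alignment_angle,
                 geometry_params = gp, rng_seed = seed),
            class = "patient_record")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort
#'
#' Defaults reproduce the study layout: 15 patients, balanced across the
#' three stem designs (5 per group).
#'
#' @param n number of patients.
#' @param seed integer master seed; per-patient seeds are derived from it.
#' @param stem_mix character vector of stem types cycled over the cohort.
#' @return list of `patient_record`s.
#' @export
generate_cohort <- function(n = 15, seed = 1,
                            stem_mix = c("PROXIMA", "COLLO_MIS", "MINIMA")) {
  if (n < 1) stemshield_stop("cohort size must be >= 1", "invalid_parameter")
  types <- rep_len(stem_mix, n)
  lapply(seq_len(n), function(i) {
    generate_patient(seed = (seed * 1000L + i) %% 2147483647L,
                     stem_type = types[i])
  })
}

#' Generate synthetic "observed" per-zone remodeling labels
#'
#' Each zone is labelled by the forward mechanostat applied to its stimulus;
#' with probability `noise_rate` the label is replaced by one of the other
#' two classes, uniformly — a minimal model of radiographic reading error.
#'
#' @param zone_stimuli numeric vector of per-zone stimuli (J/kg); names (or
#'   positions) are the zone ids.
#' @param true_thresholds [threshold_pair()]; ground-truth mechanostat.
#' @param noise_rate label-flip probability in [0, 0.5).
#' @param seed integer seed.
#' @return character vector of labels in `remodeling_classes`, one per zone.
#' @export
generate_observed_labels <- function(zone_stimuli,
                                     true_thresholds = threshold_pair(2, 12),
                                     noise_rate = 0, seed = 1) {
  if (noise_rate < 0 || noise_rate >= 0.5)
    stemshield_stop("noise_rate must be in [0, 0.5)", "invalid_parameter")
  labels <- classify_stimulus(zone_stimuli, true_thresholds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  flip <- stats::runif(length(labels)) < noise_rate
  if (any(flip)) {
    labels[flip] <- vapply(labels[flip], function(cl) {
      sample(setdiff(remodeling_classes, cl), 1)
    }, character(1))
  }
  stats::setNames(labels, names(zone_stimuli))
}

#' Write / read a cohort as CSV
#'
#' One row per patient with demographics and the geometry parameters
#' flattened into `geom_*` columns.
#'
#' @param cohort list of `patient_record`s.
#' @param path CSV file path.
#' @return `path`, invisibly (writer); list of records (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    gp <- p$geometry_params
    names(gp) <- paste0("geom_", names(gp))
    c(list(patient_id = p$patient_id, body_weight = p$body_weight,
           height = p$height, pauwels_angle = p$pauwels_angle,
           stem_type = p$stem_type, alignment_angle = p$alignment_angle,
           rng_seed = p$rng_seed), gp)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    gcols <- grep("^geom_", names(df), value = TRUE)
    gp <- as.list(r[gcols])
    names(gp) <- sub("^geom_", "", gcols)
    structure(list(patient_id = r$patient_id, body_weight = r$body_weight,
                   height = r$height, pauwels_angle = r$pauwels_angle,
                   stem_type = r$stem_type,
                   alignment_angle = r$alignment_angle,
                   geometry_params = gp, rng_seed = r$rng_seed),
              class = "patient_record")
  })
}
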