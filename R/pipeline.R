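## Orchestration: per-patient end-to-end run (geometry -> placement -> mesh
## -> loads -> solve -> SED -> stimulus -> zones -> classes), cohort runs
## with pooled calibration and statistics, and the stem-malposition sweep.
## Configuration is a JSON file (or an equivalent R list); every report
## carries a config hash, the seed and the package version.

default_run_config <- function() {
  list(
    body_weight = 70, pauwels_angle = 16, stem_type = "MINIMA",
    alignment_angle = 0, geometry_params = femur_params(),
    max_element_area = 1.0, band_width = 3, thickness = 35,
    joint_force_factor = 2.38, abductor_mode = "equilibrium",
    density_mode = "literal", t_low = 2, t_high = 12,
    weighted_median = TRUE)
}

#' Read / write a run configuration
#' @param path JSON file path.
#' @param config configuration list.
#' @return configuration list (reader); `path` invisibly (writer).
#' @export
read_config <- function(path) {
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stemshield_stop(paste("config error:", conditionMessage(e)),
                                    "config_error"))
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stemshield_stop(sprintf("stage %s: %s", name, conditionMessage(e)),
                    c("stage_error", class(e)[1]))
  })
}

#' Run the full per-patient analysis
#'
#' Executes geometry construction, stem placement, meshing, load-case
#' assembly, the plane-stress solve, SED and stimulus evaluation, Gruen-zone
#' aggregation and mechanostat classification. Deterministic in the config.
#'
#' @param config configuration list (see `default_run_config` entries) or a
#'   JSON path; a `patient_record` can be supplied via `config$patient`.
#' @param out_dir optional artifact directory: writes the per-zone CSV, the
#'   per-element CSV and a VTK mesh with result fields.
#' @param verbose log each stage with element counts, residual and time.
#' @return `patient_result`: `patient_id`, `zone_summaries` (7 rows),
#'   `overload`, `band_elements`, `mesh_stats`, `residual`, `provenance`.
#' @export
run_patient <- function(config = list(), out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!is.null(cfg$patient)) {
    p <- cfg$patient
    cfg$body_weight <- p$body_weight
    cfg$pauwels_angle <- p$pauwels_angle
    cfg$stem_type <- p$stem_type
    cfg$alignment_angle <- p$alignment_angle
    cfg$geometry_params <- p$geometry_params
    cfg$patient_id <- p$patient_id
  }
  if (is.null(cfg$patient_id)) cfg$patient_id <- "P000000"
  hash <- config_hash(cfg[setdiff(names(cfg), "patient")])
  log_stage <- function(...) if (verbose) message(sprintf(...))

  t0 <- proc.time()[3]
  femur <- stage("geometry", build_femur_contour(cfg$geometry_params))
  stem <- stage("geometry", build_stem_contour(cfg$stem_type))
  placed <- stage("placement", place_stem(femur, stem, cfg$alignment_angle))
  mesh <- stage("meshing", triangulate(femur, placed, cfg$max_element_area))
  log_stage("mesh: %d nodes, %d elements", nrow(mesh$nodes), nrow(mesh$triangles))
  materials <- stage("materials", default_materials(cfg$materials %||% list()))
  patient <- list(body_weight = cfg$body_weight,
                  pauwels_angle = cfg$pauwels_angle)
  lc <- stage("loading", build_load_case(patient, femur,
                                         joint_force_factor = cfg$joint_force_factor,
                                         abductor_mode = cfg$abductor_mode,
                                         thickness = cfg$thickness))
  sys <- stage("assembly", fe_assemble(mesh, materials, cfg$thickness))
  disp <- stage("solve", fe_solve(sys, lc))
  log_stage("solve: residual %.3e", disp$residual)
  sed <- stage("sed", strain_energy_density(sys, disp))
  stim <- stage("stimulus", stimulus_field(sed, materials, cfg$density_mode))
  band <- stage("band", interface_band(mesh, placed, cfg$band_width))
  zm <- stage("zones", partition_gruen_zones(femur, placed))
  zones <- stage("zones", zone_of_points(mesh$centroid[band, , drop = FALSE], zm))
  medians <- stage("zones", zone_median_stimulus(stim[band], mesh$area[band],
                                                 zones, cfg$weighted_median))
  thr <- threshold_pair(cfg$t_low, cfg$t_high)
  zs <- predict_zone_remodeling(medians, thr)
  ov <- cortical_overload(stim[band], mesh$area[band], mesh$region_tag[band],
                          thr$t_high)
  elapsed <- proc.time()[3] - t0
  log_stage("done in %.1f s", elapsed)

  res <- structure(list(
    patient_id = cfg$patient_id,
    stem_type = cfg$stem_type, alignment_angle = cfg$alignment_angle,
    zone_summaries = zs, overload = ov,
    band_elements = band, band_zones = zones,
    stimulus = stim, sed = sed, mesh = mesh, displacement = disp,
    mesh_stats = c(nodes = nrow(mesh$nodes), elements = nrow(mesh$triangles)),
    residual = disp$residual, wall_time_s = unname(elapsed),
    provenance = list(config_hash = hash, seed = cfg$seed %||% NA,
                      version = as.character(utils::packageVersion("stemshield")))),
    class = "patient_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    zs_out <- cbind(patient_id = cfg$patient_id, zs,
                    config_hash = hash)
    utils::write.csv(zs_out,
                     file.path(out_dir, paste0(cfg$patient_id, "_zones.csv")),
                     row.names = FALSE)
    elem <- data.frame(sed_MPa = sed$sed, stimulus_J_per_kg = stim,
                       area_mm2 = mesh$area, region = mesh$region_tag)
    utils::write.csv(elem,
                     file.path(out_dir, paste0(cfg$patient_id, "_elements.csv")),
                     row.names = FALSE)
    umag <- sqrt(rowSums(disp$u^2))
    uelem <- (umag[mesh$triangles[, 1]] + umag[mesh$triangles[, 2]] +
              umag[mesh$triangles[, 3]]) / 3
    write_vtk(mesh, file.path(out_dir, paste0(cfg$patient_id, ".vtk")),
              cell_data = list(sed = sed$sed, von_mises = sed$von_mises,
                               stimulus = ifelse(is.na(stim), 0, stim),
                               displacement = uelem))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a synthetic cohort end to end
#'
#' Generates the cohort, runs every patient, produces synthetic observed
#' labels with the ground-truth mechanostat, pools the zone table, then
#' calibrates the thresholds (lower from the resorption-zone Q1 when
#' possible, upper by exhaustive grid search) and computes the two study
#' statistics.
#'
#' @param cohort_config list: `n`, `seed` (mandatory), `stem_mix`,
#'   `noise_rate`, `true_t_low`, `true_t_high`, `grid`, `t_low_mode`
#'   (`"iqr"` default or `"default"`), plus per-run settings as in
#'   [run_patient()].
#' @param verbose log progress.
#' @return `cohort_result`: `patients` (list of `patient_result`),
#'   `zone_table` (pooled data frame), `calibration`
#'   (`calibration_result` + `t_low`, `t_low_source`), `stats`
#'   (`pairwise`, `chi_square`).
#' @export
run_cohort <- function(cohort_config = list(), verbose = FALSE) {
  cfg <- utils::modifyList(
    list(n = 15, seed = NULL, stem_mix = c("PROXIMA", "COLLO_MIS", "MINIMA"),
         noise_rate = 0, true_t_low = 2, true_t_high = 12,
         grid = c(3, 25, 0.25), t_low_mode = "iqr", objective = "three_class"),
    cohort_config)
  if (is.null(cfg$seed))
    stemshield_stop("cohort config must set an explicit seed", "config_error")
  cohort <- generate_cohort(cfg$n, cfg$seed, cfg$stem_mix)
  true_thr <- threshold_pair(cfg$true_t_low, cfg$true_t_high)

  rows <- list(); results <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    if (verbose) message(sprintf("patient %d/%d (%s)", i, length(cohort),
                                 p$stem_type))
    run_cfg_of <- function(p) utils::modifyList(cfg[setdiff(names(cfg),
      c("n", "stem_mix", "noise_rate", "true_t_low", "true_t_high",
        "grid", "t_low_mode", "objective"))], list(patient = p))
    ## a rare jittered geometry cannot seat its stem; such a patient is
    ## redrawn deterministically (the cohort analogue of an exclusion)
    res <- NULL
    for (attempt in 0:3) {
      res <- tryCatch(run_patient(run_cfg_of(p), verbose = FALSE),
                      stemshield_error = function(e) e)
      if (!inherits(res, "error")) break
      p <- generate_patient((p$rng_seed + 500000L * (attempt + 1L)) %% 2147483647L,
                            p$stem_type, p$alignment_angle)
    }
    if (inherits(res, "error")) stop(res)
    med <- stats::setNames(res$zone_summaries$median_stimulus,
                           res$zone_summaries$zone_id)
    obs <- generate_observed_labels(med, true_thr, cfg$noise_rate,
                                    seed = p$rng_seed + 7L)
    rows[[i]] <- data.frame(patient_id = p$patient_id, stem_type = p$stem_type,
                            zone_id = as.integer(names(med)),
                            median_stimulus = as.numeric(med),
                            predicted = res$zone_summaries$predicted,
                            observed = unname(obs),
                            stringsAsFactors = FALSE)
    results[[i]] <- res
  }
  zone_table <- do.call(rbind, rows)

  res_stim <- zone_table$median_stimulus[zone_table$observed == "RESORPTION"]
  if (cfg$t_low_mode == "iqr" && length(res_stim) >= 4) {
    t_low <- lower_threshold_from_iqr(res_stim)
    t_low_source <- "resorption_iqr"
  } else {
    t_low <- cfg$true_t_low
    t_low_source <- if (cfg$t_low_mode == "iqr") "default_fallback" else "default"
  }
  cal <- calibrate_upper_threshold(zone_table$median_stimulus,
                                   zone_table$observed, t_low = t_low,
                                   grid = cfg$grid, objective = cfg$objective)
  cal$t_low <- t_low; cal$t_low_source <- t_low_source

  pw <- pairwise_class_tests(zone_table$median_stimulus, zone_table$observed)
  tab <- table(zone_table$stem_type, zone_table$observed)
  chi <- if (nrow(tab) >= 2 && ncol(tab) >= 2 &&
             all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    chi_square_independence(tab) else NULL

  structure(list(patients = results, zone_table = zone_table,
                 calibration = cal,
                 stats = list(pairwise = pw, chi_square = chi,
                              stem_by_class = tab),
                 config = cfg),
            class = "cohort_result")
}

#' Stem-malposition sensitivity sweep
#'
#' Runs 3 stems x 3 alignments (varus/neutral/valgus) on one patient
#' geometry with identical mesh settings and reports cortical-overload
#' measures and zone medians per cell.
#'
#' @param patient_config per-run configuration as in [run_patient()].
#' @param varus_angle,valgus_angle malposition magnitudes in degrees
#'   (defaults +5 / -5).
#' @return `position_sweep_result`: data frame `cells` (9 rows: `stem_type`,
#'   `alignment`, `alignment_angle`, `max_cortical_stimulus`,
#'   `overload_fraction`, `zone_1`..`zone_7`) plus `results` (the 9
#'   `patient_result`s).
#' @export
position_sweep <- function(patient_config = list(), varus_angle = 5,
                           valgus_angle = -5) {
  stems <- c("COLLO_MIS", "MINIMA", "PROXIMA")
  aligns <- c(VARUS = varus_angle, NEUTRAL = 0, VALGUS = valgus_angle)
  cells <- list(); results <- list()
  k <- 0
  for (st in sort(stems)) for (al in names(aligns)[order(names(aligns))]) {
    k <- k + 1
    cfg <- utils::modifyList(patient_config,
                             list(stem_type = st, alignment_angle = aligns[[al]]))
    res <- run_patient(cfg)
    med <- res$zone_summaries$median_stimulus
    cells[[k]] <- data.frame(stem_type = st, alignment = al,
                             alignment_angle = aligns[[al]],
                             max_cortical_stimulus = res$overload$max_cortical_stimulus,
                             overload_fraction = res$overload$overload_fraction,
                             t(stats::setNames(med, paste0("zone_", 1:7))),
                             stringsAsFactors = FALSE)
    results[[k]] <- res
  }
  structure(list(cells = do.call(rbind, cells), results = results),
            class = "position_sweep_result")
}

#' Command-line entry point
#'
#' Subcommands: `simulate-cohort`, `run-patient`, `position-sweep`,
#' `calibrate`, `stats`. Arguments: `--config <json>`, `--out <dir>`,
#' `--zones <csv>` (calibrate/stats), and for `run-patient` the overrides
#' `--bw`, `--pauwels`, `--alignment`, `--stem`.
#'
#' @param args character vector of CLI arguments.
#' @return exit code: 0 success, 2 config error, 3 numerical failure.
#' @export
stemshield_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  code <- tryCatch({
    cmd <- if (length(args)) args[1] else ""
    cfg_path <- get_opt("--config")
    out <- get_opt("--out", "stemshield_out")
    cfg <- if (!is.null(cfg_path)) read_config(cfg_path) else list()
    if (cmd == "run-patient") {
      for (ov in list(c("--bw", "body_weight"), c("--pauwels", "pauwels_angle"),
                      c("--alignment", "alignment_angle"))) {
        v <- get_opt(ov[1]); if (!is.null(v)) cfg[[ov[2]]] <- as.numeric(v)
      }
      st <- get_opt("--stem"); if (!is.null(st)) cfg$stem_type <- st
      res <- run_patient(cfg, out_dir = out, verbose = TRUE)
      message(sprintf("patient %s: %d zones written to %s",
                      res$patient_id, nrow(res$zone_summaries), out))
      0L
    } else if (cmd == "simulate-cohort") {
      res <- run_cohort(cfg, verbose = TRUE)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(res$zone_table, file.path(out, "zone_table.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(t_low = res$calibration$t_low,
             t_high_star = res$calibration$t_high_star,
             accuracy = res$calibration$accuracy,
             plateau = res$calibration$plateau),
        file.path(out, "calibration.json"), auto_unbox = TRUE, digits = NA)
      0L
    } else if (cmd == "position-sweep") {
      res <- position_sweep(cfg)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(res$cells, file.path(out, "position_sweep.csv"),
                       row.names = FALSE)
      0L
    } else if (cmd %in% c("calibrate", "stats")) {
      zpath <- get_opt("--zones")
      if (is.null(zpath) || !file.exists(zpath))
        stemshield_stop("calibrate/stats need --zones <zone_table.csv>",
                        "config_error")
      zt <- utils::read.csv(zpath, stringsAsFactors = FALSE)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      if (cmd == "calibrate") {
        cal <- calibrate_upper_threshold(zt$median_stimulus, zt$observed,
                                         t_low = cfg$t_low %||% 2,
                                         grid = cfg$grid %||% c(3, 25, 0.25))
        jsonlite::write_json(cal[c("t_high_star", "accuracy", "plateau",
                                   "grid_step")],
                             file.path(out, "calibration.json"),
                             auto_unbox = TRUE, digits = NA)
      } else {
        pw <- pairwise_class_tests(zt$median_stimulus, zt$observed)
        rep <- list(pairwise = pw)
        if (!is.null(zt$stem_type)) {
          tab <- table(zt$stem_type, zt$observed)
          if (nrow(tab) >= 2 && ncol(tab) >= 2) {
            chi <- chi_square_independence(tab)
            rep$chi_square <- chi[c("statistic", "p_value", "df", "method")]
          }
        }
        jsonlite::write_json(rep, file.path(out, "stats.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      0L
    } else {
      message("usage: stemshield ",
              "<run-patient|simulate-cohort|position-sweep|calibrate|stats> ",
              "[--config cfg.json] [--zones zone_table.csv] [--out dir]")
      2L
    }
  },
  error = function(e) {
    message(conditionMessage(e))
    if (inherits(e, "config_error") || inherits(e, "invalid_parameter")) 2L else 3L
  })
  invisible(code)
}
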