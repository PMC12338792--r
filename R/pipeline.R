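#' Pipeline configuration
#'
#' Collects every tunable of the simulate/calibrate/analyze workflow with
#' validated defaults. The configuration round-trips to YAML via
#' [write_config()] / [read_config()].
#'
#' @param out_dir output directory for volumes, tables and reports.
#' @param seed master integer seed; per-volume seeds are derived from it.
#' @param window A-scan averaging window (raw columns per block).
#' @param n_trim averaged columns trimmed from each B-scan end.
#' @param prominence_mult,min_prominence prominence rule, see [calibrate()].
#' @param min_fit_points minimum attenuation ROI length.
#' @param roi_trim pixels excluded at the ROI ends, see [fit_attenuation()].
#' @param alpha ANOVA gate level.
#' @param iqr_k IQR fence multiplier.
#' @param refractive_index optical-to-geometric path divisor (1 = off).
#' @param scale log-intensity convention of generated volumes.
#' @param n_mice mice per group in simulated studies.
#' @param months months simulated.
#' @param n_ascans_per_bscan,n_bscans,axial_pitch,lateral_pitch volume
#'   geometry for simulated studies.
#' @param speckle_shape,thickness_jitter phantom noise parameters, see
#'   [phantom_spec()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "octskin_run", seed = 1,
                            window = 10, n_trim = 15,
                            prominence_mult = 4.5, min_prominence = 0.1,
                            min_fit_points = 5, roi_trim = c(1, 2),
                            alpha = 0.05, iqr_k = 3, refractive_index = 1,
                            scale = "ln_amplitude",
                            n_mice = 6, months = 0:7,
                            n_ascans_per_bscan = 1355, n_bscans = 120,
                            axial_pitch = 4, lateral_pitch = 4.4,
                            speckle_shape = 16, thickness_jitter = 10) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              window = as.integer(window), n_trim = as.integer(n_trim),
              prominence_mult = prominence_mult,
              min_prominence = min_prominence,
              min_fit_points = as.integer(min_fit_points),
              roi_trim = as.integer(roi_trim), alpha = alpha, iqr_k = iqr_k,
              refractive_index = refractive_index, scale = scale,
              n_mice = as.integer(n_mice), months = as.integer(months),
              n_ascans_per_bscan = as.integer(n_ascans_per_bscan),
              n_bscans = as.integer(n_bscans), axial_pitch = axial_pitch,
              lateral_pitch = lateral_pitch, speckle_shape = speckle_shape,
              thickness_jitter = thickness_jitter)
  stopifnot(cfg$window >= 1, cfg$n_trim >= 0, cfg$prominence_mult > 0,
            cfg$min_prominence > 0, cfg$min_fit_points >= 2,
            length(cfg$roi_trim) == 2, all(cfg$roi_trim >= 0),
            cfg$alpha > 0, cfg$alpha <= 1, cfg$iqr_k > 0,
            cfg$refractive_index > 0, cfg$n_mice >= 1,
            length(cfg$months) >= 1, all(cfg$months >= 0),
            cfg$n_ascans_per_bscan >= 1, cfg$n_bscans >= 1,
            cfg$axial_pitch > 0, cfg$lateral_pitch > 0,
            cfg$speckle_shape > 0, cfg$thickness_jitter >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Derived per-volume seed, kept inside 32-bit integer range.
.derive_seed <- function(master, index) {
  as.integer((as.double(master) * 10007 + index) %% 2147483647)
}

#' Place calibration annotations on a phantom from its ground truth
#'
#' Returns an air box ending 5 pixels above the shallowest realized surface
#' and a muscle box starting 2 pixels above the shallowest muscle interface,
#' so the pooled muscle mean includes the bright interface line and sits just
#' above the muscle plateau (see the methods vignette). This stands in for
#' the visual region identification a reader performs on real reference
#' scans.
#'
#' @param truth a `ground_truth` from [generate_volume()].
#' @param vol the matching [oct_volume()].
#' @param volume_id id recorded in the annotations.
#' @return List of two [region_annotation()]s (air, muscle).
#' @export
truth_annotations <- function(truth, vol, volume_id) {
  d <- dim(vol$intensity)
  p <- vol$axial_pitch
  surf_px0 <- ceiling(min(truth$surface_depth) / p) # 0-based row of interface
  musc_px0 <- ceiling(min(truth$muscle_depth) / p)
  air_hi <- surf_px0 - 5
  musc_lo <- musc_px0 - 2
  musc_hi <- min(musc_lo + 30, d[1])
  if (air_hi < 1 || musc_hi <= musc_lo)
    stop("volume too shallow to place default annotations", call. = FALSE)
  list(region_annotation(volume_id, "air", c(0, air_hi), c(0, d[2]), c(0, d[3])),
       region_annotation(volume_id, "muscle", c(musc_lo, musc_hi),
                         c(0, d[2]), c(0, d[3])))
}

#' Simulate a full study to disk
#'
#' Generates one phantom volume per (mouse, group, site, month) record of the
#' study design, with per-mouse true attenuation and thickness drawn around
#' the group trajectories of [study_effect_profile()]. Writes volumes
#' (TIFF + sidecar), ground truth JSONs, a study table CSV, and, for one
#' baseline volume per group, region annotations designated for calibration.
#'
#' @param config a [pipeline_config()].
#' @param mouse_sd_mu,mouse_sd_thickness between-mouse standard deviations of
#'   true dermal attenuation (mm^-1) and skin thickness (um).
#' @return Invisibly, the study table data.frame (with a `reference` column).
#' @export
run_simulate <- function(config, mouse_sd_mu = 3, mouse_sd_thickness = 25) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("volumes", "truth", "annotations"))
    dir.create(file.path(config$out_dir, sub), showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop("cannot create output directory: ", config$out_dir, call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  mu_eff <- study_effect_profile("mu_mm_inv", months = config$months)
  th_eff <- study_effect_profile("thickness_um", months = config$months)
  design <- expand.grid(mouse = seq_len(config$n_mice), group = .groups,
                        site = .sites, month = config$months,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$mouse_id <- sprintf("%s_m%d", design$group, design$mouse)
  mice <- unique(design$mouse_id)
  int_mu <- stats::setNames(rnorm(length(mice), 0, mouse_sd_mu), mice)
  int_th <- stats::setNames(rnorm(length(mice), 0, mouse_sd_thickness), mice)
  mkey <- cbind(design$group, design$site, as.character(design$month))
  design$true_mu <- pmax(5, mu_eff[mkey] + int_mu[design$mouse_id])
  design$true_thickness <- pmax(150, th_eff[mkey] + int_th[design$mouse_id])
  design$volume_id <- sprintf("%s_%s_m%d", design$mouse_id, design$site,
                              design$month)
  design$volume_path <- file.path("volumes", paste0(design$volume_id, ".tif"))
  design$reference <- design$mouse == 1 & design$month == config$months[1] &
    design$site == "back"
  refs <- list()
  for (i in seq_len(nrow(design))) {
    layers <- default_skin_layers(
      dermis_attenuation = design$true_mu[i],
      dermis_thickness = design$true_thickness[i] - 20)
    spec <- phantom_spec(layers = layers, axial_pitch = config$axial_pitch,
                         n_ascans_per_bscan = config$n_ascans_per_bscan,
                         n_bscans = config$n_bscans,
                         lateral_pitch = config$lateral_pitch,
                         speckle_shape = config$speckle_shape,
                         thickness_jitter = config$thickness_jitter,
                         seed = .derive_seed(config$seed, i))
    gen <- generate_volume(spec)
    gen$volume$source_id <- design$volume_id[i]
    write_volume(gen$volume, file.path(config$out_dir, design$volume_path[i]))
    jsonlite::write_json(
      lapply(unclass(gen$truth), function(x) if (is.matrix(x)) as.data.frame(x) else x),
      file.path(config$out_dir, "truth", paste0(design$volume_id[i], ".json")),
      auto_unbox = TRUE, digits = NA)
    if (design$reference[i]) {
      ann <- truth_annotations(gen$truth, gen$volume, design$volume_id[i])
      ann_path <- file.path("annotations", paste0(design$volume_id[i], ".json"))
      write_annotations(ann, file.path(config$out_dir, ann_path))
      refs[[length(refs) + 1]] <- list(volume_id = design$volume_id[i],
                                       volume_path = design$volume_path[i],
                                       annotation_path = ann_path)
    }
  }
  table_cols <- c("mouse_id", "group", "site", "month", "volume_path",
                  "reference")
  write_study_table(design[table_cols],
                    file.path(config$out_dir, "study_table.csv"))
  jsonlite::write_json(refs, file.path(config$out_dir, "references.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(design)
}

#' Calibrate from the reference volumes of a simulated or curated run
#'
#' Reads `references.json` in `config$out_dir` (one annotated baseline volume
#' per group), computes the [calibrate()] constants and writes them to
#' `calibration.json`.
#'
#' @param config a [pipeline_config()].
#' @return The `calibration_reference`, invisibly.
#' @export
run_calibrate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ref_path <- file.path(config$out_dir, "references.json")
  if (!file.exists(ref_path))
    stop("no references.json in ", config$out_dir, call. = FALSE)
  refs <- jsonlite::read_json(ref_path, simplifyVector = FALSE)
  references <- lapply(refs, function(r)
    list(volume = read_volume(file.path(config$out_dir, r$volume_path)),
         annotations = read_annotations(file.path(config$out_dir,
                                                  r$annotation_path))))
  cal <- calibrate(references, prominence_mult = config$prominence_mult,
                   min_prominence = config$min_prominence,
                   window = config$window)
  jsonlite::write_json(unclass(cal),
                       file.path(config$out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cal)
}

# Analyze one volume; returns thickness/attenuation metrics or NAs on
# segmentation failure.
analyze_volume <- function(vol, cal, config) {
  avg <- preprocess_volume(vol, window = config$window, n_trim = config$n_trim)
  seg <- segment_volume(avg, cal)
  out <- list(thickness_um = NA_real_, mu_mm_inv = NA_real_,
              n_valid = sum(seg$valid), n_total = nrow(seg))
  if (any(seg$valid)) {
    th <- measure_thickness(seg, vol$axial_pitch,
                            refractive_index = config$refractive_index)
    out$thickness_um <- th$volume_mean
    at <- tryCatch(
      measure_attenuation(avg, seg, vol$axial_pitch, scale = vol$scale,
                          min_points = config$min_fit_points,
                          roi_trim = config$roi_trim),
      error = function(e) NULL)
    if (!is.null(at)) out$mu_mm_inv <- at$volume_mean
  }
  out
}

#' Analyze a study: per-volume metrics and group statistics
#'
#' For every study record, reads the volume, applies A-scan averaging and
#' trimming, segments every usable averaged A-scan, and measures the volume
#' mean skin thickness and attenuation coefficient. Segmentation failure on a
#' volume is recorded as a missing value and the run continues; an unreadable
#' volume is an error naming the record. Per-metric comparison plans and
#' longitudinal summaries are then computed and everything is written as CSV
#' under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param study_table study table data.frame or CSV path (defaults to the one
#'   written by [run_simulate()]).
#' @return List with `metrics`, `comparisons`, `longitudinal`, `calibration`.
#' @export
run_analyze <- function(config,
                        study_table = file.path(config$out_dir,
                                                "study_table.csv")) {
  stopifnot(inherits(config, "pipeline_config"))
  tab <- if (is.character(study_table)) read_study_table(study_table)
         else study_table
  cal_path <- file.path(config$out_dir, "calibration.json")
  cal <- if (file.exists(cal_path)) {
    raw <- jsonlite::read_json(cal_path, simplifyVector = TRUE)
    structure(raw, class = "calibration_reference")
  } else run_calibrate(config)
  log_lines <- c(sprintf("calibration: air_mean=%.6f muscle_mean=%.6f prominence=%.6f",
                         cal$air_mean, cal$muscle_mean,
                         cal$prominence_threshold))
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    vpath <- file.path(config$out_dir, tab$volume_path[i])
    if (!file.exists(vpath))
      stop(sprintf("unreadable volume for record %s/%s/month %d: %s",
                   tab$mouse_id[i], tab$site[i], tab$month[i], vpath),
           call. = FALSE)
    m <- analyze_volume(read_volume(vpath), cal, config)
    log_lines <- c(log_lines,
                   sprintf("%s: n_valid=%d/%d thickness=%.2f mu=%.3f",
                           basename(vpath), m$n_valid, m$n_total,
                           m$thickness_um, m$mu_mm_inv))
    rows[[i]] <- data.frame(mouse_id = tab$mouse_id[i], group = tab$group[i],
                            site = tab$site[i], month = tab$month[i],
                            thickness_um = m$thickness_um,
                            mu_mm_inv = m$mu_mm_inv,
                            n_valid = m$n_valid, n_total = m$n_total,
                            stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  months <- sort(unique(metrics$month))
  comparisons <- NULL; longitudinal <- list()
  for (metric in c("thickness_um", "mu_mm_inv")) {
    keep <- !is.na(metrics[[metric]])
    ser <- metric_series(metric, data.frame(
      mouse_id = metrics$mouse_id[keep], group = metrics$group[keep],
      site = metrics$site[keep], month = metrics$month[keep],
      value = metrics[[metric]][keep], stringsAsFactors = FALSE))
    if (length(months) >= 2) {
      cmp <- run_comparison_plan(ser, alpha = config$alpha,
                                 iqr_k = config$iqr_k,
                                 baseline_month = months[1],
                                 final_month = months[length(months)])
      comparisons <- rbind(comparisons, cmp)
      longitudinal[[metric]] <- longitudinal_summary(ser)
    }
  }
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
  for (metric in names(longitudinal)) {
    utils::write.csv(longitudinal[[metric]]$means,
                     file.path(config$out_dir,
                               sprintf("longitudinal_means_%s.csv", metric)),
                     row.names = FALSE)
    utils::write.csv(longitudinal[[metric]]$trends,
                     file.path(config$out_dir,
                               sprintf("longitudinal_trends_%s.csv", metric)),
                     row.names = FALSE)
  }
  writeLines(log_lines, file.path(config$out_dir, "analysis_log.txt"))
  list(metrics = metrics, comparisons = comparisons,
       longitudinal = longitudinal, calibration = cal)
}
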