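#' Block-average the A-scan columns of a B-scan
#'
#' Column `j` of the output is the arithmetic mean (on the stored log scale)
#' of raw columns `[(j-1)*window + 1, min(j*window, n_raw)]`; the trailing
#' partial block is kept. This is the convention under which a 1355-column
#' B-scan averaged in sets of 10 and trimmed by 15 on each side yields 106
#' usable averaged A-scans.
#'
#' @param bscan 2-D numeric matrix (axial pixel x raw A-scan column) of
#'   log-scale intensities.
#' @param window number of raw columns per block (>= 1). A window larger than
#'   the number of raw columns yields a single averaged column.
#' @param axial_pitch axial pixel pitch in micrometres (metadata).
#' @return An `averaged_bscan` object: `intensity` (axial x averaged column),
#'   `n_raw_per_column`, `trimmed`, `axial_pitch`.
#' @export
average_columns <- function(bscan, window, axial_pitch = NA_real_) {
  stopifnot(is.matrix(bscan), is.numeric(bscan),
            length(window) == 1, window >= 1, window == as.integer(window))
  n_raw <- ncol(bscan)
  grp <- (seq_len(n_raw) - 1) %/% window + 1
  counts <- tabulate(grp)
  out <- t(rowsum(t(bscan), grp, reorder = TRUE)) / rep(counts, each = nrow(bscan))
  dimnames(out) <- NULL
  structure(list(intensity = out, n_raw_per_column = as.integer(window),
                 trimmed = 0L, axial_pitch = axial_pitch),
            class = "averaged_bscan")
}

#' Remove low-intensity edge columns from an averaged B-scan
#'
#' The first and last `n_trim` averaged A-scans of each B-scan are excluded
#' from analysis (scan edges typically have low signal).
#'
#' @param averaged an `averaged_bscan` from [average_columns()].
#' @param n_trim columns removed from each end; `2 * n_trim` must be smaller
#'   than the column count.
#' @return The trimmed `averaged_bscan`; `trimmed` records the count removed.
#' @export
trim_edges <- function(averaged, n_trim) {
  stopifnot(inherits(averaged, "averaged_bscan"),
            length(n_trim) == 1, n_trim >= 0, n_trim == as.integer(n_trim))
  nc <- ncol(averaged$intensity)
  if (2 * n_trim >= nc)
    stop(sprintf("trimming %d columns from each end of %d would leave nothing",
                 n_trim, nc), call. = FALSE)
  if (n_trim > 0)
    averaged$intensity <- averaged$intensity[, (n_trim + 1):(nc - n_trim), drop = FALSE]
  averaged$trimmed <- averaged$trimmed + as.integer(n_trim)
  averaged
}

#' Average and trim every B-scan of a volume
#'
#' @param vol an [oct_volume()].
#' @param window averaging window (raw A-scans per block), default 10.
#' @param n_trim averaged columns trimmed from each end, default 15.
#' @return 3-D array (axial x usable averaged column x B-scan) with attributes
#'   `n_raw_per_column`, `trimmed`, `axial_pitch` and `scale`.
#' @export
preprocess_volume <- function(vol, window = 10, n_trim = 15) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensity)
  first <- trim_edges(average_columns(vol$intensity[, , 1], window,
                                      vol$axial_pitch), n_trim)
  out <- array(NA_real_, c(d[1], ncol(first$intensity), d[3]))
  out[, , 1] <- first$intensity
  if (d[3] > 1) for (b in 2:d[3]) {
    ab <- trim_edges(average_columns(vol$intensity[, , b], window,
                                     vol$axial_pitch), n_trim)
    out[, , b] <- ab$intensity
  }
  structure(out, n_raw_per_column = as.integer(window),
            trimmed = as.integer(n_trim), axial_pitch = vol$axial_pitch,
            scale = vol$scale)
}

#' Derive calibration constants from annotated reference volumes
#'
#' The noise floor (`air_mean`) and the muscle boundary threshold
#' (`muscle_mean`) are the means of the log-scale intensities inside the
#' pooled annotated air and muscle regions across all reference volumes. The
#' peak prominence threshold is a configured surrogate for a manually tuned
#' choice: `max(prominence_mult * sd(air voxels) / sqrt(window),
#' min_prominence)`, i.e. a multiple of the noise scale of the
#' window-averaged A-scan columns that peak detection actually searches. The
#' default multiplier (4.5 standard errors) was chosen on synthetic reference
#' volumes to reject spurious air-noise peaks while retaining interface peaks
#' weakened by block averaging across a jittered interface.
#'
#' @param references list of references, each a list with elements `volume`
#'   (an [oct_volume()]) and `annotations` (list of [region_annotation()]s
#'   containing one air and one muscle region).
#' @param prominence_mult multiplier on the averaged-column air noise scale
#'   (default 4.5).
#' @param min_prominence lower floor for the prominence threshold in log
#'   units (default 0.1), so that noiseless references still yield a positive
#'   threshold.
#' @param window the A-scan averaging window used downstream (default 10).
#' @return A `calibration_reference`: `air_mean`, `muscle_mean`,
#'   `prominence_threshold`, `air_sd`, `source_volumes`.
#' @export
calibrate <- function(references, prominence_mult = 4.5, min_prominence = 0.1,
                      window = 10) {
  stopifnot(is.list(references), length(references) >= 1,
            prominence_mult > 0, min_prominence > 0, window >= 1)
  air <- list(); muscle <- list(); ids <- character(0)
  for (ref in references) {
    vol <- ref$volume
    anns <- ref$annotations
    regions <- vapply(anns, `[[`, character(1), "region")
    if (!("air" %in% regions) || !("muscle" %in% regions))
      stop("each reference needs one air and one muscle annotation", call. = FALSE)
    a <- anns[[match("air", regions)]]
    m <- anns[[match("muscle", regions)]]
    if (a$axial[2] > m$axial[1])
      stop("air region must be shallower than muscle region", call. = FALSE)
    av <- annotation_voxels(vol, a)
    mv <- annotation_voxels(vol, m)
    if (length(av) == 0 || length(mv) == 0)
      stop("empty annotated region", call. = FALSE)
    air[[length(air) + 1]] <- av
    muscle[[length(muscle) + 1]] <- mv
    ids <- c(ids, vol$source_id)
  }
  air <- unlist(air); muscle <- unlist(muscle)
  air_mean <- mean(air); muscle_mean <- mean(muscle)
  if (air_mean >= muscle_mean)
    stop(sprintf(
      "calibration failure: air mean (%.3f) not below muscle mean (%.3f)",
      air_mean, muscle_mean), call. = FALSE)
  # population sd: a noise-scale estimate that is invariant to pooling a
  # reference with itself
  air_sd <- sqrt(mean((air - air_mean)^2))
  air_noise <- air_sd / sqrt(window)
  structure(list(air_mean = air_mean, muscle_mean = muscle_mean,
                 prominence_threshold = max(prominence_mult * air_noise,
                                            min_prominence),
                 air_sd = air_sd, source_volumes = ids),
            class = "calibration_reference")
}

#' @export
print.calibration_reference <- function(x, ...) {
  cat(sprintf(
    "calibration_reference: air %.3f, muscle %.3f, prominence %.3f (from %d volume(s))\n",
    x$air_mean, x$muscle_mean, x$prominence_threshold, length(x$source_volumes)))
  invisible(x)
}
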