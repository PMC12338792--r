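#' Detect intensity peaks in an A-scan depth profile
#'
#' Local maxima whose value exceeds the noise floor and whose topographic
#' prominence is at least the threshold, in increasing depth order. A flat
#' plateau counts once, at its shallowest index.
#'
#' @param column numeric log-intensity depth profile (finite values).
#' @param noise_floor log-intensity noise floor (mean air intensity); only
#'   peaks strictly above it are returned.
#' @param prominence topographic prominence threshold (> 0, log units).
#' @return Integer vector of 1-based axial indices (possibly empty).
#' @export
detect_peaks <- function(column, noise_floor, prominence) {
  stopifnot(is.numeric(column), all(is.finite(column)),
            length(prominence) == 1, prominence > 0)
  pk <- .peak_prominences(as.numeric(column))
  if (nrow(pk) == 0) return(integer(0))
  keep <- column[pk[, 1]] > noise_floor & pk[, 2] >= prominence
  as.integer(pk[keep, 1])
}

#' Locate the dermis-muscle boundary in an A-scan
#'
#' The boundary is the first axial index deeper than the surface peak at
#' which the intensity drops strictly below the mean muscle intensity. The
#' search starts only once the profile has fallen below the surface-peak
#' value minus `descent`, so the dark trough on the surface peak's own
#' falling edge cannot trigger the global threshold.
#'
#' @param column numeric log-intensity depth profile.
#' @param surface_idx 1-based axial index of the surface peak.
#' @param muscle_mean log-intensity muscle threshold.
#' @param descent drop below the surface-peak value (log units) required
#'   before the threshold search begins; typically the calibration's
#'   prominence threshold.
#' @return 1-based axial index, or `NA_integer_` if the intensity never drops
#'   below `muscle_mean`.
#' @export
detect_muscle_boundary <- function(column, surface_idx, muscle_mean,
                                   descent = 0) {
  n <- length(column)
  stopifnot(surface_idx >= 1, surface_idx <= n)
  if (surface_idx == n) return(NA_integer_)
  after <- column[(surface_idx + 1):n]
  start <- which(after < column[surface_idx] - descent)
  if (length(start) == 0) return(NA_integer_)
  hit <- which(after[start[1]:length(after)] < muscle_mean)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(surface_idx + start[1] - 1 + hit[1])
}

#' Segment one averaged A-scan into surface, DEJ and muscle boundary
#'
#' The skin surface is the first peak above the noise floor, the
#' dermal-epidermal junction (DEJ) the second, and the muscle boundary the
#' first subsequent drop below the mean muscle intensity. A column is valid
#' only if all three are found in increasing depth order; invalid columns are
#' data (excluded from volume means), not errors.
#'
#' @param column numeric log-intensity depth profile.
#' @param cal a `calibration_reference` from [calibrate()].
#' @return List with `surface_idx`, `dej_idx`, `muscle_idx` (1-based, `NA`
#'   when not found) and logical `valid`.
#' @export
segment_column <- function(column, cal) {
  stopifnot(inherits(cal, "calibration_reference"))
  peaks <- detect_peaks(column, cal$air_mean, cal$prominence_threshold)
  surface <- if (length(peaks) >= 1) peaks[1] else NA_integer_
  dej <- if (length(peaks) >= 2) peaks[2] else NA_integer_
  muscle <- if (!is.na(surface))
    detect_muscle_boundary(column, surface, cal$muscle_mean,
                           descent = cal$prominence_threshold)
  else NA_integer_
  valid <- !is.na(surface) && !is.na(dej) && !is.na(muscle) &&
    surface < dej && dej < muscle
  list(surface_idx = surface, dej_idx = dej, muscle_idx = muscle,
       valid = valid)
}

#' Segment every usable averaged A-scan of a volume
#'
#' @param avg 3-D averaged array from [preprocess_volume()] (or any
#'   axial x column x B-scan array of log intensities).
#' @param cal a `calibration_reference`.
#' @return `data.frame` with one row per averaged A-scan: `bscan`, `column`,
#'   `surface_idx`, `dej_idx`, `muscle_idx`, `valid`.
#' @export
segment_volume <- function(avg, cal) {
  stopifnot(length(dim(avg)) == 3)
  d <- dim(avg)
  n <- d[2] * d[3]
  surface <- dej <- muscle <- integer(n)
  valid <- logical(n)
  i <- 0L
  for (b in seq_len(d[3])) {
    slab <- avg[, , b]
    for (j in seq_len(d[2])) {
      i <- i + 1L
      s <- segment_column(slab[, j], cal)
      surface[i] <- s$surface_idx; dej[i] <- s$dej_idx
      muscle[i] <- s$muscle_idx; valid[i] <- s$valid
    }
  }
  data.frame(bscan = rep(seq_len(d[3]), each = d[2]),
             column = rep(seq_len(d[2]), times = d[3]),
             surface_idx = surface, dej_idx = dej, muscle_idx = muscle,
             valid = valid)
}

#' Per-volume skin thickness from segmented columns
#'
#' Thickness is the optical path from the surface peak to the dermis-muscle
#' boundary: `(muscle_idx - surface_idx) * axial_pitch`, optionally divided
#' by a refractive index (default 1, i.e. no correction). The volume mean is
#' taken over valid columns only.
#'
#' @param segments segmentation `data.frame` from [segment_volume()].
#' @param axial_pitch axial pixel pitch in micrometres.
#' @param refractive_index divisor converting optical to geometric path.
#' @return A `thickness_result`: `per_ascan` (um, valid columns),
#'   `volume_mean`, `n_valid`, `n_total`.
#' @export
measure_thickness <- function(segments, axial_pitch, refractive_index = 1) {
  stopifnot(axial_pitch > 0, refractive_index > 0)
  ok <- segments$valid
  if (!any(ok))
    stop("segmentation failed for every A-scan in the volume", call. = FALSE)
  per <- (segments$muscle_idx[ok] - segments$surface_idx[ok]) *
    axial_pitch / refractive_index
  structure(list(per_ascan = per, volume_mean = mean(per),
                 n_valid = sum(ok), n_total = nrow(segments)),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("thickness_result: mean %.1f um over %d/%d valid A-scans\n",
              x$volume_mean, x$n_valid, x$n_total))
  invisible(x)
}
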