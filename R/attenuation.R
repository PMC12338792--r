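#' Fit the attenuation coefficient of one averaged A-scan
#'
#' Under the single-scattering Lambert-Beer model the mean detected amplitude
#' decays as `A0 * exp(-mu * z)`, so on a log scale the dermis is a straight
#' line in depth. An ordinary least-squares line is fitted to the stored log
#' intensities over the dermal region of interest, which runs from the DEJ
#' peak to the detected dermis-muscle boundary. By default the ROI excludes
#' 1 pixel after the DEJ peak and 2 pixels before the muscle boundary so that
#' the one-pixel interface reflections, which are not dermal scattering, do
#' not leverage the fit.
#'
#' `mu` is `-slope` converted to mm^-1 under the stored log convention:
#' natural-log amplitude directly, or `-slope * ln(10) / 10` for decibel
#' intensity. No round-trip factor is applied.
#'
#' @param column numeric log-intensity depth profile.
#' @param profile segmentation result for this column (list with `dej_idx`,
#'   `muscle_idx`, `valid`), e.g. from [segment_column()].
#' @param axial_pitch axial pixel pitch in micrometres.
#' @param scale `"ln_amplitude"` or `"db"`.
#' @param min_points minimum ROI length for a valid fit (default 5).
#' @param roi_trim integer length 2: pixels excluded after the DEJ peak and
#'   before the muscle boundary.
#' @return An `attenuation_fit`: `mu` (mm^-1), `intercept` (log intensity at
#'   ROI start), `roi_start`, `roi_end` (1-based, end exclusive), `n_points`,
#'   `residual_rms`, `valid`.
#' @export
fit_attenuation <- function(column, profile, axial_pitch,
                            scale = "ln_amplitude", min_points = 5,
                            roi_trim = c(1, 2)) {
  stopifnot(axial_pitch > 0, min_points >= 2, length(roi_trim) == 2)
  invalid <- list(mu = NA_real_, intercept = NA_real_,
                  roi_start = NA_integer_, roi_end = NA_integer_,
                  n_points = 0L, residual_rms = NA_real_, valid = FALSE)
  class(invalid) <- "attenuation_fit"
  if (!isTRUE(profile$valid)) return(invalid)
  start <- profile$dej_idx + roi_trim[1]
  end <- profile$muscle_idx - roi_trim[2]          # exclusive
  n <- end - start
  if (n < min_points) {
    invalid$n_points <- max(0L, as.integer(n))
    return(invalid)
  }
  rows <- start:(end - 1)
  z <- (rows - 1) * axial_pitch / 1000             # depth in mm
  y <- column[rows]
  zc <- z - mean(z)
  slope <- sum(zc * y) / sum(zc^2)
  intercept <- mean(y) - slope * mean(z) + slope * z[1]
  res <- y - (mean(y) + slope * zc)
  mu <- switch(scale,
               ln_amplitude = -slope,
               db = -slope * log(10) / 10,
               stop("unknown scale convention: ", scale, call. = FALSE))
  structure(list(mu = mu, intercept = intercept,
                 roi_start = as.integer(start), roi_end = as.integer(end),
                 n_points = as.integer(n),
                 residual_rms = sqrt(mean(res^2)), valid = TRUE),
            class = "attenuation_fit")
}

#' Per-volume attenuation coefficient from segmented columns
#'
#' Repeats [fit_attenuation()] for every usable averaged A-scan and averages
#' `mu` over the valid fits.
#'
#' @param avg 3-D averaged array from [preprocess_volume()].
#' @param segments segmentation `data.frame` from [segment_volume()].
#' @param axial_pitch axial pixel pitch in micrometres.
#' @inheritParams fit_attenuation
#' @return An `attenuation_result`: `per_ascan` (mm^-1, valid fits),
#'   `volume_mean`, `n_valid`, `n_total`.
#' @export
measure_attenuation <- function(avg, segments, axial_pitch,
                                scale = "ln_amplitude", min_points = 5,
                                roi_trim = c(1, 2)) {
  stopifnot(length(dim(avg)) == 3, nrow(segments) == dim(avg)[2] * dim(avg)[3])
  mus <- rep(NA_real_, nrow(segments))
  for (i in which(segments$valid)) {
    col <- avg[, segments$column[i], segments$bscan[i]]
    f <- fit_attenuation(col, list(dej_idx = segments$dej_idx[i],
                                   muscle_idx = segments$muscle_idx[i],
                                   valid = TRUE),
                         axial_pitch, scale, min_points, roi_trim)
    if (f$valid) mus[i] <- f$mu
  }
  ok <- !is.na(mus)
  if (!any(ok))
    stop("no valid attenuation fit in the volume", call. = FALSE)
  structure(list(per_ascan = mus[ok], volume_mean = mean(mus[ok]),
                 n_valid = sum(ok), n_total = nrow(segments)),
            class = "attenuation_result")
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf("attenuation_result: mean %.2f mm^-1 over %d/%d valid fits\n",
              x$volume_mean, x$n_valid, x$n_total))
  invisible(x)
}
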