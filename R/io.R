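#' Construct an OCT volume object
#'
#' A volume is a 3-D array of log-scale intensity values indexed
#' (axial pixel, lateral A-scan, B-scan) plus pixel geometry and the label of
#' the logarithmic intensity convention (`"ln_amplitude"` for natural-log
#' amplitude, `"db"` for decibel intensity).
#'
#' @param intensity 3-D numeric array, all values finite.
#' @param axial_pitch,lateral_pitch pixel spacing in micrometres (> 0).
#' @param scale log-intensity convention label.
#' @param source_id free-text provenance.
#' @return An `oct_volume` object.
#' @export
oct_volume <- function(intensity, axial_pitch, lateral_pitch,
                       scale = "ln_amplitude", source_id = "") {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3,
            all(dim(intensity) >= 1),
            is.numeric(axial_pitch), axial_pitch > 0,
            is.numeric(lateral_pitch), lateral_pitch > 0,
            is.character(scale), length(scale) == 1)
  if (!all(is.finite(intensity)))
    stop("oct_volume intensity values must all be finite", call. = FALSE)
  structure(list(intensity = intensity, axial_pitch = axial_pitch,
                 lateral_pitch = lateral_pitch, scale = scale,
                 source_id = source_id),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("oct_volume: %d axial x %d A-scans x %d B-scans (%g/%g um pitch, scale %s)\n",
              d[1], d[2], d[3], x$axial_pitch, x$lateral_pitch, x$scale))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensity)

# Fixed affine mapping used to place log intensities on the [0,1] range the
# TIFF writer stores (32-bit samples). Storage precision is ~2e-8 log units.
.tiff_offset <- -64
.tiff_scale <- 96

#' Write an OCT volume as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per B-scan. Log intensities are mapped by a fixed affine
#' transform onto `[0, 1]` and stored as 32-bit samples; the sidecar records
#' pitches, scale convention, shape, source id and the affine constants.
#' Values must lie in `[-64, 32]` log units.
#'
#' @param vol an [oct_volume()].
#' @param path path of the TIFF file; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  rng <- range(vol$intensity)
  if (rng[1] < .tiff_offset || rng[2] > .tiff_offset + .tiff_scale)
    stop(sprintf("intensity range [%g, %g] outside storable range [%g, %g]",
                 rng[1], rng[2], .tiff_offset, .tiff_offset + .tiff_scale),
         call. = FALSE)
  d <- dim(vol$intensity)
  pages <- lapply(seq_len(d[3]), function(b)
    (vol$intensity[, , b] - .tiff_offset) / .tiff_scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(shape = d, axial_pitch = vol$axial_pitch,
                  lateral_pitch = vol$lateral_pitch, scale = vol$scale,
                  source_id = vol$source_id,
                  affine = list(offset = .tiff_offset, scale = .tiff_scale))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an OCT volume written by [write_volume()]
#'
#' @param path path of the multi-page TIFF; `<path>.json` must exist.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("volume file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar_path))
    stop("JSON sidecar not found: ", sidecar_path, call. = FALSE)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("shape", "axial_pitch", "lateral_pitch", "scale", "source_id", "affine"))
    if (is.null(sc[[f]]))
      stop("sidecar missing required field: ", f, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(sc$shape)
  if (length(pages) != d[3] || !all(dim(pages[[1]]) == d[1:2]))
    stop(sprintf(
      "shape mismatch: sidecar says %s, TIFF holds %d pages of %s",
      paste(d, collapse = "x"), length(pages),
      paste(dim(pages[[1]]), collapse = "x")), call. = FALSE)
  arr <- array(NA_real_, d)
  for (b in seq_len(d[3]))
    arr[, , b] <- pages[[b]] * sc$affine$scale + sc$affine$offset
  oct_volume(arr, axial_pitch = as.numeric(sc$axial_pitch),
             lateral_pitch = as.numeric(sc$lateral_pitch),
             scale = sc$scale, source_id = sc$source_id)
}

#' Annotate a rectangular air or muscle region of a volume
#'
#' Bounds are 0-based half-open index ranges `[from, to)` along the axial,
#' lateral (A-scan) and B-scan axes, matching the on-disk JSON convention;
#' axial index 0 is the shallowest pixel.
#'
#' @param volume_id id of the annotated volume.
#' @param region `"air"` or `"muscle"`.
#' @param axial,lateral,bscan integer length-2 half-open ranges.
#' @return A `region_annotation` object.
#' @export
region_annotation <- function(volume_id, region, axial, lateral, bscan) {
  region <- match.arg(region, c("air", "muscle"))
  for (r in list(axial, lateral, bscan))
    stopifnot(length(r) == 2, r[1] >= 0, r[2] > r[1])
  structure(list(volume_id = volume_id, region = region,
                 axial = as.integer(axial), lateral = as.integer(lateral),
                 bscan = as.integer(bscan)),
            class = "region_annotation")
}

# Extract the annotated voxels of a volume as a numeric vector.
annotation_voxels <- function(vol, ann) {
  d <- dim(vol$intensity)
  if (ann$axial[2] > d[1] || ann$lateral[2] > d[2] || ann$bscan[2] > d[3])
    stop("annotation bounds exceed volume shape", call. = FALSE)
  as.vector(vol$intensity[(ann$axial[1] + 1):ann$axial[2],
                          (ann$lateral[1] + 1):ann$lateral[2],
                          (ann$bscan[1] + 1):ann$bscan[2]])
}

#' Write / read region annotations as JSON
#'
#' @param annotations list of [region_annotation()]s.
#' @param path JSON file path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   returns a list of [region_annotation()]s.
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(annotations, unclass)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    region_annotation(r$volume_id, r$region,
                      axial = unlist(r$axial), lateral = unlist(r$lateral),
                      bscan = unlist(r$bscan)))
}

.groups <- c("control", "uvr_control", "uvr_nmn", "uvr_pl")
.sites <- c("back", "side", "stomach")

#' Read a study design table
#'
#' CSV with header columns `mouse_id`, `group`, `site`, `month`,
#' `volume_path`. Group labels must be one of control, uvr_control, uvr_nmn,
#' uvr_pl; sites one of back, side, stomach; months integers in 0..7;
#' duplicate (mouse, site, month) rows are rejected.
#'
#' @param path CSV file path.
#' @return `data.frame` of study records (possibly zero rows).
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mouse_id", "group", "site", "month", "volume_path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("study table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(df[required])
  bad_g <- setdiff(unique(df$group), .groups)
  if (length(bad_g))
    stop(sprintf("unknown group label(s) %s; allowed: %s",
                 paste(bad_g, collapse = ", "),
                 paste(.groups, collapse = ", ")), call. = FALSE)
  bad_s <- setdiff(unique(df$site), .sites)
  if (length(bad_s))
    stop(sprintf("unknown site label(s) %s; allowed: %s",
                 paste(bad_s, collapse = ", "),
                 paste(.sites, collapse = ", ")), call. = FALSE)
  if (!all(df$month == as.integer(df$month)) ||
      any(df$month < 0) || any(df$month > 7))
    stop("month must be an integer in 0..7", call. = FALSE)
  key <- paste(df$mouse_id, df$site, df$month)
  if (anyDuplicated(key))
    stop("duplicate study records (same mouse/site/month): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  df[required]
}

#' @rdname read_study_table
#' @param table data.frame of study records.
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
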