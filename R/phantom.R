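#' Describe one layer of the skin phantom
#'
#' A layer is characterised by its thickness, its mean backscatter amplitude at
#' the layer top (linear units), and an exponential attenuation rate applied
#' with depth inside the layer. The air layer is the standoff above the skin
#' surface: its reflectivity is the noise-floor amplitude and its attenuation
#' must be zero.
#'
#' @param name one of `"air"`, `"epidermis"`, `"dermis"`, `"muscle"`.
#' @param thickness layer thickness in micrometres (> 0).
#' @param reflectivity mean linear backscatter amplitude at the layer top
#'   (>= 0; must be > 0 to be renderable on a log scale).
#' @param attenuation decay rate within the layer, in mm^-1 (>= 0).
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(name, thickness, reflectivity, attenuation) {
  name <- match.arg(name, c("air", "epidermis", "dermis", "muscle"))
  stopifnot(is.numeric(thickness), length(thickness) == 1, thickness > 0,
            is.numeric(reflectivity), length(reflectivity) == 1, reflectivity >= 0,
            is.numeric(attenuation), length(attenuation) == 1, attenuation >= 0)
  if (name == "air" && attenuation != 0)
    stop("air layer must have attenuation 0", call. = FALSE)
  structure(list(name = name, thickness = thickness,
                 reflectivity = reflectivity, attenuation = attenuation),
            class = "layer_spec")
}

#' Default four-layer skin phantom stack
#'
#' Amplitudes are arbitrary linear units; the tissue/noise-floor contrast and
#' the flat muscle plateau are chosen so that the global-threshold
#' muscle-boundary rule lands at the dermis-muscle interface (see the methods
#' vignette). The dermal attenuation default of 40 mm^-1 is a baseline-like
#' value; around 25 mm^-1 is typical of heavily UV-exposed skin.
#'
#' @param dermis_attenuation dermal attenuation coefficient, mm^-1.
#' @param dermis_thickness dermis thickness, micrometres.
#' @param epidermis_thickness epidermis thickness, micrometres.
#' @param air_standoff air gap above the surface, micrometres.
#' @param muscle_thickness rendered muscle depth, micrometres.
#' @return List of four [layer_spec()] objects (air, epidermis, dermis, muscle).
#' @export
default_skin_layers <- function(dermis_attenuation = 40,
                                dermis_thickness = 400,
                                epidermis_thickness = 20,
                                air_standoff = 100,
                                muscle_thickness = 160) {
  list(
    layer_spec("air",       air_standoff,        1e-9, 0),
    layer_spec("epidermis", epidermis_thickness, 0.6,  15),
    layer_spec("dermis",    dermis_thickness,    1.0,  dermis_attenuation),
    layer_spec("muscle",    muscle_thickness,    4e-9, 0)
  )
}

#' Specify a layered-skin OCT phantom
#'
#' Geometry defaults mirror a 6 x 6 mm VivoSight-style acquisition: 1355
#' A-scans per B-scan, 120 B-scans, 4.4 um lateral A-scan spacing. The axial
#' pixel pitch defaults to 4 um (the instrument's axial resolution is ~5.5 um;
#' its pixel pitch is not public, so this is a free simulator parameter).
#'
#' @param layers ordered list of [layer_spec()]s: air, epidermis, dermis, muscle.
#' @param axial_pitch axial micrometres per pixel (> 0).
#' @param n_ascans_per_bscan,n_bscans lateral volume dimensions (>= 1).
#' @param lateral_pitch micrometres per A-scan.
#' @param speckle_shape shape parameter of the unit-mean gamma multiplicative
#'   speckle on linear amplitude; larger is less noisy; `Inf` disables speckle.
#' @param thickness_jitter standard deviation (um) of the smooth lateral
#'   variation applied independently to each tissue interface; fields are
#'   truncated at 4 standard deviations.
#' @param seed integer RNG seed used by [generate_volume()]; `NULL` uses the
#'   ambient RNG state.
#' @param n_axial number of axial pixels; default fits the layer stack exactly.
#' @param spike_factor interface reflections are rendered as one-pixel peaks of
#'   `spike_factor` times the underlying layer reflectivity.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(layers = default_skin_layers(),
                         axial_pitch = 4,
                         n_ascans_per_bscan = 1355,
                         n_bscans = 120,
                         lateral_pitch = 4.4,
                         speckle_shape = 16,
                         thickness_jitter = 10,
                         seed = NULL,
                         n_axial = NULL,
                         spike_factor = 2) {
  stopifnot(is.list(layers), length(layers) == 4,
            all(vapply(layers, inherits, logical(1), "layer_spec")),
            axial_pitch > 0, n_ascans_per_bscan >= 1, n_bscans >= 1,
            lateral_pitch > 0, speckle_shape > 0, thickness_jitter >= 0,
            spike_factor > 0)
  nm <- vapply(layers, `[[`, character(1), "name")
  if (!identical(nm, c("air", "epidermis", "dermis", "muscle")))
    stop("layers must be exactly air, epidermis, dermis, muscle (shallow to deep)",
         call. = FALSE)
  total <- sum(vapply(layers, `[[`, numeric(1), "thickness"))
  if (is.null(n_axial)) n_axial <- as.integer(ceiling(total / axial_pitch))
  if (n_axial * axial_pitch < total)
    stop(sprintf("layer stack (%g um) deeper than axial window (%g um)",
                 total, n_axial * axial_pitch), call. = FALSE)
  structure(list(layers = layers, axial_pitch = axial_pitch,
                 n_ascans_per_bscan = as.integer(n_ascans_per_bscan),
                 n_bscans = as.integer(n_bscans),
                 lateral_pitch = lateral_pitch,
                 speckle_shape = speckle_shape,
                 thickness_jitter = thickness_jitter,
                 seed = seed, n_axial = as.integer(n_axial),
                 spike_factor = spike_factor),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %d x %d x %d (axial x A-scan x B-scan), pitch %g um\n",
              x$n_axial, x$n_ascans_per_bscan, x$n_bscans, x$axial_pitch))
  for (l in x$layers)
    cat(sprintf("  %-9s %6g um  A0=%g  mu=%g mm^-1\n",
                l$name, l$thickness, l$reflectivity, l$attenuation))
  invisible(x)
}

# 1-based axial pixel index of the shallowest sample at or below depth d (um).
interface_pixel <- function(d, axial_pitch) {
  as.integer(ceiling(d / axial_pitch - 1e-9)) + 1L
}

# Render a matrix of A-scans (axial x n_columns) given per-column interface
# depths (3 x n_columns: surface, DEJ, muscle top, um). Speckle is drawn from
# the ambient RNG stream. Returns log-amplitude (natural log).
render_ascans <- function(spec, depth_mat) {
  n_ax <- spec$n_axial
  n_col <- ncol(depth_mat)
  p <- spec$axial_pitch
  z <- (seq_len(n_ax) - 1) * p                      # um
  max_depth <- z[n_ax]
  labels <- c("surface (epidermis top)", "DEJ (dermis top)", "muscle top")
  for (k in 1:3) {
    bad <- depth_mat[k, ] <= 0 | depth_mat[k, ] > max_depth
    if (any(bad))
      stop(sprintf("interface out of axial range: %s (depth %g um, window %g um)",
                   labels[k], depth_mat[k, which(bad)[1]], max_depth),
           call. = FALSE)
  }
  if (any(diff(depth_mat) <= 0))
    stop("interface depths must be strictly increasing (surface < DEJ < muscle)",
         call. = FALSE)
  tissue <- spec$layers[2:4]
  if (spec$layers[[1]]$reflectivity <= 0)
    stop("air reflectivity (noise-floor amplitude) must be > 0 to render on a log scale",
         call. = FALSE)
  amp <- matrix(spec$layers[[1]]$reflectivity, n_ax, n_col)
  zc <- matrix(z, n_ax, n_col)
  for (k in 1:3) {
    top <- matrix(depth_mat[k, ], n_ax, n_col, byrow = TRUE)
    m <- zc >= top
    lay <- tissue[[k]]
    if (lay$reflectivity <= 0)
      stop(sprintf("layer %s reflectivity must be > 0 to render on a log scale",
                   lay$name), call. = FALSE)
    amp[m] <- lay$reflectivity * exp(-lay$attenuation * (zc[m] - top[m]) / 1000)
  }
  for (k in 1:3) {
    ip <- interface_pixel(depth_mat[k, ], p)
    amp[cbind(ip, seq_len(n_col))] <- spec$spike_factor * tissue[[k]]$reflectivity
  }
  if (is.finite(spec$speckle_shape))
    amp <- amp * rgamma(length(amp), shape = spec$speckle_shape,
                        rate = spec$speckle_shape)
  log(amp)
}

#' Generate a single synthetic A-scan
#'
#' Renders one depth profile of the phantom: piecewise
#' `A0 * exp(-mu * (z - z_top))` linear amplitude below each interface, a
#' one-pixel reflection spike at each tissue interface, multiplicative gamma
#' speckle, and a natural-log transform. Speckle draws come from the ambient
#' RNG stream (seed it with [set.seed()] for reproducibility).
#'
#' @param spec a [phantom_spec()].
#' @param interface_depths numeric length 3: depths (um) of the skin surface,
#'   the dermal-epidermal junction and the muscle top; strictly increasing and
#'   within the axial window.
#' @return Numeric vector of `spec$n_axial` log-amplitude values.
#' @export
generate_ascan <- function(spec, interface_depths) {
  stopifnot(inherits(spec, "phantom_spec"),
            is.numeric(interface_depths), length(interface_depths) == 3)
  drop(render_ascans(spec, matrix(interface_depths, 3, 1)))
}

# Linear-interpolation weight matrix mapping c control points to n positions.
lin_weights <- function(n, c) {
  if (c == 1) return(matrix(1, n, 1))
  p <- seq(1, c, length.out = n)
  i0 <- pmin(floor(p), c - 1)
  fr <- p - i0
  w <- matrix(0, n, c)
  w[cbind(seq_len(n), i0)] <- 1 - fr
  w[cbind(seq_len(n), i0 + 1)] <- fr
  w
}

# Smooth lateral random field: coarse iid Gaussian grid, truncated at +-clamp,
# bilinearly upsampled to nx x ny.
smooth_field <- function(nx, ny, sd, clamp = 4 * sd) {
  if (sd == 0) return(matrix(0, nx, ny))
  cx <- max(2, ceiling(nx / 64) + 1)
  cy <- max(2, ceiling(ny / 16) + 1)
  g <- matrix(pmin(pmax(rnorm(cx * cy, 0, sd), -clamp), clamp), cx, cy)
  lin_weights(nx, cx) %*% g %*% t(lin_weights(ny, cy))
}

#' Generate a full phantom OCT volume with ground truth
#'
#' Each tissue interface receives an independent smooth lateral jitter field
#' (sd `thickness_jitter`, truncated at 4 sd); layer ordering is preserved by
#' enforcing minimum gaps (8 um epidermis, 40 um dermis). The realised
#' per-position interface depths and the dermal attenuation are recorded as
#' ground truth.
#'
#' @param spec a [phantom_spec()]. If `spec$seed` is set the volume is
#'   bit-reproducible; the ambient RNG state is restored on exit.
#' @return List with elements `volume` (an [oct_volume()]) and `truth` (a
#'   `ground_truth` object with per-position `surface_depth`, `dej_depth`,
#'   `muscle_depth`, `skin_thickness` matrices in um and scalar
#'   `dermal_attenuation` in mm^-1).
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
  }
  th <- vapply(spec$layers, `[[`, numeric(1), "thickness")
  nominal <- cumsum(th)[1:3]              # surface, DEJ, muscle-top depths
  nx <- spec$n_ascans_per_bscan
  ny <- spec$n_bscans
  j <- spec$thickness_jitter
  surf <- nominal[1] + smooth_field(nx, ny, j)
  dej  <- nominal[2] + smooth_field(nx, ny, j)
  musc <- nominal[3] + smooth_field(nx, ny, j)
  dej  <- pmax(dej, surf + 8)
  musc <- pmax(musc, dej + 40)
  vol <- array(NA_real_, c(spec$n_axial, nx, ny))
  for (b in seq_len(ny)) {
    depths <- rbind(surf[, b], dej[, b], musc[, b])
    vol[, , b] <- render_ascans(spec, depths)
  }
  truth <- structure(list(surface_depth = surf, dej_depth = dej,
                          muscle_depth = musc,
                          dermal_attenuation = spec$layers[[3]]$attenuation,
                          skin_thickness = musc - surf),
                     class = "ground_truth")
  volume <- oct_volume(vol, axial_pitch = spec$axial_pitch,
                       lateral_pitch = spec$lateral_pitch,
                       scale = "ln_amplitude",
                       source_id = sprintf("phantom(seed=%s)",
                                           if (is.null(spec$seed)) "ambient" else spec$seed))
  list(volume = volume, truth = truth)
}
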