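#' Expected metric trajectories for a simulated study
#'
#' Returns the per-group, per-site, per-month expected value of a metric,
#' interpolated linearly between a common baseline and a month-7 target. The
#' defaults emulate a photodamage study: dermal attenuation starts around
#' 41.5 mm^-1 everywhere (baseline-like) and falls towards the low twenties
#' in UV-exposed groups, while combined epidermis+dermis thickness starts
#' near 420 um and grows by up to ~120 um under UV exposure. Sites receive
#' different fractions of the group effect (the back is most exposed); the
#' `site_weight` arguments scale the baseline-to-target change.
#'
#' @param metric `"mu_mm_inv"` or `"thickness_um"`.
#' @param baseline common baseline value (all groups, month 0).
#' @param month7_targets named numeric: month-7 expected value per group at a
#'   fully exposed site.
#' @param site_weight named numeric: fraction of the group effect realised at
#'   each site.
#' @param months integer vector of months covered.
#' @return 3-D numeric array indexed `[group, site, month]` (dimnames set;
#'   month index is `as.character(month)`).
#' @export
study_effect_profile <- function(metric = c("mu_mm_inv", "thickness_um"),
                                 baseline = NULL, month7_targets = NULL,
                                 site_weight = c(back = 1, side = 0.6,
                                                 stomach = 0.2),
                                 months = 0:7) {
  metric <- match.arg(metric)
  if (is.null(baseline))
    baseline <- switch(metric, mu_mm_inv = 41.5, thickness_um = 420)
  if (is.null(month7_targets))
    month7_targets <- switch(metric,
      mu_mm_inv = c(control = 40, uvr_control = 22, uvr_nmn = 27, uvr_pl = 25),
      thickness_um = c(control = 420, uvr_control = 540, uvr_nmn = 500,
                       uvr_pl = 510))
  stopifnot(all(.groups %in% names(month7_targets)),
            all(.sites %in% names(site_weight)))
  arr <- array(NA_real_, c(length(.groups), length(.sites), length(months)),
               dimnames = list(.groups, .sites, as.character(months)))
  for (g in .groups) for (s in .sites) for (i in seq_along(months)) {
    frac <- months[i] / 7
    delta <- (month7_targets[[g]] - baseline) * site_weight[[s]]
    arr[g, s, i] <- baseline + frac * delta
  }
  arr
}

#' Simulate per-volume metric values for a study design
#'
#' Draws one metric value per (mouse, group, site, month): the expected
#' trajectory plus a per-mouse random intercept (biological variability
#' shared across that mouse's sites and months) plus independent
#' measurement noise (the per-volume estimation error of the imaging
#' pipeline). Draws come from the ambient RNG stream.
#'
#' @param metric `"mu_mm_inv"` or `"thickness_um"`.
#' @param effects trajectory array from [study_effect_profile()]; its month
#'   dimnames define the months simulated.
#' @param n_mice mice per group (default 6).
#' @param mouse_sd between-mouse standard deviation (default 3 mm^-1 for
#'   attenuation, 25 um for thickness).
#' @param noise_sd per-volume measurement noise (default 0.5 mm^-1 / 6 um).
#' @return A [metric_series()].
#' @export
simulate_metric_series <- function(metric = c("mu_mm_inv", "thickness_um"),
                                   effects = study_effect_profile(metric),
                                   n_mice = 6, mouse_sd = NULL,
                                   noise_sd = NULL) {
  metric <- match.arg(metric)
  if (is.null(mouse_sd))
    mouse_sd <- switch(metric, mu_mm_inv = 3, thickness_um = 25)
  if (is.null(noise_sd))
    noise_sd <- switch(metric, mu_mm_inv = 0.5, thickness_um = 6)
  months <- as.integer(dimnames(effects)[[3]])
  recs <- expand.grid(mouse = seq_len(n_mice), group = .groups,
                      site = .sites, month = months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  recs$mouse_id <- sprintf("%s_m%d", recs$group, recs$mouse)
  mice <- unique(recs$mouse_id)
  intercept <- stats::setNames(rnorm(length(mice), 0, mouse_sd), mice)
  mu <- effects[cbind(recs$group, recs$site, as.character(recs$month))]
  recs$value <- mu + intercept[recs$mouse_id] +
    rnorm(nrow(recs), 0, noise_sd)
  metric_series(metric, recs[c("mouse_id", "group", "site", "month", "value")])
}
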