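# Small phantom and calibration fixtures built in code.

small_spec <- function(mu = 30, n_ascans = 200, n_bscans = 10, seed = 1,
                       speckle_shape = 16, thickness_jitter = 10, ...) {
  phantom_spec(default_skin_layers(dermis_attenuation = mu),
               n_ascans_per_bscan = n_ascans, n_bscans = n_bscans,
               speckle_shape = speckle_shape,
               thickness_jitter = thickness_jitter, seed = seed, ...)
}

noiseless_spec <- function(mu = 30, n_ascans = 50, n_bscans = 2, seed = 1, ...) {
  small_spec(mu = mu, n_ascans = n_ascans, n_bscans = n_bscans, seed = seed,
             speckle_shape = Inf, thickness_jitter = 0, ...)
}

# Generate a volume and calibrate it from its own ground-truth annotations.
phantom_with_cal <- function(spec, window = 10) {
  gen <- generate_volume(spec)
  ann <- octskin:::truth_annotations(gen$truth, gen$volume, "fixture")
  cal <- calibrate(list(list(volume = gen$volume, annotations = ann)),
                   window = window)
  c(gen, list(cal = cal))
}

# Full imaging-pipeline metrics for one phantom volume.
phantom_metrics <- function(spec, window = 10, n_trim = 15) {
  px <- phantom_with_cal(spec, window = window)
  avg <- preprocess_volume(px$volume, window = window, n_trim = n_trim)
  seg <- segment_volume(avg, px$cal)
  list(truth = px$truth, seg = seg,
       thickness = measure_thickness(seg, px$volume$axial_pitch),
       attenuation = measure_attenuation(avg, seg, px$volume$axial_pitch))
}
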