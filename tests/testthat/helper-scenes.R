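# Small scene builders shared across tests. Unit tests use few vesicles and
# small fields so the suite stays fast; study-scale scenes live in the
# fixture registry and are exercised in the acceptance tests.

tiny_kinetics <- function(...) {
  kinetic_params(lag_min = 10, rate_au_per_min = 5, plateau_au = 600,
                 baseline_max_au = 100, baseline_tau_min = 5, ...)
}

# crisp, noise-free scene: the forward-model oracle configuration
noiseless_scene <- function(n_guvs = 4, seed = 11, ...) {
  simulation_scene(image_shape = c(160, 160), pixel_size_um = 0.25,
                   n_guvs = n_guvs, radius_range_um = c(3, 5),
                   psf_sigma_um = 0, photon_gain = Inf, read_noise_sd = 0,
                   kinetics = tiny_kinetics(), seed = seed, ...)
}

noisy_scene <- function(n_guvs = 4, seed = 12, ...) {
  simulation_scene(image_shape = c(160, 160), pixel_size_um = 0.25,
                   n_guvs = n_guvs, radius_range_um = c(3, 5),
                   psf_sigma_um = 0, photon_gain = 50, read_noise_sd = 1,
                   kinetics = tiny_kinetics(), seed = seed, ...)
}

# rasterized annulus helper (independent of the simulator internals)
raster_annulus <- function(shape, center_px, radius_px, half_width_px) {
  d <- sqrt(outer((seq_len(shape[1]) - center_px[1])^2,
                  (seq_len(shape[2]) - center_px[2])^2, `+`))
  abs(d - radius_px) <= half_width_px
}
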