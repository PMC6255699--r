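# Small shared fixtures: test-scale render parameters and a quick scan pair.

test_render_params <- function(field_um = 120, noise_sd = 5, ...) {
  field_render_params(field_um, gaussian_noise_sd = noise_sd, ...)
}

# A seeded scan pair with a known number of conduits at a given potential.
make_test_pair <- function(n = 20, psi = -3, b = -2.87, S = 40, seed = 42,
                           field_um = 120, noise_sd = 5,
                           area_mean = 96, area_sd = 66) {
  pop <- sample_conduit_population(n, area_mean, area_sd, field_um = field_um,
                                   seed = seed)
  pop <- assign_embolism_thresholds(pop, b, S, seed = seed + 1)
  render_scan_pair(pop, psi, test_render_params(field_um, noise_sd),
                   seed = seed + 2)
}

# Rasterised-disk pixel-count oracle: number of pixel centres inside a disk,
# computed by brute-force enumeration (independent of the renderer).
disk_pixel_area <- function(cx_um, cy_um, r_um, px = 0.65, n_px = 200) {
  centers <- (seq_len(n_px) - 0.5) * px
  sum(outer((centers - cy_um)^2, (centers - cx_um)^2, `+`) <= r_um^2) * px^2
}
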