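# Small-scale fixtures: an 8 mm isotropic 20x20x8 phantom keeps unit tests
# fast while preserving all tissue classes and room for lesions/cavities.

small_profile <- function(n_pairs = 4L, noise_sd = 5, bias = 0,
                          field_strength = 1.5, name = "mini") {
  scanner_profile(name, field_strength, n_pairs,
                  grid = c(20L, 20L, 8L), voxel_size = c(8, 8, 8),
                  noise_sd = noise_sd, bias_field_amplitude = bias)
}

small_spec <- function(...) {
  phantom_spec(grid = c(20L, 20L, 8L), voxel_size = c(8, 8, 8),
               head_semiaxes = c(60, 65, 28), gm_thickness = 12, ...)
}

small_params <- function(field_strength = 1.5) {
  quant_params(t1_blood = t1_blood_for_field(field_strength))
}

# Build an asl_series by hand from explicit volumes (control-first).
manual_series <- function(vols, m0, profile = NULL, p = small_params(),
                          order = "control_first") {
  if (is.null(profile))
    profile <- scanner_profile("manual", 1.5, dim(vols)[4] / 2,
                               grid = dim(vols)[1:3],
                               voxel_size = c(1, 1, 1))
  structure(list(volumes = vols, m0 = m0, profile = profile, params = p,
                 order = order, seed = 0L),
            class = "asl_series")
}
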