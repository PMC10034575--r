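# Small in-code fixtures shared across test files.

iso1 <- c(1, 1, 1)

uniform_grid <- function(dose = 60, shape = c(10, 10, 10), spacing = iso1) {
  dose_grid(array(dose, dim = shape), spacing)
}

full_mask <- function(shape = c(10, 10, 10), spacing = iso1, label = "CTV") {
  structure_mask(array(TRUE, dim = shape), label, spacing)
}

# half the voxels at `hi`, half at `lo`, split along x
two_level_grid <- function(hi = 60, lo = 40, shape = c(10, 10, 10),
                           spacing = iso1) {
  v <- array(lo, dim = shape)
  v[seq_len(shape[1] / 2), , ] <- hi
  dose_grid(v, spacing)
}

random_dose_grid <- function(shape = c(8, 8, 8), spacing = iso1,
                             max_gy = 60) {
  dose_grid(array(stats::runif(prod(shape), 0.5, max_gy), dim = shape),
            spacing)
}

# A tiny but complete synthetic series for plumbing tests.
tiny_series <- function(n_fractions = 3, seed = 11, drift = 2, amp = 1,
                        shape = c(24, 24, 24), spacing = c(4, 4, 4),
                        margin = 5) {
  cfg <- sim_config(grid_shape = shape, spacing_mm = spacing,
                    ctv_semiaxes_mm = c(16, 14, 14),
                    n_fractions = n_fractions, drift_sd_mm = drift,
                    deform_amp_mm = amp, margin_mm = margin, seed = seed)
  simulate_series(cfg)
}
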