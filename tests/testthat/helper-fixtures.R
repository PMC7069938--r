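# Shared fixtures: small geometries keep unit tests fast; the acceptance
# tests build the full study conditions themselves.

tiny_probe <- function(n = 8) make_linear_probe(n, 100e-6)

tiny_grid <- function() {
  make_grid(-50e-6, 50e-6, 14.95e-3, 15.05e-3, 25e-6) # 5 x 5 = 25 points
}

default_pulse <- function() make_pulse(15e6, 0.93, 62.5e6)

# heavily oversampled pulse: the sampled waveform is band-limited to
# numerical precision, so frequency-domain fractional delays are exact
fine_pulse <- function() make_pulse(15e6, 0.93, 250e6)

tiny_model <- function(pulse = fine_pulse(), probe = tiny_probe(),
                       grid = tiny_grid(), modality = "PA") {
  sub <- select_elements(probe, probe$n_elements, "all")
  win <- grid_time_window(probe, sub, grid, pulse, modality)
  psf <- simulate_psf(probe, sub, pulse, 0, 15e-3, modality, 1500, win)
  list(model = build_matrix(psf, grid), psf = psf, subset = sub,
       window = win, probe = probe, grid = grid, pulse = pulse)
}

# lateral profile of a matrix image through its global maximum row
expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
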