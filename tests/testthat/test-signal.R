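test_that("pulse spectrum peaks at the center frequency and is normalized", {
  p <- make_pulse(15e6, 0.6, 62.5e6)
  w <- p$waveform$amplitude
  spec <- Mod(stats::fft(w))[seq_len(length(w) %/% 2)]
  freqs <- (seq_along(spec) - 1) / length(w) * p$fs
  expect_lt(abs(freqs[which.max(spec)] - 15e6), p$fs / length(w) + 1e-9)
  expect_equal(max(envelope(w)), 1, tolerance = 2e-3)
  expect_equal(max(abs(p$waveform$amplitude)), 1)
  expect_error(make_pulse(15e6, 0.6, 20e6), class = "sparsus_error_sampling")
})

test_that("RF synthesis places envelope peaks at the time of flight", {
  probe <- make_linear_probe(65, 100e-6) # odd count: element 33 on axis
  sub <- select_elements(probe, probe$n_elements, "all")
  pulse <- default_pulse()
  src <- source_set(0, 15e-3)

  rf_pa <- synthesize_rf(src, probe, sub, pulse, "PA", 1500)
  k <- 33 # element at x = 0
  env <- envelope(rf_pa$samples[, k])
  t_peak <- rf_times(rf_pa)[which.max(env)]
  expect_lt(abs(t_peak - 10e-6), 0.5 / pulse$fs)

  rf_us <- synthesize_rf(src, probe, sub, pulse, "US_planewave", 1500)
  env_us <- envelope(rf_us$samples[, k])
  t_peak_us <- rf_times(rf_us)[which.max(env_us)]
  expect_lt(abs(t_peak_us - 20e-6), 0.5 / pulse$fs)

  # linearity: two unit sources at one point = 2 x single source
  two <- source_set(c(0, 0), c(15e-3, 15e-3))
  rf2 <- synthesize_rf(two, probe, sub, pulse, "PA", 1500,
                       window = c(rf_pa$t0, max(rf_times(rf_pa))))
  expect_equal(rf2$samples, 2 * rf_pa$samples, tolerance = 1e-12)

  expect_error(
    synthesize_rf(src, probe, sub, pulse, "PA", 1500,
                  window = c(9.99e-6, 10.01e-6)),
    class = "sparsus_error_truncation"
  )
})

test_that("axial source shifts move envelope peaks by dz/c (PA) or 2 dz/c (US)", {
  probe <- make_linear_probe(9, 100e-6)
  sub <- select_elements(probe, 9, "all")
  pulse <- default_pulse()
  dz <- 40e-6
  for (mod in c("PA", "US_planewave")) {
    factor <- if (mod == "PA") 1 else 2
    win <- c(if (mod == "PA") 9.5e-6 else 19.5e-6,
             if (mod == "PA") 10.8e-6 else 20.8e-6)
    rf_a <- synthesize_rf(source_set(0, 15e-3), probe, sub, pulse, mod, 1500, win)
    rf_b <- synthesize_rf(source_set(0, 15e-3 + dz), probe, sub, pulse, mod,
                          1500, win)
    for (k in c(1, 5, 9)) {
      ta <- rf_times(rf_a)[which.max(envelope(rf_a$samples[, k]))]
      tb <- rf_times(rf_b)[which.max(envelope(rf_b$samples[, k]))]
      # one-way path difference at an off-axis element is slightly below dz/c
      expected <- if (mod == "PA") {
        (sqrt(probe$element_x[k]^2 + (15e-3 + dz)^2) -
           sqrt(probe$element_x[k]^2 + 15e-3^2)) / 1500
      } else {
        dz / 1500 + (sqrt(probe$element_x[k]^2 + (15e-3 + dz)^2) -
                       sqrt(probe$element_x[k]^2 + 15e-3^2)) / 1500
      }
      # both peak times are quantized to the sample grid: allow one sample
      expect_lt(abs((tb - ta) - expected), 1.01 / pulse$fs)
      if (k == 5) expect_rel_equal(expected, factor * dz / 1500, 1e-3)
    }
  }
})

test_that("noise injection has the requested rms and is reproducible", {
  probe <- make_linear_probe(16, 100e-6)
  sub <- select_elements(probe, 16, "all")
  rf <- synthesize_rf(source_set(0, 15e-3), probe, sub, default_pulse(), "PA")
  rf$samples <- matrix(0, 2000, 16) # large zero record

  expect_identical(add_noise(rf, 0, 1)$samples, rf$samples)

  noisy <- add_noise(rf, 30, seed = 42)
  expect_lt(abs(stats::sd(noisy$samples - rf$samples) - 30) / 30, 0.02)
  expect_identical(noisy$samples, add_noise(rf, 30, seed = 42)$samples)
  expect_false(identical(noisy$samples, add_noise(rf, 30, seed = 43)$samples))
})

test_that("SNR is peak amplitude over signal-free noise deviation", {
  probe <- make_linear_probe(16, 100e-6)
  sub <- select_elements(probe, 16, "all")
  rf <- synthesize_rf(source_set(0, 15e-3), probe, sub, default_pulse(), "PA",
                      1500, window = c(9.0e-6, 10.7e-6))
  rf$samples <- rf$samples * 4500
  # the first ~40 samples precede every arrival: signal-free
  free <- 1:40
  expect_lt(max(abs(rf$samples[free, ])), 1e-6)
  noisy <- add_noise(rf, 30, seed = 5)
  snr <- measure_snr(noisy, free)
  expect_lt(abs(snr - 150) / 150, 0.1)

  rf_zero <- rf
  rf_zero$samples[free, ] <- 0
  expect_equal(measure_snr(rf_zero, free), Inf)

  # SNR scales linearly with signal amplitude at fixed noise
  noisy2 <- rf
  noisy2$samples <- 2 * rf$samples + (noisy$samples - rf$samples)
  expect_rel_equal(measure_snr(noisy2, free), 2 * snr, 0.05)
})

test_that("envelope is the analytic-signal magnitude", {
  t <- seq(0, 1, length.out = 512)
  x <- 3 * cos(2 * pi * 25 * t)
  env <- envelope(x)
  interior <- 50:462
  expect_lt(max(abs(env[interior] - 3)), 0.03)
  expect_equal(envelope(-x), env, tolerance = 1e-12)
  expect_true(all(env >= 0))

  p <- default_pulse()
  w <- p$waveform
  expect_equal(w$t[which.max(envelope(w$amplitude))], 0, tolerance = 1 / p$fs)
})

test_that("lateral FWHM matches closed forms and flags bad profiles", {
  g <- make_grid(-500e-6, 500e-6, 0, 0, 12.5e-6)
  sg <- 66e-6
  img <- matrix(exp(-g$x^2 / (2 * sg^2)), nrow = 1)
  expect_rel_equal(lateral_fwhm(img, g), 2 * sqrt(2 * log(2)) * sg, 0.01)

  spike <- matrix(0, 1, g$n_x)
  spike[1, 41] <- 1
  expect_lte(lateral_fwhm(spike, g), 12.5e-6 + 1e-12)

  flat <- matrix(1.5, 2, g$n_x) # never falls below half of the peak value 2
  flat[1, 10] <- 2
  expect_error(lateral_fwhm(flat, g), class = "sparsus_error_fwhm")
})
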