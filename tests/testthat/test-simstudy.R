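# a small, fast study configuration shared by the tests below
fast_cfg <- function(N_values = c(4, 16), snr_values = c(5, 150),
                     n_realizations = 3) {
  sweep_config(
    N_values = N_values, snr_values = snr_values,
    n_realizations = n_realizations,
    base_seed = 7,
    probe = make_linear_probe(32, 100e-6),
    grid = make_grid(-200e-6, 200e-6, 14.975e-3, 15.025e-3, 12.5e-6),
    scene = microchannel_scene(3),
    solver_max_iters = 600, solver_tolerance = 1e-7
  )
}

test_that("per-cell seeds are splittable, distinct and below 2^31", {
  seeds <- outer(c(2, 16, 128), 0:50,
                 function(N, r) mapply(sparsus:::cell_seed, 1, N, r))
  expect_equal(anyDuplicated(as.vector(seeds)), 0L)
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_identical(sparsus:::cell_seed(1, 16, 3), sparsus:::cell_seed(1, 16, 3))
})

test_that("a single cell run is deterministic and self-consistent", {
  cfg <- fast_cfg()
  ctx <- simstudy_context(cfg)
  r1 <- run_cell(16, 150, cfg, realization = 1L, ctx = ctx)
  r2 <- run_cell(16, 150, cfg, realization = 1L, ctx = ctx)
  expect_identical(r1$C, r2$C)
  expect_identical(r1$recon$T_hat, r2$recon$T_hat)
  expect_gte(r1$C, 0)
  expect_lte(r1$C, 1)

  # zero signal amplitude: pure noise, no information
  r0 <- run_cell(16, 1e-6, cfg, realization = 1L, ctx = ctx)
  expect_lt(r0$C, 0.5)
})

test_that("the sweep reproduces run_cell and is bit-reproducible", {
  cfg <- fast_cfg(N_values = 16, snr_values = 150, n_realizations = 2)
  sw <- run_sweep(cfg)
  expect_equal(nrow(sw$records), 2)
  expect_equal(nrow(sw$mean_C), 1)
  expect_true(all(sw$mean_C$mean_C >= 0 & sw$mean_C$mean_C <= 1))

  # cell consistency: the same alpha and seed give the same C
  ctx <- simstudy_context(cfg)
  direct <- run_cell(16, 150, cfg, realization = 1L,
                     alpha = sw$mean_C$alpha[1], ctx = ctx)
  expect_identical(direct$C, sw$records$C[sw$records$realization == 1])

  sw2 <- run_sweep(cfg)
  expect_identical(sw$records, sw2$records)
  expect_identical(sw$mean_C, sw2$mean_C)

  gl <- glance(sw)
  expect_equal(gl$n_cells, 1)
  expect_identical(tidy(sw), sw$records)
})

test_that("noise realizations are shared along the SNR axis at fixed N", {
  cfg <- fast_cfg()
  expect_identical(sparsus:::cell_seed(cfg$base_seed, 16, 1),
                   sparsus:::cell_seed(cfg$base_seed, 16, 1))
  # the seed does not depend on the SNR value by construction
  s_low <- run_cell(16, 5, cfg, realization = 2L,
                    ctx = simstudy_context(cfg))$seed
  s_high <- run_cell(16, 150, cfg, realization = 2L,
                     ctx = simstudy_context(cfg))$seed
  expect_identical(s_low, s_high)
})

test_that("minimal element count interpolates the quality table", {
  # hand-built sweep result: C rises with N and SNR
  tbl <- tidyr::expand_grid(N = c(2, 4, 8), snr = c(10, 100))
  tbl$mean_C <- c(0.1, 0.3, 0.5, 0.7, 0.75, 0.9)
  sw <- structure(list(mean_C = tbl, records = NULL,
                       config = list(N_values = c(2, 4, 8),
                                     snr_values = c(10, 100))),
                  class = "sparsus_sweep")

  expect_equal(minimal_elements(sw, 0.7, 100)$n_min, 4)
  expect_equal(minimal_elements(sw, 0, 100)$n_min, 2)
  nm <- minimal_elements(sw, 1.01, 100)
  expect_false(nm$achieved)
  expect_true(is.na(nm$n_min))
  expect_error(minimal_elements(sw, 0.5, 1000), class = "sparsus_error_range")

  # interpolation between the SNR grid lines (linear in log SNR)
  mid <- minimal_elements(sw, 0.6, sqrt(10 * 100))
  expect_equal(mid$table$C_at, c(0.2, 0.6, 0.825), tolerance = 1e-9)
  expect_equal(mid$n_min, 4)
})

test_that("the sqrt(N) contour fit recovers constructed coefficients", {
  N_vals <- c(2, 4, 8, 16, 64)
  snr_grid <- c(1, 3, 10, 30, 100, 300)
  # construct mean C so that the C = 0.8 crossing sits exactly at 5 sqrt(N),
  # with N = 2 an outlier far off the trend
  tbl <- tidyr::expand_grid(N = N_vals, snr = snr_grid)
  target_snr <- function(N) if (N == 2) 250 else 5 * sqrt(N)
  tbl$mean_C <- mapply(function(N, snr) {
    0.8 + 0.3 * log10(snr / target_snr(N))
  }, tbl$N, tbl$snr)
  sw <- structure(list(mean_C = tbl, records = NULL,
                       config = list(N_values = N_vals,
                                     snr_values = snr_grid)),
                  class = "sparsus_sweep")

  fit <- fit_sqrt_n_contour(sw, target_C = 0.8)
  expect_true(fit$fitted)
  expect_equal(fit$a, 5, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999)
  expect_true(fit$table$excluded[fit$table$N == 2])

  # removing the N = 2 outlier does not change the fit (documented exclusion)
  sw2 <- sw
  sw2$mean_C <- sw$mean_C[sw$mean_C$N != 2, ]
  fit2 <- fit_sqrt_n_contour(sw2, target_C = 0.8)
  expect_equal(fit2$a, fit$a, tolerance = 1e-9)

  # too few crossings: refused, not fabricated
  sw3 <- sw
  sw3$mean_C <- sw$mean_C[sw$mean_C$N %in% c(2, 4), ]
  fit3 <- fit_sqrt_n_contour(sw3, target_C = 0.8)
  expect_false(fit3$fitted)
  expect_true(is.na(fit3$a))

  expect_equal(glance(fit)$a, fit$a)
  expect_s3_class(tidy(fit), "data.frame")
})

test_that("sweep plots build without evaluation errors", {
  tbl <- tidyr::expand_grid(N = c(2, 4), snr = c(1, 10))
  tbl$mean_C <- c(0.1, 0.2, 0.3, 0.4)
  sw <- structure(list(mean_C = tbl, records = NULL,
                       config = list(N_values = c(2, 4), snr_values = c(1, 10),
                                     n_realizations = 1)),
                  class = "sparsus_sweep")
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
})
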