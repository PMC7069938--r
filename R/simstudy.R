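#' The default reconstruction window of the reference configuration
#'
#' Lateral band of 0.75 mm around the array axis by a 0.15 mm depth band
#' around the 15 mm elevation focus, sampled at the 12.5 um reconstruction
#' step: 61 x 13 = 793 grid points.
#'
#' @param depth Center depth in meters.
#' @param step Grid step in meters.
#' @return A `sparsus_grid`.
#' @export
default_recon_grid <- function(depth = 15e-3, step = 12.5e-6) {
  make_grid(-375e-6, 375e-6, depth - 75e-6, depth + 75e-6, step)
}

#' Configuration of the Monte-Carlo SNR / element-count study
#'
#' Bundles the study conditions: the imaged scene (five point sources
#' 125 um apart at 15 mm depth), the 128-element 100 um-pitch 15 MHz array,
#' additive Gaussian noise of rms `sigma_n = 30`, the element-count and SNR
#' grids, and the solver/selection settings. SNR is imposed by scaling the
#' noiseless signal amplitude so that its peak divided by `sigma_n` equals
#' the target.
#'
#' @param N_values Element counts (regular subsets with fixed endpoints).
#' @param snr_values Target SNR grid.
#' @param n_realizations Noise realizations per (N, SNR) cell.
#' @param base_seed Master seed; all per-cell seeds derive from it.
#' @param scene A [source_set()]; default [microchannel_scene()].
#' @param sigma_n Noise rms.
#' @param probe,pulse,grid,modality,c0 Acquisition model.
#' @param alpha_fractions,support_budget Regularization scan (see
#'   [choose_alpha()]); alpha is re-chosen per (N, SNR) cell on a dedicated
#'   calibration realization and then held fixed within the cell.
#' @param solver_max_iters,solver_tolerance,nonnegativity FISTA settings.
#' @param smoothing_sigma,fine_step Display post-processing.
#' @param n_time_samples Number of time samples kept per element. The
#'   default `NULL` keeps the full auto-sized window covering every
#'   arrival; a finite value (e.g. 36, giving `m = 4608` data samples with
#'   128 elements) trims records to a fixed acquisition window starting
#'   just before the earliest grid arrival, as in fixed-depth hardware
#'   acquisition. Severe trimming discards the outer-element arrivals and
#'   degrades both the diffraction-limited and the sparse reconstruction.
#' @return A `sparsus_sweep_config` list.
#' @export
sweep_config <- function(N_values = c(2, 3, 4, 8, 16, 32, 64, 128),
                         snr_values = round(10^seq(log10(0.5), log10(300), length.out = 8), 2),
                         n_realizations = 100,
                         base_seed = 1L,
                         scene = microchannel_scene(),
                         sigma_n = 30,
                         probe = make_linear_probe(128, 100e-6),
                         pulse = make_pulse(),
                         grid = default_recon_grid(),
                         modality = "PA",
                         c0 = 1500,
                         alpha_fractions = 10^seq(log10(0.5), -2, length.out = 8),
                         support_budget = 25,
                         solver_max_iters = 1500,
                         solver_tolerance = 1e-7,
                         nonnegativity = FALSE,
                         smoothing_sigma = 12.5e-6,
                         fine_step = 3.125e-6,
                         n_time_samples = NULL) {
  stopifnot(all(N_values >= 2), all(snr_values > 0), n_realizations >= 1,
            sigma_n >= 0)
  structure(
    list(
      N_values = sort(unique(as.integer(N_values))),
      snr_values = sort(unique(snr_values)),
      n_realizations = as.integer(n_realizations),
      base_seed = as.integer(base_seed),
      scene = scene, sigma_n = sigma_n,
      probe = probe, pulse = pulse, grid = grid,
      modality = modality, c0 = c0,
      alpha_fractions = alpha_fractions, support_budget = support_budget,
      solver_max_iters = solver_max_iters,
      solver_tolerance = solver_tolerance,
      nonnegativity = nonnegativity,
      smoothing_sigma = smoothing_sigma, fine_step = fine_step,
      n_time_samples = if (is.null(n_time_samples)) NULL else
        as.integer(n_time_samples)
    ),
    class = "sparsus_sweep_config"
  )
}

# splittable deterministic seed scheme: Lehmer-style mixing, < 2^31.
# Noise seeds depend on (base_seed, N, realization) but not on SNR, so the
# same noise realizations are shared along the SNR axis (paired seeds).
mix_seed <- function(s, v) {
  ((s %% 2147483647) * 48271 + v + 1) %% 2147483647
}
cell_seed <- function(base_seed, N, realization) {
  as.integer(mix_seed(mix_seed(base_seed, N), realization) + 1)
}

#' Build (and cache) the per-element-count simulation context
#'
#' Prepares, for each element count, the regular subset, the noiseless
#' unit-amplitude five-source RF record, the forward model built from a
#' noiseless single-source PSF at the grid center, its Gram matrix and
#' Lipschitz constant, plus the post-processed ideal object. All records
#' share the full-array time window so data vectors are consistent across
#' subsets.
#'
#' @param config A [sweep_config()].
#' @return A context environment consumed by [run_cell()] / [run_sweep()].
#' @export
simstudy_context <- function(config) {
  ctx <- new.env(parent = emptyenv())
  ctx$config <- config
  full <- select_elements(config$probe, config$probe$n_elements, "all")
  ctx$window <- grid_time_window(config$probe, full, config$grid, config$pulse,
                                 config$modality, config$c0)
  ideal <- make_ideal_object(config$scene, config$grid)
  ctx$ideal_display <- smooth_and_upsample(ideal, config$grid,
                                           config$smoothing_sigma,
                                           config$fine_step)
  ctx$models <- list()
  ctx
}

ctx_model <- function(ctx, N) {
  key <- as.character(N)
  if (!is.null(ctx$models[[key]])) return(ctx$models[[key]])
  cfg <- ctx$config
  subset <- select_elements(cfg$probe, N, "regular")
  center <- list(x = mean(range(cfg$grid$x)), z = mean(range(cfg$grid$z)))
  psf <- simulate_psf(cfg$probe, subset, cfg$pulse, center$x, center$z,
                      cfg$modality, cfg$c0, window = ctx$window)
  rf0 <- synthesize_rf(cfg$scene, cfg$probe, subset, cfg$pulse,
                       cfg$modality, cfg$c0, window = ctx$window)
  if (!is.null(cfg$n_time_samples)) {
    # fixed acquisition window opening just before the earliest grid arrival
    start <- max(1L, as.integer(round(2 * cfg$pulse$sigma_t * cfg$pulse$fs)))
    n_keep <- min(cfg$n_time_samples, nrow(psf$rf$samples) - start + 1L)
    psf$rf <- trim_rf(psf$rf, n_keep, start)
    rf0 <- trim_rf(rf0, n_keep, start)
  }
  # window truncation of off-center columns is expected here
  model <- suppressWarnings(build_matrix(psf, cfg$grid, c0 = cfg$c0))
  precompute_gram(model)
  lipschitz_estimate(model)
  entry <- list(N = N, subset = subset, model = model, rf0 = rf0,
                peak0 = max(abs(rf0$samples)))
  ctx$models[[key]] <- entry
  entry
}

#' Run one Monte-Carlo realization of the reconstruction study
#'
#' Synthesizes the five-source RF record on the N-element regular subset
#' with the signal amplitude scaled so the noiseless peak over `sigma_n`
#' equals `target_snr`, adds Gaussian noise, inverts with FISTA using the
#' forward model built from a noiseless single-source PSF, post-processes,
#' and scores the normalized correlation against the ideal object. An
#' all-zero reconstruction scores `C = 0`.
#'
#' @param N Element count.
#' @param target_snr Target SNR (noiseless peak / sigma_n).
#' @param config A [sweep_config()].
#' @param realization Realization index (enters the seed derivation).
#' @param alpha Regularization weight; `NULL` runs the [choose_alpha()]
#'   scan on this realization's data.
#' @param ctx Optional prebuilt [simstudy_context()] (strongly recommended
#'   when calling repeatedly).
#' @return A list with `C`, `recon`, `display`, `alpha`, `seed`, `N`,
#'   `snr`, `realization`.
#' @export
run_cell <- function(N, target_snr, config, realization = 1L, alpha = NULL,
                     ctx = NULL) {
  if (is.null(ctx)) ctx <- simstudy_context(config)
  cm <- ctx_model(ctx, N)
  amp <- target_snr * config$sigma_n / cm$peak0
  seed <- cell_seed(config$base_seed, N, realization)
  rf <- cm$rf0
  rf$samples <- rf$samples * amp
  rf <- add_noise(rf, config$sigma_n, seed)
  S <- as.vector(rf$samples)
  if (is.null(alpha)) {
    ca <- choose_alpha(cm$model, S,
                       fractions = config$alpha_fractions,
                       support_budget = config$support_budget,
                       max_iters = config$solver_max_iters,
                       tolerance = config$solver_tolerance,
                       nonnegativity = config$nonnegativity)
    alpha <- ca$alpha
    rec <- ca$result
  } else {
    rec <- fista_solve(cm$model, S,
                       solver_config(alpha,
                                     max_iters = config$solver_max_iters,
                                     tolerance = config$solver_tolerance,
                                     nonnegativity = config$nonnegativity))
  }
  disp <- smooth_and_upsample(rec, config$grid, config$smoothing_sigma,
                              config$fine_step)
  C <- if (isTRUE(disp$zero_image)) 0 else {
    image_correlation(disp, ctx$ideal_display)
  }
  list(C = C, recon = rec, display = disp, alpha = alpha, seed = seed,
       N = N, snr = target_snr, realization = realization)
}

#' Run the full Monte-Carlo sweep over element count and SNR
#'
#' For every (N, SNR) cell: the regularization weight is chosen once by the
#' [choose_alpha()] scan on a calibration realization (index 0), then the
#' configured number of scored realizations is run at that fixed alpha.
#' Failed realizations (solver errors) are recorded and excluded from the
#' cell mean; a cell with more than 10% failures is flagged. The whole
#' sweep is bit-reproducible from `base_seed`.
#'
#' @param config A [sweep_config()].
#' @param progress Print one line per cell.
#' @return A `sparsus_sweep`: list with `records` (tibble: N, snr,
#'   realization, seed, C, alpha, support, n_iters, converged, failed),
#'   `mean_C` (tibble: N, snr, mean_C, n_used, n_failed, alpha, flagged),
#'   `config`.
#' @export
run_sweep <- function(config, progress = FALSE) {
  ctx <- simstudy_context(config)
  rec_rows <- list()
  cell_rows <- list()
  for (N in config$N_values) {
    cm <- ctx_model(ctx, N) # build/caches the model once per N
    for (snr in config$snr_values) {
      # median alpha over three dedicated calibration realizations: the
      # scan's choice on a single draw is noisy near the budget boundary
      alphas <- vapply(0:2, function(rc) {
        run_cell(N, snr, config, realization = 1000000L + rc,
                 alpha = NULL, ctx = ctx)$alpha
      }, numeric(1))
      alpha_cell <- stats::median(alphas)
      rows <- vector("list", config$n_realizations)
      for (r in seq_len(config$n_realizations)) {
        res <- tryCatch(
          run_cell(N, snr, config, realization = r, alpha = alpha_cell,
                   ctx = ctx),
          error = function(e) e
        )
        rows[[r]] <- if (inherits(res, "error")) {
          tibble::tibble(N = N, snr = snr, realization = r,
                         seed = cell_seed(config$base_seed, N, r),
                         C = NA_real_, alpha = alpha_cell,
                         support = NA_integer_, n_iters = NA_integer_,
                         converged = NA, failed = TRUE)
        } else {
          tibble::tibble(N = N, snr = snr, realization = r, seed = res$seed,
                         C = res$C, alpha = alpha_cell,
                         support = length(res$recon$support),
                         n_iters = res$recon$n_iters,
                         converged = res$recon$converged, failed = FALSE)
        }
      }
      rec_rows[[length(rec_rows) + 1]] <- dplyr::bind_rows(rows)
      cells <- rec_rows[[length(rec_rows)]]
      cell_rows[[length(cell_rows) + 1]] <- tibble::tibble(
        N = N, snr = snr,
        mean_C = mean(cells$C, na.rm = TRUE),
        n_used = sum(!cells$failed),
        n_failed = sum(cells$failed),
        alpha = alpha_cell,
        flagged = mean(cells$failed) > 0.1
      )
      if (progress) {
        message(sprintf("N = %3d  SNR = %7.2f  mean C = %.3f  (alpha %.3g)",
                        N, snr, cell_rows[[length(cell_rows)]]$mean_C,
                        alpha_cell))
      }
    }
  }
  structure(
    list(records = dplyr::bind_rows(rec_rows),
         mean_C = dplyr::bind_rows(cell_rows),
         config = config),
    class = "sparsus_sweep"
  )
}

#' @export
print.sparsus_sweep <- function(x, ...) {
  cat(sprintf(
    "<sparsus_sweep> %d N values x %d SNR values x %d realizations\n",
    length(x$config$N_values), length(x$config$snr_values),
    x$config$n_realizations
  ))
  print(x$mean_C, n = 10)
  invisible(x)
}

#' @export
tidy.sparsus_sweep <- function(x, ...) x$records

#' @export
glance.sparsus_sweep <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$mean_C),
    n_realizations = x$config$n_realizations,
    n_failed = sum(x$mean_C$n_failed),
    min_C = min(x$mean_C$mean_C),
    max_C = max(x$mean_C$mean_C)
  )
}

# interpolate a cell table's mean C at an off-grid SNR (linear in log SNR)
interp_C_at_snr <- function(tbl, at_snr) {
  tbl <- tbl[order(tbl$snr), ]
  if (at_snr < min(tbl$snr) || at_snr > max(tbl$snr)) {
    rlang::abort("`at_snr` lies outside the sweep's SNR range.",
                 class = "sparsus_error_range")
  }
  if (nrow(tbl) == 1) return(tbl$mean_C)
  stats::approx(log10(tbl$snr), tbl$mean_C, xout = log10(at_snr))$y
}

#' Smallest element count achieving a target reconstruction quality
#'
#' Interpolates each element count's mean correlation at `at_snr` (linearly
#' in log SNR) and reports the smallest N meeting `target_C`.
#'
#' @param sweep A [run_sweep()] result.
#' @param target_C Correlation threshold.
#' @param at_snr SNR at which the requirement is evaluated; must lie inside
#'   the sweep's SNR range.
#' @return A `sparsus_minimal`: list with `n_min` (`NA` when no N
#'   qualifies), `achieved`, `target_C`, `at_snr`, and the per-N `table`.
#' @export
minimal_elements <- function(sweep, target_C, at_snr) {
  tbl <- dplyr::group_by(sweep$mean_C, .data$N)
  tbl <- dplyr::summarise(tbl, C_at = interp_C_at_snr(
    dplyr::pick(dplyr::everything()), at_snr), .groups = "drop")
  hit <- tbl$N[tbl$C_at >= target_C]
  structure(
    list(
      n_min = if (length(hit)) min(hit) else NA_integer_,
      achieved = length(hit) > 0,
      target_C = target_C, at_snr = at_snr, table = tbl
    ),
    class = "sparsus_minimal"
  )
}

#' @export
print.sparsus_minimal <- function(x, ...) {
  if (x$achieved) {
    cat(sprintf("<sparsus_minimal> N_min = %d for C >= %.2f at SNR = %g\n",
                x$n_min, x$target_C, x$at_snr))
  } else {
    cat(sprintf("<sparsus_minimal> no element count reaches C >= %.2f at SNR = %g\n",
                x$target_C, x$at_snr))
  }
  invisible(x)
}

# SNR at which a single N's mean C first crosses the target (log-linear)
contour_snr <- function(tbl, target_C) {
  tbl <- tbl[order(tbl$snr), ]
  above <- which(tbl$mean_C >= target_C)
  if (length(above) == 0) return(NA_real_)
  i <- min(above)
  if (i == 1) return(tbl$snr[1])
  x0 <- log10(tbl$snr[i - 1]); x1 <- log10(tbl$snr[i])
  y0 <- tbl$mean_C[i - 1]; y1 <- tbl$mean_C[i]
  10^(x0 + (target_C - y0) / (y1 - y0) * (x1 - x0))
}

#' Fit the square-root-of-N scaling of the iso-quality SNR contour
#'
#' Extracts, for every element count, the SNR at which the mean correlation
#' reaches `target_C` (interpolated in log SNR) and fits
#' `SNR = a * sqrt(N)` by least squares. `N = 2` is excluded by default:
#' that regime demands disproportionately high SNR and falls off the
#' square-root trend.
#'
#' @param sweep A [run_sweep()] result.
#' @param target_C Contour level (default 0.8).
#' @param exclude_N Element counts excluded from the fit.
#' @return A `sparsus_contour_fit`: list with `fitted` (logical), `a`,
#'   `r_squared` (uncentered, zero-intercept), and `table` (N, snr_star,
#'   fitted value, residual, excluded).
#' @export
fit_sqrt_n_contour <- function(sweep, target_C = 0.8, exclude_N = 2) {
  per_n <- dplyr::group_by(sweep$mean_C, .data$N)
  per_n <- dplyr::summarise(per_n, snr_star = contour_snr(
    dplyr::pick(dplyr::everything()), target_C), .groups = "drop")
  per_n$excluded <- per_n$N %in% exclude_N | is.na(per_n$snr_star)
  use <- per_n[!per_n$excluded, ]
  if (nrow(use) < 3) {
    return(structure(
      list(fitted = FALSE, a = NA_real_, r_squared = NA_real_,
           target_C = target_C, table = per_n),
      class = "sparsus_contour_fit"
    ))
  }
  fit <- stats::lm(snr_star ~ 0 + I(sqrt(N)), data = use)
  a <- unname(stats::coef(fit)[1])
  per_n$fitted_snr <- a * sqrt(per_n$N)
  per_n$residual <- per_n$snr_star - per_n$fitted_snr
  rss <- sum(per_n$residual[!per_n$excluded]^2)
  r2 <- 1 - rss / sum(use$snr_star^2)
  structure(
    list(fitted = TRUE, a = a, r_squared = r2, target_C = target_C,
         table = per_n),
    class = "sparsus_contour_fit"
  )
}

#' @export
print.sparsus_contour_fit <- function(x, ...) {
  if (x$fitted) {
    cat(sprintf(
      "<sparsus_contour_fit> SNR(C = %.2f) = %.3g * sqrt(N), R^2 = %.3f\n",
      x$target_C, x$a, x$r_squared
    ))
  } else {
    cat("<sparsus_contour_fit> fit refused: contour insufficiently sampled\n")
  }
  invisible(x)
}

#' @export
tidy.sparsus_contour_fit <- function(x, ...) x$table

#' @export
glance.sparsus_contour_fit <- function(x, ...) {
  tibble::tibble(fitted = x$fitted, a = x$a, r_squared = x$r_squared,
                 target_C = x$target_C)
}
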