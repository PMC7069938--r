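#' Default run configuration
#'
#' Nested configuration with every physical quantity carrying its unit in
#' the key name. The defaults reproduce the reference study conditions: a
#' 128-element, 100 um-pitch, 15 MHz linear array; a 61 x 13 = 793-point
#' reconstruction grid (12.5 um step) around the 15 mm focus; a five-source
#' scene 125 um apart; Gaussian noise of rms 30; and the FISTA solver with
#' the logarithmic alpha scan.
#'
#' @return A nested named list (class `sparsus_config`).
#' @export
default_config <- function() {
  structure(list(
    probe = list(n_elements = 128L, pitch_m = 100e-6, center_x_m = 0),
    grid = list(x_min_m = -375e-6, x_max_m = 375e-6,
                z_min_m = 14.925e-3, z_max_m = 15.075e-3, step_m = 12.5e-6),
    pulse = list(center_frequency_hz = 15e6, fractional_bandwidth = 0.93,
                 sampling_rate_hz = 62.5e6),
    scene = list(n_sources = 5L, spacing_m = 125e-6, depth_m = 15e-3),
    medium = list(sound_speed_m_s = 1500),
    modality = "PA",
    noise = list(sigma_n = 30),
    solver = list(alpha_fractions_log10_min = -2,
                  alpha_fractions_log10_max = -0.30103,
                  alpha_n_candidates = 8L,
                  support_budget = 25L,
                  max_iters = 1500L, tolerance = 1e-7,
                  nonnegativity = FALSE),
    postprocess = list(smoothing_sigma_m = 12.5e-6, fine_step_m = 3.125e-6,
                       prominence_frac = 0.05),
    sweep = list(N_values = c(2L, 3L, 4L, 8L, 16L, 32L, 64L, 128L),
                 snr_values = round(10^seq(log10(0.5), log10(300),
                                           length.out = 8), 2),
                 n_realizations = 100L, base_seed = 1L)
  ), class = "sparsus_config")
}

# recursive merge of user values over defaults, rejecting unknown keys
merge_config <- function(default, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(default)) {
      rlang::abort(sprintf("Unknown configuration key: '%s'.", full),
                   class = "sparsus_error_config")
    }
    if (is.list(default[[key]]) && !is.null(names(default[[key]]))) {
      if (!is.list(user[[key]])) {
        rlang::abort(sprintf("Key '%s' must be a section.", full),
                     class = "sparsus_error_config")
      }
      default[[key]] <- merge_config(default[[key]], user[[key]], full)
    } else {
      default[[key]] <- user[[key]]
    }
  }
  default
}

check_positive <- function(cfg, keys) {
  for (k in keys) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    v <- cfg
    for (p in parts) v <- v[[p]]
    if (is.null(v) || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      rlang::abort(sprintf("Configuration key '%s' must be positive.", k),
                   class = "sparsus_error_config")
    }
  }
}

validate_config <- function(cfg) {
  check_positive(cfg, c(
    "probe.pitch_m", "grid.step_m", "pulse.center_frequency_hz",
    "pulse.fractional_bandwidth", "pulse.sampling_rate_hz",
    "scene.spacing_m", "scene.depth_m", "medium.sound_speed_m_s",
    "solver.tolerance", "postprocess.smoothing_sigma_m",
    "postprocess.fine_step_m", "sweep.snr_values"
  ))
  if (cfg$probe$n_elements < 2) {
    rlang::abort("Configuration key 'probe.n_elements' must be >= 2.",
                 class = "sparsus_error_config")
  }
  if (!cfg$modality %in% c("PA", "US_planewave")) {
    rlang::abort("Configuration key 'modality' must be 'PA' or 'US_planewave'.",
                 class = "sparsus_error_config")
  }
  if (cfg$noise$sigma_n < 0) {
    rlang::abort("Configuration key 'noise.sigma_n' must be >= 0.",
                 class = "sparsus_error_config")
  }
  cfg
}

#' Load, validate and normalize a YAML run configuration
#'
#' Unknown keys are rejected (with the offending key named); missing keys
#' are filled with the documented defaults, so the returned object is fully
#' materialized and self-describing. `save_config(load_config(p))` is
#' byte-stable.
#'
#' @param path Path to a YAML file; a partial configuration is fine.
#' @return A validated `sparsus_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config()), user)
  validate_config(structure(cfg, class = "sparsus_config"))
}

#' @rdname load_config
#' @param config A `sparsus_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Materialize model objects from a configuration
#'
#' @param config A `sparsus_config`.
#' @return `config_probe()`: a `sparsus_probe`; `config_grid()`: a
#'   `sparsus_grid`; `config_pulse()`: a `sparsus_pulse`;
#'   `config_scene()`: a [source_set()]; `config_sweep()`: a
#'   [sweep_config()].
#' @export
config_probe <- function(config) {
  make_linear_probe(config$probe$n_elements, config$probe$pitch_m,
                    config$probe$center_x_m)
}

#' @rdname config_probe
#' @export
config_grid <- function(config) {
  make_grid(config$grid$x_min_m, config$grid$x_max_m,
            config$grid$z_min_m, config$grid$z_max_m, config$grid$step_m)
}

#' @rdname config_probe
#' @export
config_pulse <- function(config) {
  make_pulse(config$pulse$center_frequency_hz,
             config$pulse$fractional_bandwidth,
             config$pulse$sampling_rate_hz)
}

#' @rdname config_probe
#' @export
config_scene <- function(config) {
  microchannel_scene(config$scene$n_sources, config$scene$spacing_m,
                     config$scene$depth_m)
}

#' @rdname config_probe
#' @export
config_sweep <- function(config) {
  s <- config$solver
  sweep_config(
    N_values = config$sweep$N_values,
    snr_values = config$sweep$snr_values,
    n_realizations = config$sweep$n_realizations,
    base_seed = config$sweep$base_seed,
    scene = config_scene(config),
    sigma_n = config$noise$sigma_n,
    probe = config_probe(config),
    pulse = config_pulse(config),
    grid = config_grid(config),
    modality = config$modality,
    c0 = config$medium$sound_speed_m_s,
    alpha_fractions = 10^seq(s$alpha_fractions_log10_max,
                             s$alpha_fractions_log10_min,
                             length.out = s$alpha_n_candidates),
    support_budget = s$support_budget,
    solver_max_iters = s$max_iters,
    solver_tolerance = s$tolerance,
    nonnegativity = s$nonnegativity,
    smoothing_sigma = config$postprocess$smoothing_sigma_m,
    fine_step = config$postprocess$fine_step_m
  )
}

#' Run the paired DAS + sparse reconstruction and write all artifacts
#'
#' End-to-end single-scene run on synthetic data: synthesizes the
#' configured scene's RF record (plus noise), builds the forward model from
#' a noiseless single-source PSF, reconstructs with both delay-and-sum and
#' FISTA, post-processes, and writes images, a metrics row and a JSON run
#' manifest (configuration echo, seeds, file hashes) to `out_dir`.
#'
#' @param config A `sparsus_config`.
#' @param out_dir Output directory (created if needed).
#' @param seed Noise seed.
#' @param target_snr Target SNR of the synthetic record (noiseless peak
#'   over `sigma_n`); ignored when `sigma_n = 0`.
#' @return Invisibly, a list with `das`, `recon`, `display`, `metrics`,
#'   `manifest_path`.
#' @export
reconstruct_run <- function(config, out_dir, seed = 1L, target_snr = 150) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- config_probe(config)
  grid <- config_grid(config)
  pulse <- config_pulse(config)
  scene <- config_scene(config)
  c0 <- config$medium$sound_speed_m_s
  subset <- select_elements(probe, probe$n_elements, "all")
  window <- grid_time_window(probe, subset, grid, pulse, config$modality, c0)

  rf0 <- synthesize_rf(scene, probe, subset, pulse, config$modality, c0, window)
  sigma_n <- config$noise$sigma_n
  if (sigma_n > 0) {
    rf0$samples <- rf0$samples * target_snr * sigma_n / max(abs(rf0$samples))
    rf <- add_noise(rf0, sigma_n, seed)
  } else {
    rf <- rf0
  }

  center <- list(x = mean(range(grid$x)), z = mean(range(grid$z)))
  psf <- simulate_psf(probe, subset, pulse, center$x, center$z,
                      config$modality, c0, window)
  model <- build_matrix(psf, grid, c0 = c0)
  precompute_gram(model)

  das <- das_reconstruct(rf, probe, subset, grid, c0)
  s <- config$solver
  ca <- choose_alpha(model, as.vector(rf$samples),
                     fractions = 10^seq(s$alpha_fractions_log10_max,
                                        s$alpha_fractions_log10_min,
                                        length.out = s$alpha_n_candidates),
                     support_budget = s$support_budget,
                     max_iters = s$max_iters, tolerance = s$tolerance,
                     nonnegativity = s$nonnegativity)
  pp <- config$postprocess
  disp <- smooth_and_upsample(ca$result, grid, pp$smoothing_sigma_m,
                              pp$fine_step_m)
  ideal <- smooth_and_upsample(make_ideal_object(scene, grid), grid,
                               pp$smoothing_sigma_m, pp$fine_step_m)
  C <- if (isTRUE(disp$zero_image)) 0 else image_correlation(disp, ideal)

  rf_path <- file.path(out_dir, "rf.tsv")
  das_path <- file.path(out_dir, "das_envelope.tsv")
  sparse_path <- file.path(out_dir, "sparse_display.tsv")
  write_rf(rf, rf_path)
  write_image(das$envelope, das_path,
              list(kind = "das_envelope", step_m = grid$step))
  write_image(disp$pixels, sparse_path,
              list(kind = "sparse_display", step_m = disp$fine_step))
  metrics <- tibble::tibble(
    scene = "synthetic_microchannels", N = probe$n_elements,
    snr = target_snr, seed = seed, C = C, alpha = ca$alpha,
    support = length(ca$result$support)
  )
  metrics_path <- file.path(out_dir, "metrics.tsv")
  utils::write.table(metrics, metrics_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest <- list(
    package = "sparsus",
    version = as.character(utils::packageVersion("sparsus")),
    seed = seed, target_snr = target_snr,
    config = unclass(config),
    files = lapply(
      stats::setNames(
        c(rf_path, das_path, sparse_path, metrics_path),
        c("rf", "das_envelope", "sparse_display", "metrics")
      ),
      function(p) list(path = basename(p), md5 = unname(tools::md5sum(p)))
    ),
    metrics = as.list(metrics)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(das = das, recon = ca$result, display = disp,
                 metrics = metrics, manifest_path = manifest_path))
}
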