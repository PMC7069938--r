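#' Arrival-time difference between a grid point and the calibration source
#'
#' Time-of-flight delay applied to the single-PSF record to obtain the
#' response of a point at `point` from the response measured for a source at
#' `source`. For photoacoustics the delay is the one-way path difference;
#' for single plane-wave ultrasound the plane-wave emission delay
#' `(z_i - z_j)/c` is added (the wave is emitted at `t = 0` from `z = 0`
#' with normal incidence). The sign convention is the physical arrival-time
#' difference: `delay_law() > 0` means the point's response arrives later
#' than the calibration source's, and the PSF column is delayed by that
#' amount — validated against [synthesize_rf()] in the test suite.
#'
#' @param point List/vector with `x`, `z` of the reconstruction point(s);
#'   `x` and `z` may be vectors of equal length.
#' @param source List/vector with `x`, `z` of the calibration source.
#' @param element List/vector with `x`, `z` of the receiving element.
#' @param c0 Speed of sound, m/s.
#' @param modality `"PA"` or `"US_planewave"`.
#' @return Delay(s) in seconds.
#' @export
delay_law <- function(point, source, element, c0 = 1500,
                      modality = c("PA", "US_planewave")) {
  modality <- match.arg(modality)
  stopifnot(c0 > 0)
  d_ik <- sqrt((point$x - element$x)^2 + (point$z - element$z)^2)
  d_jk <- sqrt((source$x - element$x)^2 + (source$z - element$z)^2)
  delta_us <- if (modality == "US_planewave") 1 else 0
  delta_us * (point$z - source$z) / c0 + (d_ik - d_jk) / c0
}

#' Wrap an RF record as a single-source PSF calibration record
#'
#' The forward model is built from one measured (or simulated) PSF: the full
#' set of RF traces recorded from a single point-like source. The record is
#' checked for a single dominant envelope lobe per trace.
#'
#' @param rf A `sparsus_rf` record containing one source's response.
#' @param source_x,source_z Calibration source position in meters.
#' @return A `sparsus_psf`: list with `rf`, `source`, `modality`.
#' @export
psf_record <- function(rf, source_x, source_z) {
  stopifnot(inherits(rf, "sparsus_rf"))
  # light validation: one connected region above half max per element envelope
  env <- envelope(rf$samples)
  multi <- vapply(seq_len(ncol(env)), function(k) {
    e <- env[, k]
    above <- e > max(e) / 2
    sum(diff(c(FALSE, above, FALSE)) == 1) > 1
  }, logical(1))
  if (mean(multi) > 0.1) {
    rlang::warn("More than 10% of element traces show multiple envelope lobes; is this a single-source record?")
  }
  structure(
    list(rf = rf, source = list(x = source_x, z = source_z),
         modality = rf$modality),
    class = "sparsus_psf"
  )
}

#' Simulate a noiseless single-source PSF record
#'
#' Convenience wrapper around [synthesize_rf()] for a unit source, typically
#' at the center of the field of view.
#'
#' @inheritParams synthesize_rf
#' @param source_x,source_z Calibration source position in meters.
#' @return A `sparsus_psf`.
#' @export
simulate_psf <- function(probe, subset = NULL, pulse = make_pulse(),
                         source_x = 0, source_z = 15e-3,
                         modality = "PA", c0 = 1500, window = NULL) {
  rf <- synthesize_rf(source_set(source_x, source_z), probe, subset, pulse,
                      modality, c0, window)
  psf_record(rf, source_x, source_z)
}

#' Time window guaranteed to contain every grid point's response
#'
#' Computes `c(t_start, t_end)` covering the arrivals of all grid points at
#' all active elements with a 6 sigma_t pulse margin, so that neither the
#' PSF record nor any delayed copy is truncated.
#'
#' @param probe,subset,grid,pulse Geometry, element subset, grid and pulse.
#' @param modality `"PA"` or `"US_planewave"`.
#' @param c0 Speed of sound, m/s.
#' @return Length-2 numeric window in seconds.
#' @export
grid_time_window <- function(probe, subset, grid, pulse,
                             modality = "PA", c0 = 1500) {
  if (is.null(subset)) subset <- select_elements(probe, probe$n_elements, "all")
  co <- grid_coords(grid)
  # extremes occur at grid corners; evaluate all corner/edge combinations cheaply
  xs <- c(min(co$x), max(co$x))
  zs <- c(min(co$z), max(co$z))
  corners <- expand.grid(x = xs, z = zs)
  ta <- arrival_times(corners$x, corners$z,
                      probe$element_x[subset$indices],
                      probe$element_z[subset$indices], modality, c0)
  c(min(ta) - 6 * pulse$sigma_t, max(ta) + 6 * pulse$sigma_t)
}

#' Build the forward-model matrix from a single PSF record
#'
#' Assembles the `m x n` matrix `A` whose column `p` is the vectorized RF
#' response of a unit source at grid point `p`, obtained by fractional-delay
#' shifting of the single measured PSF according to [delay_law()]. Shifts
#' are applied in the frequency domain (phase ramps on a zero-padded FFT),
#' giving sub-sample accuracy; content shifted outside the time window is
#' dropped (zero-padding), with a warning if the worst-case energy loss
#' exceeds 0.5%.
#'
#' Vectorization: row `(k - 1) * n_t + i` holds time sample `i` of active
#' element `k`; column order is the grid's depth-major raster order.
#'
#' @param psf A [psf_record()] (or [simulate_psf()]) object.
#' @param grid A [make_grid()] reconstruction grid.
#' @param subset Optional element subset to model; must be a subset of the
#'   elements present in the PSF record. Default: all recorded elements.
#' @param c0 Speed of sound, m/s.
#' @param pad If `TRUE` (default) delayed copies spilling out of the window
#'   are zero-padded (with the energy warning); if `FALSE` any spill is an
#'   error.
#' @return A `sparsus_model`: list with `A`, `time_axis`, `grid`, `subset`,
#'   `probe`, `source`, `modality`, `fs`, `n_t`, and `col_energy` (per-column
#'   l2 norm relative to the vectorized PSF).
#' @export
build_matrix <- function(psf, grid, subset = NULL, c0 = 1500, pad = TRUE) {
  stopifnot(inherits(psf, "sparsus_psf"))
  rf <- psf$rf
  probe <- rf$probe
  rec_idx <- rf$subset$indices
  if (is.null(subset)) {
    use_idx <- rec_idx
  } else {
    use_idx <- subset$indices
    if (!all(use_idx %in% rec_idx)) {
      rlang::abort("Requested subset contains elements absent from the PSF record.",
                   class = "sparsus_error_subset")
    }
  }
  cols_in_rec <- match(use_idx, rec_idx)
  n_t <- nrow(rf$samples)
  n_el <- length(use_idx)
  fs <- rf$fs
  co <- grid_coords(grid)

  # per (point, element) arrival-time difference w.r.t. the calibration source
  el_x <- probe$element_x[use_idx]
  el_z <- probe$element_z[use_idx]
  ta_pts <- arrival_times(co$x, co$z, el_x, el_z, psf$modality, c0)
  ta_src <- arrival_times(psf$source$x, psf$source$z, el_x, el_z,
                          psf$modality, c0)
  dt <- sweep(ta_pts, 2, as.vector(ta_src)) # n_points x n_el, seconds

  max_shift <- max(abs(dt)) * fs
  if (!pad && max_shift > 0.5) {
    rlang::abort("Delayed PSF copies spill outside the time window and pad = FALSE.",
                 class = "sparsus_error_truncation")
  }
  n_fft <- 2^ceiling(log2(2 * n_t + 2 * ceiling(max_shift) + 4))
  f <- c(0:(n_fft / 2), -(n_fft / 2 - 1):-1) / n_fft * fs

  A <- matrix(0, n_t * n_el, grid$n_points)
  for (k in seq_len(n_el)) {
    trace <- rf$samples[, cols_in_rec[k]]
    # short raised-cosine taper guards against edge discontinuities
    nt_tap <- min(4L, n_t %/% 4L)
    if (nt_tap > 0) {
      w <- 0.5 * (1 - cos(pi * (seq_len(nt_tap) - 0.5) / nt_tap))
      trace[seq_len(nt_tap)] <- trace[seq_len(nt_tap)] * w
      trace[n_t + 1 - seq_len(nt_tap)] <- trace[n_t + 1 - seq_len(nt_tap)] * w
    }
    spec <- stats::fft(c(trace, numeric(n_fft - n_t)))
    # one inverse FFT per grid point, batched as columns
    ramps <- exp(-2i * pi * outer(f, dt[, k]))
    shifted <- Re(stats::mvfft(ramps * spec, inverse = TRUE)) / n_fft
    A[(k - 1) * n_t + seq_len(n_t), ] <- shifted[seq_len(n_t), ]
  }

  psf_norm <- sqrt(sum(rf$samples[, cols_in_rec]^2))
  col_energy <- sqrt(colSums(A^2)) / psf_norm
  if (pad && min(col_energy) < sqrt(1 - 0.005)) {
    rlang::warn(sprintf(
      "Forward-model columns lose up to %.2f%% of the PSF energy to window truncation.",
      100 * (1 - min(col_energy)^2)
    ))
  }

  structure(
    list(
      A = A, time_axis = rf_times(rf), grid = grid,
      subset = list(indices = use_idx, scheme = "model", n_total = probe$n_elements),
      probe = probe, source = psf$source, modality = psf$modality,
      fs = fs, n_t = n_t, col_energy = col_energy,
      cache = new.env(parent = emptyenv())
    ),
    class = "sparsus_model"
  )
}

#' @export
print.sparsus_model <- function(x, ...) {
  cat(sprintf(
    "<sparsus_model> A: %d x %d (%d elements x %d samples), %s\n",
    nrow(x$A), ncol(x$A), length(x$subset$indices), x$n_t, x$modality
  ))
  invisible(x)
}

#' Precompute and cache the Gram matrix of a forward model
#'
#' Attaches `G = t(A) %*% A` to the model's cache. The FISTA solver uses it
#' to run every iteration in the (much smaller) grid space, which pays off
#' when the same model is inverted for many noise realizations.
#'
#' @param model A `sparsus_model`.
#' @return `G` (invisibly); the model caches it by reference.
#' @export
precompute_gram <- function(model) {
  if (is.null(model$cache$G)) {
    model$cache$G <- crossprod(model$A)
  }
  invisible(model$cache$G)
}

#' Numerical diagnostics of a forward model
#'
#' Reports the numerical rank (singular values above
#' `max(dim(A)) * eps * sigma_max`, the conventional default tolerance),
#' the mutual coherence (largest normalized inner product between distinct
#' columns), and the condition number, flagging the underdetermined regime
#' `rank < n`.
#'
#' @param model A `sparsus_model` (or plain matrix).
#' @return A list with `m`, `n`, `rank`, `tolerance`, `mutual_coherence`,
#'   `condition_number`, `underdetermined`.
#' @export
model_diagnostics <- function(model) {
  A <- if (inherits(model, "sparsus_model")) model$A else model
  sv <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * sv[1]
  rk <- sum(sv > tol)
  cn <- crossprod(A)
  nrm <- sqrt(diag(cn))
  cn <- cn / outer(nrm, nrm)
  diag(cn) <- 0
  list(
    m = nrow(A), n = ncol(A), rank = rk, tolerance = tol,
    mutual_coherence = max(abs(cn)),
    condition_number = sv[1] / sv[max(rk, 1)],
    underdetermined = rk < ncol(A)
  )
}
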