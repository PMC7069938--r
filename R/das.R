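#' Delay-and-sum beamforming on a reconstruction grid
#'
#' The conventional diffraction-limited baseline: for every grid point, the
#' RF samples at the modality-appropriate time of flight (one-way for
#' photoacoustics; plane-wave emission delay `z/c` plus the return path for
#' plane-wave ultrasound) are summed across the active elements, with
#' linear interpolation between time samples. No apodization and no
#' f-number gating are applied. The envelope is the analytic-signal
#' magnitude taken along the depth axis of each lateral line, the standard
#' B-mode convention.
#'
#' @param rf A `sparsus_rf` record whose columns match `subset`.
#' @param probe A [make_linear_probe()] geometry.
#' @param subset A [select_elements()] subset (default: the record's).
#' @param grid A [make_grid()] reconstruction grid.
#' @param c0 Speed of sound, m/s.
#' @return A `sparsus_das`: list with `amplitude` (signed `n_z x n_x` map),
#'   `envelope` (nonnegative), `grid`.
#' @export
das_reconstruct <- function(rf, probe, subset = NULL, grid, c0 = 1500) {
  if (is.null(subset)) subset <- rf$subset
  idx <- subset$indices
  if (length(idx) != ncol(rf$samples)) {
    rlang::abort("Subset size does not match the number of RF channels.",
                 class = "sparsus_error_dimension")
  }
  co <- grid_coords(grid)
  tau <- arrival_times(co$x, co$z, probe$element_x[idx], probe$element_z[idx],
                       rf$modality, c0)
  n_t <- nrow(rf$samples)
  pos <- (tau - rf$t0) * rf$fs + 1
  acc <- numeric(grid$n_points)
  n_out <- 0L
  for (k in seq_along(idx)) {
    p <- pos[, k]
    i0 <- floor(p)
    frac <- p - i0
    ok <- i0 >= 1 & i0 < n_t
    n_out <- n_out + sum(!ok)
    v <- numeric(grid$n_points)
    v[ok] <- rf$samples[i0[ok], k] * (1 - frac[ok]) +
      rf$samples[i0[ok] + 1, k] * frac[ok]
    acc <- acc + v
  }
  if (n_out > 0) {
    rlang::warn(sprintf(
      "%d grid-point/element times of flight fall outside the RF window (zero contribution).",
      n_out
    ))
  }
  amp <- grid_image(acc, grid)
  env <- if (grid$n_z >= 4) envelope(amp) else abs(amp)
  structure(
    list(amplitude = amp, envelope = env, grid = grid),
    class = "sparsus_das"
  )
}

#' @export
print.sparsus_das <- function(x, ...) {
  cat(sprintf("<sparsus_das> %d x %d image, peak envelope %.4g\n",
              x$grid$n_z, x$grid$n_x, max(x$envelope)))
  invisible(x)
}
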