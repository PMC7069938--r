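#' Gaussian-modulated transmit/receive pulse
#'
#' Models the system impulse waveform as a Gaussian-modulated sinusoid,
#' `p(t) = exp(-t^2 / (2 sigma_t^2)) * cos(2 pi f_c t)`, whose -6 dB
#' amplitude-spectrum full width equals `fractional_bandwidth * f_c`. The
#' envelope peak is 1 at the reference time `t = 0`.
#'
#' @param center_frequency Center frequency in Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth (dimensionless).
#' @param sampling_rate Sampling rate in Hz; must exceed the Nyquist
#'   requirement `2 * center_frequency * (1 + fractional_bandwidth)`.
#'
#' @return A `sparsus_pulse`: list with `fc`, `fbw`, `fs`, `sigma_t` (envelope
#'   standard deviation, s), and a sampled `waveform` tibble (`t`, `amplitude`)
#'   over +/- 6 sigma_t.
#' @export
make_pulse <- function(center_frequency = 15e6, fractional_bandwidth = 0.93,
                       sampling_rate = 62.5e6) {
  stopifnot(center_frequency > 0, fractional_bandwidth > 0, sampling_rate > 0)
  if (sampling_rate <= 2 * center_frequency * (1 + fractional_bandwidth)) {
    rlang::abort(
      sprintf(
        "Sampling rate %.3g Hz violates the Nyquist guard 2 * fc * (1 + bw) = %.3g Hz.",
        sampling_rate, 2 * center_frequency * (1 + fractional_bandwidth)
      ),
      class = "sparsus_error_sampling"
    )
  }
  # -6 dB width of the Gaussian amplitude spectrum: 2 sqrt(2 ln 2) sigma_f
  sigma_f <- fractional_bandwidth * center_frequency / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  n_half <- ceiling(6 * sigma_t * sampling_rate)
  tt <- (-n_half:n_half) / sampling_rate # symmetric grid through t = 0
  p <- structure(
    list(
      fc = center_frequency, fbw = fractional_bandwidth, fs = sampling_rate,
      sigma_t = sigma_t,
      waveform = tibble::tibble(
        t = tt,
        amplitude = exp(-tt^2 / (2 * sigma_t^2)) * cos(2 * pi * center_frequency * tt)
      )
    ),
    class = "sparsus_pulse"
  )
  p
}

#' Evaluate a pulse waveform at arbitrary times
#'
#' @param pulse A [make_pulse()] object.
#' @param t Times in seconds (vector or matrix), relative to the envelope peak.
#' @return Amplitudes with the shape of `t`.
#' @export
pulse_eval <- function(pulse, t) {
  exp(-t^2 / (2 * pulse$sigma_t^2)) * cos(2 * pi * pulse$fc * t)
}

#' @export
print.sparsus_pulse <- function(x, ...) {
  cat(sprintf(
    "<sparsus_pulse> fc %.1f MHz, -6 dB bandwidth %.0f%%, fs %.1f MHz\n",
    x$fc / 1e6, x$fbw * 100, x$fs / 1e6
  ))
  invisible(x)
}

#' Define a set of point sources
#'
#' @param x,z Source coordinates in meters.
#' @param amplitude Nonnegative per-source weights (recycled).
#' @return A tibble with columns `x`, `z`, `amplitude`.
#' @export
source_set <- function(x, z, amplitude = 1) {
  stopifnot(length(x) == length(z), all(amplitude >= 0))
  tibble::tibble(x = x, z = z, amplitude = rep_len(amplitude, length(x)))
}

#' Five point sources at the standard microchannel layout
#'
#' Lateral row of equispaced point sources centered on `x = 0` at a fixed
#' depth, mimicking a cross-section through parallel microfluidic channels.
#'
#' @param n_sources Number of sources.
#' @param spacing Center-to-center distance in meters (default 125 um).
#' @param depth Source depth in meters (default 15 mm, the elevation focus).
#' @return A [source_set()] tibble.
#' @export
microchannel_scene <- function(n_sources = 5, spacing = 125e-6, depth = 15e-3) {
  xs <- (seq_len(n_sources) - (n_sources + 1) / 2) * spacing
  source_set(xs, rep(depth, n_sources))
}

# One-way (PA) or plane-wave (US) arrival times, seconds.
# Returns an n_sources x n_elements matrix.
arrival_times <- function(src_x, src_z, el_x, el_z, modality, c0) {
  d <- sqrt(outer(src_x, el_x, "-")^2 + outer(src_z, el_z, "-")^2)
  delta_us <- if (modality == "US_planewave") 1 else 0
  delta_us * src_z / c0 + d / c0
}

#' Synthesize RF channel data for point sources on a linear array
#'
#' Models each element's received trace as the superposition of time-delayed
#' copies of a common pulse, one per point source: one-way time of flight for
#' photoacoustics, plane-wave emission delay `z/c` plus the return path for
#' single plane-wave ultrasound. Delays are exact (the pulse is evaluated
#' analytically at shifted times), so the synthesis carries no resampling
#' error and serves as an independent oracle for the matrix-based model.
#'
#' @param sources A [source_set()] tibble.
#' @param probe A [make_linear_probe()] geometry.
#' @param subset A [select_elements()] subset (default: all elements).
#' @param pulse A [make_pulse()] object.
#' @param modality `"PA"` or `"US_planewave"`.
#' @param c0 Speed of sound, m/s.
#' @param window Optional time window `c(t_start, t_end)` in seconds. When
#'   omitted, a window covering every arrival with a 6 sigma_t pulse margin
#'   is used. If a supplied window would truncate any source's pulse (within
#'   a 4 sigma_t guard) the function refuses with a truncation error.
#'
#' @return A `sparsus_rf`: list with `samples` (time x element matrix), `fs`,
#'   `t0`, `modality`, `probe`, `subset`.
#' @export
synthesize_rf <- function(sources, probe, subset = NULL, pulse = make_pulse(),
                          modality = c("PA", "US_planewave"), c0 = 1500,
                          window = NULL) {
  modality <- match.arg(modality)
  if (is.null(subset)) subset <- select_elements(probe, probe$n_elements, "all")
  ex <- probe$element_x[subset$indices]
  ez <- probe$element_z[subset$indices]
  ta <- arrival_times(sources$x, sources$z, ex, ez, modality, c0)
  guard <- 4 * pulse$sigma_t
  if (is.null(window)) {
    window <- c(min(ta) - 6 * pulse$sigma_t, max(ta) + 6 * pulse$sigma_t)
  } else if (min(ta) < window[1] + guard || max(ta) > window[2] - guard) {
    rlang::abort(
      "Source arrivals fall outside the requested time window (4 sigma_t guard); enlarge the window.",
      class = "sparsus_error_truncation"
    )
  }
  fs <- pulse$fs
  n_t <- ceiling((window[2] - window[1]) * fs) + 1
  t <- window[1] + (seq_len(n_t) - 1) / fs
  samples <- matrix(0, n_t, length(ex))
  for (j in seq_len(nrow(sources))) {
    if (sources$amplitude[j] == 0) next
    dt <- outer(t, ta[j, ], "-")
    samples <- samples + sources$amplitude[j] * pulse_eval(pulse, dt)
  }
  structure(
    list(samples = samples, fs = fs, t0 = window[1], modality = modality,
         probe = probe, subset = subset),
    class = "sparsus_rf"
  )
}

#' @export
print.sparsus_rf <- function(x, ...) {
  cat(sprintf(
    "<sparsus_rf> %d samples x %d elements, fs %.1f MHz, t0 %.3f us, %s\n",
    nrow(x$samples), ncol(x$samples), x$fs / 1e6, x$t0 * 1e6, x$modality
  ))
  invisible(x)
}

#' Sample times of an RF record
#' @param rf A `sparsus_rf` object.
#' @return Vector of absolute sample times in seconds.
#' @export
rf_times <- function(rf) {
  rf$t0 + (seq_len(nrow(rf$samples)) - 1) / rf$fs
}

#' Trim an RF record to a fixed number of time samples
#'
#' Utility for reproducing fixed-size data vectors (e.g. a 36-sample window
#' per element). Keeps samples `start .. start + n_samples - 1`.
#'
#' @param rf A `sparsus_rf` object.
#' @param n_samples Number of samples to keep.
#' @param start First sample index to keep (1-based).
#' @return The trimmed `sparsus_rf`.
#' @export
trim_rf <- function(rf, n_samples, start = 1L) {
  stopifnot(start >= 1, start + n_samples - 1 <= nrow(rf$samples))
  rf$t0 <- rf$t0 + (start - 1) / rf$fs
  rf$samples <- rf$samples[start:(start + n_samples - 1), , drop = FALSE]
  rf
}

#' Add white Gaussian measurement noise to an RF record
#'
#' @param rf A `sparsus_rf` object.
#' @param sigma_n Noise rms (standard deviation) in the same arbitrary
#'   voltage units as the samples.
#' @param seed Integer seed; the draw is bit-reproducible.
#' @return The noisy `sparsus_rf`.
#' @export
add_noise <- function(rf, sigma_n, seed = 1L) {
  stopifnot(sigma_n >= 0)
  if (sigma_n == 0) return(rf)
  noise <- withr::with_seed(
    as.integer(seed),
    matrix(stats::rnorm(length(rf$samples), 0, sigma_n),
           nrow(rf$samples), ncol(rf$samples))
  )
  rf$samples <- rf$samples + noise
  rf
}

#' Signal-to-noise ratio of an RF record
#'
#' SNR is defined as the peak absolute RF amplitude divided by the noise
#' standard deviation estimated over a signal-free block of time samples.
#'
#' @param rf A `sparsus_rf` object.
#' @param signal_free_region Integer vector of time-sample indices known to
#'   contain no signal.
#' @return A single dimensionless SNR; `Inf` when the region has zero
#'   variance.
#' @export
measure_snr <- function(rf, signal_free_region) {
  stopifnot(length(signal_free_region) >= 2,
            all(signal_free_region >= 1),
            all(signal_free_region <= nrow(rf$samples)))
  noise_sd <- stats::sd(as.vector(rf$samples[signal_free_region, ]))
  peak <- max(abs(rf$samples))
  if (noise_sd == 0) return(Inf)
  peak / noise_sd
}

#' Analytic-signal envelope of a sampled trace
#'
#' Magnitude of the analytic signal computed with the FFT (positive
#' frequencies doubled, negative zeroed).
#'
#' @param x Numeric vector (length >= 4) or a matrix whose columns are
#'   traces.
#' @return Nonnegative envelope with the shape of `x`.
#' @export
envelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, envelope))
  n <- length(x)
  stopifnot(n >= 4)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Lateral full width at half maximum of an image
#'
#' Measures the conventional resolution metric: the width at half maximum of
#' the lateral profile through the image's unique global maximum, with
#' linear interpolation between grid samples.
#'
#' @param image An `n_z x n_x` nonnegative amplitude map (rows = depth).
#' @param x Lateral coordinates of the image columns in meters, or a
#'   `sparsus_grid` whose `x` is used.
#' @return FWHM in meters.
#' @export
lateral_fwhm <- function(image, x) {
  if (inherits(x, "sparsus_grid")) x <- x$x
  stopifnot(ncol(image) == length(x))
  pk <- which(image == max(image))
  if (length(pk) != 1L) {
    rlang::abort("Image must have a unique global maximum.",
                 class = "sparsus_error_fwhm")
  }
  iz <- (pk - 1) %% nrow(image) + 1
  ix <- (pk - 1) %/% nrow(image) + 1
  prof <- image[iz, ]
  half <- prof[ix] / 2
  cross <- function(side_idx) {
    # walk from the peak outward until the profile falls below half max
    for (i in seq_along(side_idx)[-1]) {
      a <- side_idx[i - 1]; b <- side_idx[i]
      if (prof[b] <= half) {
        frac <- (prof[a] - half) / (prof[a] - prof[b])
        return(x[a] + frac * (x[b] - x[a]))
      }
    }
    rlang::abort("Lateral profile never falls below half maximum inside the grid.",
                 class = "sparsus_error_fwhm")
  }
  x_right <- cross(ix:length(x))
  x_left <- cross(ix:1)
  abs(x_right - x_left)
}
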