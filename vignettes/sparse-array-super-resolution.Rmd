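---
title: "Model-based super-resolution for sparse linear arrays: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based super-resolution for sparse linear arrays: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The imaging problem

A linear ultrasound array observes a sparse scene — a handful of point-like
absorbers (photoacoustics, PA) or scatterers (single plane-wave ultrasound,
US) — at a depth where the diffraction-limited lateral resolution,
`lambda * z / D` for wavelength `lambda`, depth `z` and aperture `D`, is
larger than the spacing between the structures. Conventional delay-and-sum
(DAS) beamforming then shows a single unresolved bar. When the scene is
known to be sparse, the image can instead be recovered by inverting a
linear forward model with an l1 penalty, which concentrates the estimate
on few grid cells and separates structures well below the diffraction
limit. Because the prior, not the aperture sampling density, carries the
resolution, most of the array's elements can be dropped — as long as the
first and last elements are kept, so the aperture (and with it the
conditioning of the comparison) stays fixed.

## Forward model from a single PSF

Under linearity, the vectorized RF data obey `S = A T` where column `p` of
`A` holds the RF response of a unit source at grid point `p`. `sparsus`
builds every column from **one** point-spread-function (PSF) record — the
time-by-element RF matrix of a single point source — by assuming that
responses of different points differ only by their per-element arrival
time. The applied delay between grid point `i` and the calibration source
`j` seen from element `k` is the physical arrival-time difference

    dt = delta_US * (z_i - z_j) / c + (|r_i - r_k| - |r_j - r_k|) / c

with `delta_US = 1` for plane-wave US (the emitted plane wave reaches
depth `z` after `z/c`) and `0` for PA. The sign convention is fixed by the
package's oracle test: the column built for point `i` must equal, to
fractional-delay accuracy, an independently synthesized RF record of a
unit source at `i`.

Delays are applied as frequency-domain phase ramps on zero-padded FFTs of
each element trace, because at a 62.5 MHz sampling rate one sample
(16 ns, i.e. 24 um of one-way path) is comparable to the 12.5 um grid
step: nearest-sample shifting would alias the grid. The padded length is
chosen so circularly wrapped content never re-enters the kept window; a
4-sample raised-cosine taper guards the trace edges. Content shifted
outside the window is dropped, with a warning once the worst-case column
energy loss exceeds 0.5%.

## Inversion

The estimate solves

    T_hat = argmin_T  ||S - A T||_2^2 + alpha^2 * ||T||_1

with the objective exactly in this scaling (no 1/2 on the quadratic term),
so the gradient of the smooth part is `2 A' (A T - S)`, its Lipschitz
constant `L = 2 ||A||_2^2` (estimated by power iteration with a safety
factor), the proximal threshold per step is `alpha^2 / L`, and the
smallest `alpha^2` producing the all-zero solution is
`2 * max |A' S|`. The solver is the monotone variant of FISTA with an
adaptive restart: when the momentum step would increase the objective, the
iterate is kept and the momentum is reset. Plain FISTA is not monotone,
and on these highly coherent systems its objective ripples can trigger a
relative-change stopping rule far from optimality; the restart removes
both problems at no extra cost per iteration. Convergence is declared when
the relative objective change of an accepted step falls below the
tolerance (default `1e-8`, capped at 2000 iterations for standalone
solves; the Monte-Carlo driver uses `1e-7` / 1500, which the optimality
tests show is ample at the study's problem sizes). Iterations run in the
`n`-dimensional grid space via a cached Gram matrix `A'A`, exploiting
iterate sparsity, so one iteration costs far less than a pass over the
`m x n` matrix.

A nonnegativity flag (one-sided threshold) exists but is off by default:
PA absorption is physically nonnegative, but the US scattering contrast is
modeled as a signed amplitude, and the reference procedure states no
constraint.

### Choosing alpha

The regularization weight is, by the method's nature, a heuristic: it is
tuned until the image looks like a plausible sparse scene. The package
makes that reproducible: `choose_alpha()` scans `alpha^2` over a
logarithmic grid of fractions (default 8 points from 0.5 down to 0.01) of
`alpha_max^2`, warm-starting from large to small `alpha`, and selects the
smallest `alpha` whose solution stays within a support budget (default
25 cells — five cells per expected structure for the five-source scene).
Small supports at large `alpha` distort positions; very small `alpha`
fits noise; the budget rule follows the edge of the compact-support
regime. The budget is enforced on the *effective* support — the smallest
number of cells carrying 95% of the solution's l1 mass — because the raw
nonzero count is inflated by near-zero cells and oscillates across noise
realizations right at the budget boundary, making the selected `alpha`
erratic between realizations of the same condition. In the
Monte-Carlo driver `alpha` is chosen per (N, SNR) cell as the median of
the scan's choice over three dedicated calibration realizations, then
held fixed for that cell's scored realizations, mirroring per-condition
rather than per-image tuning; the value used is recorded in the sweep
table. The C surface is materially sensitive to this heuristic — an
unavoidable degree of freedom the reference leaves unspecified.

## The synthetic-data generator

`synthesize_rf()` implements exactly the generative assumptions of the
forward model: every element receives time-delayed copies of one common
pulse — no directivity, no attenuation, no element-to-element impulse
response variation, no speed-of-sound heterogeneity. The pulse is a
Gaussian-modulated sinusoid evaluated analytically at the delayed times,
so the generator is an oracle for the matrix path with no shared
resampling code. Defaults model the reference hardware:

* center frequency 15 MHz; sampling rate 62.5 MHz (the standard 4x
  oversampling of that acquisition platform);
* -6 dB fractional bandwidth 0.93. The probe is a wide-band CMUT array
  whose nominal band, 8-22 MHz, spans 93% of the center frequency; a
  narrow-band choice (e.g. 0.6) lengthens the pulse, strengthens column
  coherence along both axes, and visibly degrades the sparse recovery at
  intermediate SNR, so the bandwidth is the single most influential
  unstated parameter of the study;
* speed of sound 1500 m/s (water); five sources 125 um apart at the
  15 mm elevation focus; noise is i.i.d. zero-mean Gaussian with rms
  `sigma_n = 30` added to every sample, and SNR is imposed by scaling the
  noiseless signal so its peak over `sigma_n` hits the target — the
  stated definition (peak RF amplitude over the noise deviation in a
  signal-free region) is measured by `measure_snr()`.

The reconstruction window is a 61 x 13 grid (12.5 um step) spanning
0.75 mm laterally and 0.15 mm axially around the focus — 793 unknowns,
matching the reference reconstruction size; only the total count is
printed there, so the aspect ratio is this package's choice. The time
window is auto-sized to contain every grid point's arrival at every
element with a 6 sigma_t pulse margin (about 100 samples per element at
the defaults). A fixed-length window option (`n_time_samples`) exists; a
36-sample window reproduces the reference's printed data-vector length
(m = 4608 at 128 elements) but cannot contain the 0.86 us arrival spread
across the 12.7 mm aperture at 62.5 MHz, and measurably cripples every
reconstruction, so the full window is the default and the 36-sample
record is treated as a bookkeeping reference only.

What the generator does **not** emulate: the elastic layer above the
real microchannels (neglected in the reference's own model), transducer
directivity and bandwidth mismatch between calibration and scene records,
out-of-plane scattering, or any forward-model error — the PSF used to
build `A` is exact up to fractional-delay interpolation. Passing tests
therefore demonstrate the correctness of the algorithmic chain, not
robustness to the model mismatch that dominates real acquisitions.

## Post-processing and the quality metric

Reconstructions (and the ideal object: value 1 in the five true cells,
ties to the lower-index cell) are smoothed with an isotropic Gaussian of
sigma 12.5 um — one grid step, chosen to smooth point-like l1 output
without merging structures 125 um apart — truncated at 4 sigma with zero
padding, interpolated to a 3.125 um grid by two-pass cubic splines, and
normalized to a unit maximum. Quality is the plain normalized inner
product C between the two processed images (no mean subtraction): 1 for
proportional images, 0 for disjoint support, scale-invariant. An all-zero
reconstruction is scored C = 0 rather than undefined. Peak spacing uses
prominence-ranked local maxima (default prominence threshold 5% of the
profile maximum) along the lateral profile through the global peak;
"unresolved" is the failure to find the expected number of prominent
maxima.

## The Monte-Carlo study

`run_sweep()` maps mean C over element counts N (regular subsets with
fixed endpoints) and SNR targets, 25-100 realizations per cell. Seeds
derive from `(base_seed, N, realization)` through a Lehmer-style mixing
kept below 2^31; the SNR index is deliberately excluded so that cells
along the SNR axis share noise realizations, making the
monotonicity-in-SNR comparison a paired one. `minimal_elements()`
interpolates mean C linearly in log SNR; `fit_sqrt_n_contour()` extracts
the SNR achieving a target C per N and fits `SNR = a * sqrt(N)`,
excluding N = 2, where the two-element geometry demands disproportionate
SNR and falls off the square-root trend; the reported R^2 is the
uncentered (through-origin) coefficient of determination.

Problem sizes used by the test suite: unit tests run on probes of 8-65
elements and grids of 25-125 points; the study-level tests use the full
128-element, 793-point configuration with 25 realizations per sweep cell
and 100 realizations for the three reference (N, SNR) conditions.

## Known limitations

* The reference's pulse bandwidth, sampling window and alpha heuristic
  are unstated; mean C at intermediate SNR shifts by several tenths
  across plausible settings of these, while the qualitative structure
  (monotone trends, square-root contour, minimal element count, the
  high- and low-SNR plateaus) is stable.
* The axial direction is nearly unresolved in PA at this geometry (the
  one-way bandwidth gives ~170 um axial correlation against a 150 um
  deep grid), so l1 mass may legitimately migrate within a depth column.
* Dense `A` storage (about 10 MB at the defaults) is deliberate; an
  implicit-operator backend would be needed for 3D or much finer grids.
* The solver handles a single receive event; coherent compounding over
  plane-wave angles and per-point measured PSF libraries are out of
  scope.
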