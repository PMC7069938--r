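# sparsus

Sparsity-constrained, model-based super-resolution reconstruction for
photoacoustic (PA) and single plane-wave ultrasound (US) imaging with
sparse linear transducer arrays.

## The problem

A linear array imaging point-like structures at depth `z` resolves
laterally no better than the diffraction limit `lambda * z / D`
(wavelength `lambda`, aperture `D`). At 15 MHz, 15 mm depth and a
12.7 mm aperture that is roughly 120-155 um — too coarse to separate
structures 125 um apart, which delay-and-sum (DAS) beamforming renders as
one unresolved bar. When the scene is sparse, reconstruction can instead
be posed as an inverse problem with an l1 prior, which separates
structures well below the diffraction limit and keeps working when most
array elements are discarded, provided the two outermost elements are
kept so the aperture is unchanged. The package is aimed at imaging
scientists who want a complete, reproducible reference implementation of
that pipeline, including the Monte-Carlo study that maps reconstruction
quality against SNR and element count.

## The method

1. **Forward model from a single PSF.** The vectorized RF data obey
   `S = A T`, where column `p` of `A` is the RF response of a unit source
   at reconstruction-grid point `p`. All columns are derived from one
   measured (or simulated) point-spread-function record by per-element
   time shifts `dt = delta_US (z_i - z_j)/c + (|r_i - r_k| - |r_j - r_k|)/c`
   (`delta_US = 1` for plane-wave US, 0 for PA), applied with sub-sample
   accuracy as frequency-domain phase ramps.
2. **Sparse inversion.** `T_hat = argmin_T ||S - A T||_2^2 + alpha^2 ||T||_1`,
   solved with a monotone FISTA (adaptive restart, 1/L step from a
   safeguarded power iteration). `alpha` is selected by a reproducible
   scan over fractions of `alpha_max` with a support-size budget.
3. **Assessment.** Images are Gaussian-smoothed (sigma 12.5 um),
   interpolated to 3.125 um and peak-normalized; quality is the
   normalized inner product `C` against the identically processed ideal
   object, and resolution is checked by prominence-ranked peak spacing.
   DAS (`das_reconstruct()`) provides the diffraction-limited baseline.

## Worked example

Five point sources 125 um apart at 15 mm depth, imaged by a 16-element
sparse subset (of 128, endpoints fixed) at SNR 150:

```r
library(sparsus)

cfg <- sweep_config()              # the default study conditions
ctx <- simstudy_context(cfg)
res <- run_cell(N = 16, target_snr = 150, cfg, realization = 1, ctx = ctx)

glance(res$recon)
peak_spacing(res$display, expected_peaks = 5)$mean_spacing * 1e6
res$C
```

```
#> # A tibble: 1 x 6
#>   alpha support_size n_iters converged objective residual_norm
#>   <dbl>        <int>   <int> <lgl>         <dbl>         <dbl>
#> 1  26.2           22     333 TRUE       5807306.         1156.
#> [1] 125
#> [1] 0.9966573
```

The 16-element reconstruction places its support on the five true
sources (mean peak spacing 125 um, `C = 0.997`), while DAS on the same
data cannot separate them: `peak_spacing()` on the DAS image raises an
under-resolved error. `run_sweep()` repeats this over a grid of element
counts and SNRs, `minimal_elements()` reports the smallest N reaching a
target quality, and `fit_sqrt_n_contour()` fits the `SNR ~ sqrt(N)`
iso-quality trend. `autoplot()` methods display RF images, displays and
sweep heat maps; a thin CLI (`exec/sparsus`) exposes `synth`, `das`,
`sparse` and `sweep` subcommands over YAML configurations.

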