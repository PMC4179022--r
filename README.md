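# voltkit

Post-acquisition processing of voltammetric and amperometric data in R.

Electrochemical sensing produces current–potential (or current–time)
records whose scientific content — peak currents and potentials, wave
heights and half-wave potentials, electron counts, the balance of kinetic,
diffusion and capacitive current — has to be extracted *after* the
measurement. Instrument software covers only part of that workflow, each
vendor exports a different ASCII flavour, and the more powerful
transformations live scattered across the literature. voltkit collects the
whole post-processing chain into one scriptable, tested package for
electroanalytical chemists and biosensor developers:

* **Tolerant ASCII parsing** of potentiostat exports (CHI-, BASi-,
  Autolab-style and generic XY text; mixed delimiters, decimal commas,
  junk headers, multi-curve layouts), plus a canonical CSV writer.
* **Pretreatment**: Savitzky–Golay smoothing, blank subtraction,
  uncompensated-resistance (Ru) and double-layer-capacitance (C_DL)
  correction, and conversion to dimensionless current.
* **Transforms**: derivative, integral, and the half-order pair —
  semiintegration via the Grünwald–Letnikov convolution
  (`m_j = sqrt(dt) * sum_k w_k I_{j-k}`, `w_k = w_{k-1}(k-1/2)/k`), which
  turns a reversible voltammogram into a wave-shaped "neopolarogram", and
  semidifferentiation (semiintegration followed by differentiation).
* **Elimination voltammetry**: for voltammograms recorded at relative scan
  rates `rho_i`, solves `sum_i a_i rho_i^p = {1 conserved, 0 eliminated}`
  over the component powers (kinetic `v^0`, diffusion `v^1/2`, capacitive
  `v^1`) and applies `f(I) = sum_i a_i I_i(E)` — including all six
  standard functions E1–E6 for any rate set.
* **Peak and wave evaluation** against cursor-defined baselines: chord
  baselines for DPV/SWV, tangent baselines for CV, flat / skewed /
  separate baselines for waves and amperometric staircases, with CSV
  export of `(E, I)` result rows.
* **Synthetic signals** with known ground truth (reversible Nernstian CVs
  built through their semiintegral, three-component scan-rate mixtures,
  Gaussian peaks, sigmoid waves, staircase amperograms, Ru/C_DL forward
  distortion, instrument-dialect writers) so every claim is testable
  without instrument data.

Everything is tibble-first: voltammograms are tibbles with metadata
attributes, results come back as one-row tibbles, elimination fits have
`tidy()`/`glance()` methods, and every result type has an `autoplot()`.

## Worked example

Count transferred electrons from a (synthetic, noisy) reversible CV and
solve the classical elimination function:

```r
library(voltkit)

cv <- synth_cv(n_points = 2049, noise_sigma = 2e-8, seed = 7)
params <- attr(cv, "params")   # A = 0.1 cm2, C = 1 mM, D = 1e-5 cm2/s, v = 0.1 V/s

psi <- cv |>
  smooth_current(poly_order = 3, side_points = 7) |>
  to_dimensionless(params)
neo <- semiintegrate(psi)      # the neopolarogram
half <- (nrow(neo) + 1) %/% 2
round(max(neo$current[1:half]), 3)
#> [1] 1
```

The plateau of the semiintegrated dimensionless record reads out the
apparent number of transferred electrons — here 1, as constructed.

```r
fit <- solve_elimination(
  elimination_spec("diffusion", c("kinetic", "capacitive"), c(0.5, 1, 2)))
tidy(fit)
#> # A tibble: 3 × 2
#>   rel_rate coefficient
#>      <dbl>       <dbl>
#> 1      0.5      -11.7
#> 2      1         17.5
#> 3      2         -5.83
```

These are the textbook coefficients (−11.657, 17.485, −5.8284) of the
scan-rate trio `0.5v : 1v : 2v` combination in which only the diffusion
current survives; `apply_elimination()` applies them to a measured trio.
Peak evaluation on the forward sweep with a tangent baseline:

```r
find_peak(split_cycles(psi)[[1]], left = -0.15, right = 0.2,
          baseline = "tangent", tangent_window = 0.02)
#> # A tibble: 1 × 6
#>   peak_E peak_I baseline_slope baseline_intercept baseline_kind iupac
#>    <dbl>  <dbl>          <dbl>              <dbl> <chr>         <lgl>
#> 1 0.0283 0.423           0.116             0.0203 tangent       TRUE
```

`peak_I` is the baseline-subtracted dimensionless peak height; 0.42 ± a
few percent is what a reversible one-electron wave should give after foot
tangent subtraction (the raw peak function maximum is 0.446).

See `vignettes/voltkit-methods.Rmd` for the models, conventions
(orientation, IR-sign, dimensionless time) and numerical choices.

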