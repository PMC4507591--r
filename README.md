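# thzchem

Chemometric discrimination of sample classes from terahertz time-domain
spectroscopy (THz-TDS), built for the crop/food-authentication setting
where eight wheat varieties are told apart by the minor differences in
their pellets' THz absorption spectra.

The package is aimed at spectroscopists and chemometricians who want a
fully testable, simulation-backed implementation of the classic
THz-TDS + PLS workflow:

1. **Simulate** reference and sample time-domain scans for K labelled
   classes with prescribed optics (featureless absorption rising with
   frequency, class-mean levels, a narrow class-discriminative band,
   smooth pellet-to-pellet deviation, instrument noise with a dynamic-range
   rolloff).
2. **Extract** optical constants from the sample/reference transfer
   function of a thin pellet,
   `H(ω) = [4n/(n+1)²]·exp(−iω(N−1)d/c) = ρ·e^{−iφ}` with `N = n − ik`
   and `k = αc/(2ω)`:

   ```
   n(ω) = 1 + φ(ω)·c/(ω·d)
   α(ω) = (2/d)·ln( 4n / (ρ·(n+1)²) )      [cm⁻¹]
   ```

   including FFT, frequency-unwrapped and zero-anchored phase, and
   resampling onto a 128-variable grid over 0.2–1.5 THz.
3. **Model** with a from-scratch NIPALS PLS1 regression (`X = TPᵀ + E`,
   `y = Tq + f`) on the class code 1..K as numeric response, with RMSEC /
   RMSECV / RMSEP and the reference-vs-predicted correlation R, leave-one-out
   cross-validation, stratified calibration/prediction splitting and
   nearest-class assignment.
4. **Select variables** with interval PLS (iPLS): equal-width intervals,
   one cross-validated PLS model per interval, minimum-RMSECV selection,
   compared against the full-spectrum model.

`pls_fit()` returns a classed model object with the usual `print`,
`summary`, `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
See the methods vignette (`vignettes/thz-chemometrics-methods.Rmd`) for
the model, its assumptions, and every numerical design choice.

## Worked example

```r
library(thzchem)

report <- run_thz_pipeline(default_run_config())
print(report)
```

```
THz discrimination run: 160 samples, 8 classes

Full-spectrum PLS (calibration set, leave-one-out CV):
          feature factors  r_cal rmsec   r_cv rmsecv  rmsep accuracy_cv
       absorption       5 0.9948 0.234 0.9932 0.2669 0.2435      0.9479
 refractive_index       5 0.6856 1.668 0.6043 1.8352 2.0440      0.1979
 accuracy_pred
        0.9375
        0.2188

iPLS on the absorption feature:
 interval_width n_intervals selected   f_lo   f_hi factors   r_cv rmsecv  rmsep
              4          32       15 0.7732 0.8039       4 0.9888 0.3427 0.3305
              8          16        8 0.7732 0.8449       5 0.9950 0.2281 0.2069
             16           8        4 0.6913 0.8449       5 0.9948 0.2342 0.2070
 accuracy_pred full_rmsecv
        0.8906      0.2669
        0.9844      0.2669
        0.9844      0.2669

best configuration: width 8, interval 8 (0.7732-0.8449 THz), RMSECV 0.2281 (full spectrum 0.2669)
```

Reading the table: the default experiment simulates 8 classes × 20 pellets,
extracts both features, and fits 5-factor PLS models on a stratified 96/64
calibration/prediction split. Absorption discriminates far better than
refractive index (RMSECV 0.27 vs 1.84 on the 1–8 class axis; 94% vs 20%
leave-one-out class accuracy). Width-8 iPLS finds interval 8 — variables
57–64, 0.773–0.845 THz, exactly where the simulator plants the
class-discriminative absorption band — and its 8-variable model beats the
128-variable full-spectrum model (RMSECV 0.228 vs 0.267, prediction-set
RMSEP 0.207 vs 0.244, 98% held-out accuracy).

Lower-level pieces are usable on their own:

```r
sm  <- simulate_spectra_matrix(wheat_class_profiles(), n_per_class = 10, seed = 1)
fit <- pls_fit(sm, ncomp = 5)          # NIPALS PLS1
summary(fit)
cv  <- loo_cv(sm, ncomp = 5)           # RMSECV, R
ip  <- run_ipls(sm, interval_width = 8, ncomp = 5)
plot(ip)                               # per-interval RMSECV bars
```

A command-line front end with `simulate` / `extract` / `fit` / `ipls` /
`predict` / `run` subcommands is in `inst/scripts/thzchem.R`; configs are
YAML (`read_run_config()` merges them over `default_run_config()`).

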