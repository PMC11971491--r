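# regfit

Linear-combination model fitting of in vivo ¹H MR spectroscopy (MRS) data
with **soft constraints (regularization) on the per-signal frequency and
line-broadening parameters**, plus everything needed to measure what that
regularization buys: a density-matrix basis simulator, a synthetic-spectrum
benchmark generator with known ground truth, and an evaluation harness.

## Who this is for

MRS methods researchers and analysts who want (a) a self-contained,
inspectable linear-combination fitter in R, or (b) a reproducible testbed
for studying how soft constraints on nonlinear fit parameters affect
metabolite quantification accuracy.

## The model

A measured spectrum is modeled as a non-negative combination of modified
basis signals plus a penalized-spline baseline. Each basis FID is adjusted
in the time domain,

```
M̃ᵢ(t) = Mᵢ(t) · l(t) · exp((2πi fᵢ − π dᵢ) t),
```

with a global Gaussian lineshape `l(t)` (asymmetry parameter `a_g`), a
global shift `f0` and phase `φ0`. Amplitudes are eliminated by variable
projection (non-negative on the basis block) and the nonlinear parameters
are refined by Levenberg–Marquardt. In the regularized mode the residual is
augmented with

```
σ·fᵢ/(f_reg·F0·10⁻⁶),   σ·(dᵢ − d_exp)/d_reg,   σ·a_g/a_reg,
```

where `σ` is the noise SD from a signal-free region, so each soft
constraint competes with the data on the noise scale. Defaults
(`f_reg = 0.004 ppm`, `d_exp = 0.78 Hz`, `d_reg = 0.156 Hz`,
`a_reg = 0.1`) mirror the widely used LCModel assumptions;
`d_exp`/`d_reg` come from `expected_broadening(2.0, 127.8)` and
`expected_broadening(0.4, 127.8)`. Three modes are provided: `reg`
(regularized), `noreg` (hard-boxed, unregularized comparison) and `ff`
(fixed individual frequencies).

See the methods vignette (`vignettes/regularized-mrs-fitting.Rmd`) for the
full model, the fitting schedule, and design rationale.

## Worked example

```r
library(regfit)
basis <- default_basis()                                   # 29 signals, simulated at 3 T
cfg   <- synth_config(n_spectra = 1, snr_targets = 30, master_seed = 42)
ds    <- generate_dataset(cfg, basis)                      # spectra + ground truth + water ref
fit   <- fit_spectrum(ds$spectra[[1]], basis, mode = "reg",
                      water_amplitude = water_amplitude(ds$water))
print(fit)
```

```
<fit_result 'snr30_0001' mode=reg: obj 1.22e+07, 107 iter, converged=TRUE>
   Ala    Asp     Cr   GABA    Glc    Glu    Gln    GSH    GPC    Gly    Lac
 0.000  2.030  4.617  0.144  0.753 11.268  3.421  1.290  1.131  0.812  0.000
   Ins    NAA   NAAG   PCho    PCr   PEth   sIns    Tau
 4.817 10.093  2.396  0.253  5.235  0.913  0.333  1.813
```

The printed values are water-scaled concentrations in mM (the synthetic
water reference has amplitude 25116 = WCONC × ATTH2O, which maps unit basis
amplitude to exactly 1 mM). At SNR 30 the fit recovers NAA (true 10.0 mM)
as 10.09 mM; summing squared errors over the 19 metabolites against the
generator's ground truth:

```r
sse_metabolites(fit$concentrations_mm, ds$truths[[1]]$concentrations_mm)$sse
#> 4.76   # mM², this spectrum
```

`run_benchmark()` repeats this over many spectra and modes and reports the
relative reduction in mean squared error from regularization with Welch
t-tests; `bland_altman()` summarizes between-method agreement.

## Command line

A thin CLI over the same functions ships in `inst/cli/regfit.R`:

```sh
Rscript inst/cli/regfit.R simulate --out data/ --n 50 --snr 10,30 --seed 1
Rscript inst/cli/regfit.R fit --data data/spectra.nii.gz --out fits/ --mode reg
Rscript inst/cli/regfit.R evaluate --results fits/ --truth data/truth.csv --out eval/
```

Spectra are read and written as NIfTI-MRS (complex FID, JSON header
extension); basis sets also round-trip through the LCModel `.basis` format.

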