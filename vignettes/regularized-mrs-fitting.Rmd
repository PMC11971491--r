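---
title: "Regularized linear-combination fitting of 1H MRS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized linear-combination fitting of 1H MRS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regfit)
```

## The problem

Quantifying brain metabolites from a single-voxel proton MR spectrum means
estimating, from one noisy complex FID, the amplitudes of 25-30 overlapping
reference signals together with roughly 60 nonlinear nuisance parameters:
a zero-order phase, a global frequency offset, a global lineshape (field
inhomogeneity), and - for every basis signal - a small individual frequency
shift $f_i$ and Lorentzian damping $d_i$ that absorb temperature, pH and
relaxation differences between the reference simulation and the tissue.
With so many weakly determined parameters the unpenalized least-squares
problem is close to ill-posed: low-amplitude signals trade frequency and
width adjustments against each other and against the baseline, and the fit
lands in poor local minima.

`regfit` implements the soft-constraint (Tikhonov) remedy: the individual
$f_i$, $d_i$ and the lineshape asymmetry $a_g$ are penalized toward
expected values inside the optimization, with the penalty scaled by the
spectral noise level so that the constraints relax automatically on good
data. The package contains everything needed to demonstrate the accuracy
gain end-to-end: a spin-system simulator that builds the basis, the fitting
engine with three variants (regularized, unregularized, fixed-frequency),
a synthetic-data generator with known ground truth, and the evaluation
harness.

## Forward model

Each basis FID $M_i(t)$ is modified in the time domain,

$$\tilde M_i(t) = M_i(t)\, l(t)\, e^{(2\pi i f_i - \pi d_i) t},$$

where $l(t)$ is the global lineshape envelope shared by all signals and
$d_i \ge 0$ produces a Lorentzian broadening of FWHM $d_i$ Hz. A global
shift $f_0$ and phase $\phi_0$ multiply all signals uniformly. The real
part of the Fourier-transformed modified basis, restricted to the fit range
(0.2-4.0 ppm by default), is concatenated with a cubic B-spline baseline
block $B$ (knot spacing 0.15 ppm, second-order difference penalty) and the
combined amplitude vector $\hat a$ is solved at every iterate by penalized
least squares with non-negativity on the basis block only (variable
projection). The modeled spectrum is $\hat y = [\,\tilde M\; B\,]\hat a$.

The global lineshape is a Gaussian of frequency-domain FWHM $w$,
$l(t) = \exp(-t^2 (\pi w)^2 / (4 \ln 2))$, optionally made asymmetric by
letting the width vary sigmoidally across the peak,
$w(\nu) = 2w/(1 + e^{-a_g \nu})$. The asymmetric kernel is constructed on
an oversampled frequency grid and converted to a one-sided time-domain
multiplier, which makes the $a_g \to 0$ limit match the symmetric Gaussian
path exactly (verified to about 1e-9 in the tests) and preserves peak area
(the envelope equals 1 at $t = 0$).

## The regularized objective

The fitted residual is the stack of the data misfit and the penalty terms

$$f_i^r = \frac{\sigma f_i}{f_{reg}\, F_0 \times 10^{-6}}, \qquad
  d_i^r = \frac{\sigma (d_i - d_{exp})}{d_{reg}}, \qquad
  a_g^r = \frac{\sigma a_g}{a_{reg}},$$

whose squared norm is minimized by Levenberg-Marquardt. $\sigma$ is the
noise SD of the real spectrum in the signal-free 9.5-10.5 ppm region, so a
unit parameter deviation (in regularization units) costs as much as one
noise-sized residual point. The defaults mirror the LCModel assumptions:
$f_{reg} = 0.004$ ppm, $d_{exp} = 0.78$ Hz, $d_{reg} = 0.156$ Hz,
$a_{reg} = 0.1$. The expectation values 0.78 and 0.156 Hz come from
converting the LCModel DEEXT2/DESDT2 defaults (2.0 and 0.4) with
`expected_broadening(x, 127.8) = x * sqrt(127.8 / 85.15) / pi`; the
square-root field scaling is the form that reproduces the published
values.

Three fitting modes are provided:

* **reg** - the penalized objective; non-negativity is the only constraint
  on $d_i$, $f_i$ and $a_g$ are unbounded, $f_0$ is boxed at
  $\pm 0.05$ ppm around the coarse alignment.
* **noreg** - plain least squares, representing the hard-constrained
  predecessor method: $f_i$ boxed at $\pm 2 \times 1.96 \times 0.004$ ppm,
  $a_g$ at $\pm 0.25$, $f_0$ frozen at the coarse estimate, and $d_i$
  boxed in $[0,\, d_{exp} + 2 \times 1.96 \times d_{reg}]$. The damping box
  uses the same two-times-95 %-interval construction as the frequency box;
  without it the unregularized fit collapses (a near-zero-amplitude signal
  broadens without bound and absorbs baseline-like power, inflating its
  amplitude by an order of magnitude), which would make the comparison
  meaningless rather than merely unregularized.
* **ff** - the regularized fit with $|f_i| \le 10^{-6}$ Hz, eliminating
  the individual shifts from the model.

## Fitting schedule

A simplified coarse-to-fine schedule precedes the full optimization:

1. $\sigma$ from the 9.5-10.5 ppm region (the generator leaves it empty).
2. Coarse alignment: $f_0$ by cross-correlating the data with a reference
   spectrum (the basis at its nominal benchmark concentrations, expected
   damping, 4 Hz Gaussian lineshape) on the spectral grid, then 1-D
   refinement of $f_0$, $\phi_0$ and the Gaussian width against the data
   misfit with a very stiff baseline and $f_i = 0$, $d_i = d_{exp}$.
3. Baseline stiffness: the spline penalty weight is chosen from 15
   log-spaced candidates ($10^{-2}$ to $10^{10}$) by minimizing
   $N \log(RSS/N) + 2 m \cdot ED$, where $ED$ is the effective dimension
   (trace of the penalized hat matrix) and $m = 5$ weights parsimony, a
   conventional choice for penalized-spline model selection in this
   setting. The weight is then held fixed.
4. Levenberg-Marquardt over all nonlinear parameters (`minpack.lm`),
   with amplitudes eliminated by variable projection at every evaluation.
   The individual frequencies are released gradually: a short pre-fit
   (up to 60 iterations) settles the dampings, lineshape and global
   parameters with every $f_i$ still frozen at zero before the full fit
   frees them. Without this, near-degenerate singlet pairs - the two
   choline trimethyl resonances sit 0.004 ppm apart, the same scale as the
   shift variability - can swap identities early and strand the fit in a
   local minimum. The Jacobian is analytic in the Kaufman (fixed-amplitude)
   approximation, which shares one Fourier transform between the $f_i$ and
   $d_i$ derivatives of each signal; at an exact non-negative solve the
   projected residual is orthogonal to the free columns, so first-order
   optimality is unaffected. Convergence: relative change below 1e-10 or
   150 iterations per pass, with one restart from the converged point kept
   when it still improves the objective (the step-size criterion can fire
   prematurely in narrow curved valleys); a numerically zero residual
   (noiseless input) is also accepted as converged. Initialization is the
   expectation point ($f_i = 0$, $d_i = d_{exp}$, $a_g = 0$), the natural
   start for the penalized objective; non-negative solves break degenerate
   ties by lowest basis index.

This schedule stands in for the published four-phase approach of the
predecessor algorithm, whose exact internal stages are out of scope here;
all comparisons in the package are internal (reg vs noreg vs ff with an
identical surrounding pipeline), so conclusions about regularization do not
depend on replicating those stages exactly.

## The basis set

`default_basis()` simulates 19 metabolites by dense density-matrix
propagation (full isotropic J-coupling, so strong-coupling patterns are
exact) for an ideal-pulse semi-LASER sequence at 3 T (TE 8 + 11 + 9 ms),
1024 complex points at 2000 Hz. Ideal semi-LASER is realized as a 90-degree
excitation plus four instantaneous 180-degree pulses placed so chemical
shift refocuses at the start of acquisition while J evolution accumulates
over the full TE; with an even pulse count an uncoupled spin reproduces
pulse-acquire exactly, which the tests exploit. Shifts and couplings are
embedded in an editable JSON file following the standard literature values;
molecules are split into uncoupled moieties where possible (a 3-proton
methyl singlet is one spin scaled by three), and glucose is simulated as
both anomers weighted 0.36/0.64. No relaxation is applied during the
sequence, and the first FID point sits at the echo center, so simulated
data carry no first-order phase.

The remaining 10 signals are parametric: four lipid and five macromolecule
resonances with published broad-component parameters, plus the inverted
-CrCH2 singlet at 3.913 ppm (modeling the effect of water suppression on
the creatine CH2 resonances). Basis FIDs are normalized to one unit per
proton at $t = 0$; with the water-reference amplitude
WCONC x ATTH2O = 35880 x 0.7 = 25116, a fitted amplitude of 1 then
corresponds to 1 mM.

## Synthetic benchmark

`generate_dataset()` reproduces the benchmark conditions: per-signal
frequency shifts drawn from N(0, 0.004 ppm) and Lorentzian broadenings from
N(0.78, 0.156 Hz) (truncated at zero; truncation probability ~3e-7), or the
matched uniform variants over the 95 % intervals; scaling by the nominal
healthy-brain concentrations; 4 Hz global Gaussian broadening; and complex
white noise calibrated so that max(real spectrum)/SD(noise) hits the target
SNR in expectation (the time-domain per-component SD is the frequency-domain
SD divided by sqrt(N)). Per-spectrum seeds derive deterministically from the
master seed, and each ground-truth record regenerates its spectrum
bit-exactly. What the generator deliberately omits - baseline distortions,
residual water, phase errors, eddy currents, frequency drift - bounds what
the benchmark can show: passing it demonstrates the estimator's behavior
under model-matched variability, not robustness to real-world artifacts.

## Evaluation

Accuracy is the sum of squared concentration errors over the 19 metabolites
(lipids, macromolecules and -CrCH2 are excluded). Methods are compared by
the relative reduction in mean SSE and a Welch two-sample t-test on the
per-spectrum SSE distributions (the unequal-variance form is the defensible
default since the two methods' error distributions differ); no
multiple-testing correction is applied, matching the reporting convention
of the underlying study design. Bland-Altman agreement summaries
(bias and 1.96-SD limits) are available for method pairs; tNAA is formed by
summing the NAA and NAAG estimates.

The packaged acceptance run uses 200 spectra per SNR regime at SNR 10 and
100 - enough for the mean-SSE reductions to stabilize to a few percentage
points while keeping the full run in the tens of minutes on one core; the
published conditions (1000 spectra, four SNR regimes) are reproducible with
`synth_config(n_spectra = 1000, snr_targets = c(10, 30, 60, 100))`.

## Numerical choices and degenerate inputs

* ppm convention: the zero-frequency bin maps to 4.65 ppm (water) and ppm
  decreases with increasing frequency offset, so the generated water
  reference lands on-center.
* The canonical domain is the time-domain FID; frequency-domain views are
  derived by a single DFT and never stored.
* The noise-region SD of a noiseless spectrum is not exactly zero (FID
  truncation leaks ~1e-5 of the peak into the far spectral tails);
  `measure_snr()` therefore reports ratios above 1e5 as infinite, and
  `fit_spectrum()` floors sigma at 1e-12.
* A rank-deficient spline subproblem falls back to a tiny ridge rather
  than failing.
* NIfTI-MRS dwell times are stored as 32-bit floats by the format, so
  sampling frequencies round-trip to ~1e-7 relative accuracy; complex data
  round-trip bit-exactly.

## Known limitations

* The fitted lineshape family is Gaussian-with-asymmetry only; Voigt or
  model-free lineshapes are out of scope.
* Ideal pulses: no shaped-pulse or spatial-localization effects in the
  basis simulation, and no relaxation during the echo time.
* One spectrum per fit; no MRSI spatial modeling.
* The unregularized comparison mode represents a hard-constrained
  predecessor whose exact box widths are not published; its damping box is
  this package's own documented construction, and the high-SNR accuracy gap
  between the modes is sensitive to it and to optimizer details (how often
  each mode escapes local minima).
* Parameter recovery for individual signals degrades when two basis
  signals are separated by less than the assumed shift variability (the
  choline pair); the graduated-release schedule prevents outright identity
  swaps on noiseless data, but such pairs remain the least determined
  parameters of the model.
* Uncertainty estimates (Cramér-Rao bounds) are not computed.
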