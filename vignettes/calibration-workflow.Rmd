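---
title: "Multivariate calibration of overlapping voltammograms: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate calibration of overlapping voltammograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltacal)
```

# Scope

`voltacal` implements the complete chemometric workflow for quantifying
four NSAIDs — paracetamol, diclofenac, naproxen and aspirin — simultaneously
from differential-pulse voltammograms (DPV) whose oxidation peaks overlap.
This vignette explains the models and their assumptions, the tunable
parameters and why their defaults are what they are, what the synthetic
data generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

# The measurement model behind the simulator

A DPV scan records current at 177 potentials from 0 V in steps of
0.00585 V (the optimized step potential), ending near 1.03 V. The
simulator models the current of a mixture as

$$ i(E) \;=\; b_0 + b_1 \, s \, E \;+\; \sum_k A_k \,
   c_{\mathrm{owner}(k)} \exp\!\left(-\frac{(E - E_k)^2}{2\sigma_k^2}\right)
   \;+\; \varepsilon(E), \qquad \varepsilon \sim N(0, \sigma_n^2) $$

- **Gaussian peaks.** DPV peaks are approximately symmetric and bell-shaped;
  a Gaussian is the standard idealization when no mechanistic peak-shape
  model is fitted. Peak centers follow the observed oxidation potentials:
  paracetamol 0.446 V, diclofenac 0.629 V with a secondary peak at 1.02 V
  at 40% of the primary sensitivity, naproxen 0.888 V, aspirin 0.880 V,
  ascorbic acid 0.30 V. All widths default to $\sigma = 0.05$ V.
- **Linearity.** Peak amplitude is `sensitivity × concentration`; the
  relative sensitivities are anchored so that an equimolar four-drug mix
  reproduces the observed peak-current proportions at pH 10
  (7.26 : 8.81 : 18.10 for paracetamol : diclofenac : the merged
  naproxen+aspirin peak), with an absolute scale of 0.1 µA per µmol L⁻¹
  for paracetamol. Only relative magnitudes matter for calibration.
  An optional saturation scale $c_{\mathrm{sat}}$ replaces $c$ by
  $c_{\mathrm{sat}}(1 - e^{-c/c_{\mathrm{sat}}})$ to emulate electrode
  response flattening; it is off by default, keeping the generator linear.
- **Interferents.** Ascorbic acid is redox-active and gets its own peak at
  fixed concentration (80 µmol L⁻¹). Glucose (18.5) and SDS (22 µmol L⁻¹)
  are not redox-active; they perturb the baseline slope multiplicatively by
  $(1 + 0.001\,c)$ each — a small matrix effect rather than a peak.
- **Baseline and noise.** The affine baseline defaults to 0.5 µA intercept
  and 2 µA V⁻¹ slope; the noise standard deviation defaults to 1% of the
  maximum clean current of the generated sample set. Neither is measurable
  from the published record, so these are stand-ins at magnitudes typical
  of carbon-paste DPV, not reconstructions of the real instrument.

The 0–1.05 V window and the 177-point count cannot both hold exactly with a
0.00585 V step (176 steps span 1.0296 V); the grid keeps the printed point
count and step, so the last potential is ≈1.03 V. Naproxen's reported
second peak near 1.12 V lies outside this window and is not simulated.

**What passing tests do and do not show.** The generator reproduces the
*statistical structure* the calibration relies on — linear response,
near-collinear naproxen/aspirin signatures (trace correlation ≈ 0.997),
fixed interferents, smooth baseline, additive noise. It does not emulate
electrode drift or fouling, pH effects, scan-rate effects, non-Gaussian
peak asymmetry, or inter-session sensitivity changes. Results on synthetic
data therefore validate the *mechanics* of the pipeline, not the analytical
performance of any physical sensor.

# Experimental designs

The calibration set is the 3⁴ full factorial: every combination of
{0.5, 40.25, 80} µmol L⁻¹ per analyte, 81 mixtures. Only the range
0.5–80 µmol L⁻¹ is prescribed; the mid level is the arithmetic midpoint.
Rows are generated in deterministic lexicographic order (no randomization:
the simulated instrument has no drift, and determinism makes every artifact
reproducible).

The DPV parameters (step potential, interval time, modulation time,
modulation amplitude) are optimized on a 4-factor Box–Behnken design:
for each of the 6 factor pairs the four (±1, ±1) vertices with the other
factors at mid level, plus center points. Three center points make the
run count 27, matching the reported experiment (24 edge runs + 3 centers).
The physical ranges of the four factors are not part of the published
record; the shipped defaults (`dpv_factor_ranges()`) bracket the reported
optimum (0.00585 V, 0.75 s, 0.05 s, 0.05 V) so that it is representable
inside the coded cube. Physical-unit optima are therefore illustrative;
coded-scale results are exact.

# Response surfaces and multi-response optimization

Each response (anodic peak current of paracetamol, diclofenac, and the
merged naproxen/aspirin peak) is a full quadratic in the four coded
factors: intercept, 4 linear, 4 pure quadratic and 6 interaction terms —
14 coefficients, fitted by least squares. The three published coefficient
sets ship as a JSON fixture (`nsaid_rsm_models()`); `fit_quadratic()`
recovers them to 1e-8 from noiseless evaluations on the 27-run design,
which is the fit's correctness oracle.

The joint optimum maximizes a weighted sum of min–max normalized responses
(equal weights by default) over $[-1,1]^4$. Normalization makes the three
responses commensurate without units; the published optimization used a
commercial desirability tool whose settings are not recorded, and a
weighted normalized sum is the simplest member of that family. Because the
composite of three quadratics can be multimodal on a box, the optimizer is
a dense 41-points-per-axis grid sweep followed by box-constrained
quasi-Newton polish from the best grid point, with the normalization frozen
from the sweep so the polished score remains comparable; ties prefer the
lexicographically lowest coded point. A test cross-checks the result
against an independent brute-force sweep on a coarser grid.

# Wavelet compression

Each 177-point trace is passed through an iterated two-channel Daubechies-4
filter bank (8-tap filters, orthonormal) with half-point symmetric boundary
extension and full-convolution lengths, so one analysis level maps
$n \to \lfloor (n+7)/2 \rfloor$: 177 → 92 → 49 → 28 at level 3. This is
the only standard boundary convention that yields exactly 28 coefficients
from 177 points, which pins down the convention. Detail coefficients are
discarded outright (not thresholded): the compression argument is that
smooth DPV peaks live almost entirely in the approximation subspace.

Reconstruction fidelity is scored by the *comparison factor*, implemented
as the Pearson correlation between the original trace and its
approximation-only reconstruction — a similarity bounded in [−1, 1] like
the published value (0.9823); on the default synthetic set the mean is
≈0.996. Correlation was chosen over alternatives (normalized inner
product, reconstruction R²) because it is the conventional bounded
similarity score; the exact published formula is not stated.

The filter bank satisfies perfect reconstruction when details are retained
(tested to 1e-9), and the per-level length recurrence is tested against a
brute-force convolution oracle for all lengths 8–512.

# Calibration models

## PLS

`pls_calibration()` is NIPALS PLS2 in regression mode: latent scores
$t = Xw$ maximizing covariance with the response block, X-deflation per
component, regression coefficients
$B = W(P^\top W)^{-1}Q^\top$ on centered data. The inner iteration starts
from the response column with the largest variance, making the fit
deterministic. At full rank PLS reproduces multivariate least squares,
which is one of the test oracles; an independent implementation (mixOmics)
is a second. The default 12 components follow the published choice;
`select_ncomp()` provides the cross-validated alternative (10-fold by
default; the published account states cross-validation without the scheme).
Near-ties in the CV curve (within a relative 1e-8) resolve to the smaller
model so numerically flat curves do not inflate the component count.

## Neural network

`mlp_calibration()` trains a 28×16×8×4 perceptron — identity input stage,
two tanh hidden layers, linear output — on data min–max scaled to [−1, 1]
per variable. The published "purelin input layer" is read as an identity
stage with no trainable input activation, the standard reading of that
toolbox convention.

Training is Bayesian-regularized Levenberg–Marquardt: minimize
$F = \beta E_d + \alpha E_w$ with $E_d = \tfrac12\sum e^2$ (scaled
targets), $E_w = \tfrac12\sum w^2$, LM damping adapted by step acceptance,
and $(\alpha, \beta)$ re-estimated by the MacKay evidence approximation
after accepted steps, with the effective parameter count computed from the
eigenvalues of $J^\top J$ ($\gamma = \sum \beta\lambda_i /
(\beta\lambda_i + \alpha)$), which remains defined when $J^\top J$ is
singular. Two numerical guards address the over-parameterized regime
(636 weights vs 324 residuals, where the textbook update degenerates):

- the evidence updates engage only after a 3-epoch unregularized warm
  start — updating from a random network collapses the trade-off into pure
  weight decay, while engaging only after convergence lets the network
  interpolate measurement noise first; both failure modes are real and
  observed, and the warm start sits between them;
- the misfit weight is floored at $\beta \ge 0.05N/(2E_d)$, since
  $\gamma \to N$ would otherwise silence the data term entirely.

Training stops when the scaled mean-squared error reaches the target
(default 0.015, the published training-error setting read as normalized
MSE, that toolchain's convention) or at 2000 epochs, with a stall guard.
Up to 3 seeded weight initializations are tried and the first reaching the
target is kept (selection by training error only); initialization is
uniform on [−0.5, 0.5]. The published learning rate (0.05) and momentum
(0.5) belong to gradient-descent training and are internally inconsistent
with Bayesian-regularized LM; both are accepted in `mlp_config()` and used
when `algorithm = "gd"` is selected.

# Figures of merit

For each analyte and stage the package regresses obtained on expected
concentrations: R, slope $m \pm \Delta m$ and intercept $b \pm \Delta b$
with two-sided t-based 95% half-widths (an ideal calibration has
$R = 1$, $m = 1$, $b = 0$). Intercepts are reported in mol L⁻¹ by default
— matching the magnitudes conventional in validation tables — with
µmol L⁻¹ available. Recovery yield is the mean percentage ratio
$R_y = (100/N)\sum y_i / y_{\exp,i}$; note it is unstable when expected
concentrations approach the lower design level (0.5 µmol L⁻¹), where small
absolute errors produce huge ratios — visible in training-set recoveries,
and an intrinsic property of the ratio definition, not a bug. LOD = 3σ/m
and LOQ = 10σ/m use the residual standard deviation of the testing
regression as σ: "standard deviation of the response" is ambiguous
(residual SD, blank SD, replicate SD all appear in practice), and the
residual SD is the only candidate computable from quantities this workflow
produces.

# Pipeline, determinism, problem sizes

`run_full_pipeline()` chains design → simulation (81 training + 10 random
test mixtures) → compression (28 × n blocks) → PLS and MLP calibration →
evaluation, writing every artifact (CSV/JSON) with an MD5 manifest. One
global seed deterministically derives per-stage seeds by hashing the stage
name modulo $2^{31}-1$, so stages have independent, collision-free
streams and every artifact is regenerable from config + seed alone.
Artifacts already up to date (same hash) are not rewritten. PLS artifacts
are bit-identical across reruns; MLP artifacts are identical under the
same seed.

Default problem sizes (81 training scans of 177 points, 10 test scans,
three 41⁴-point grid sweeps for the optimizer, MLP training of a few dozen
LM epochs) run in seconds; the test suite uses the same sizes throughout.

# Known limitations

- The naproxen/aspirin pair is nearly collinear by construction
  (signature correlation ≈ 0.997). The information ceiling for unmixing
  them at the default noise level corresponds to test correlations of
  roughly 0.98; a trained calibration necessarily sits below that, and the
  neural network's test-set correlations for these two analytes
  (typically 0.94–0.97 across seeds) are materially worse than for the
  resolved analytes. This mirrors the real analytical difficulty the
  workflow exists to address, and it bounds what any calibration — linear
  or not — can achieve on these conditions.
- The published PLS-fails/ANN-succeeds contrast on naproxen and aspirin
  does not reproduce on a linear generator: when the data truly are linear
  in concentration, PLS is near-optimal. Injecting nonlinearity via the
  saturation term degrades PLS first, demonstrating the mechanism, but the
  default conditions stay linear.
- Physical-unit outputs of the response-surface stage depend on factor
  ranges that are not part of the published record.
- The simulator's noise and baseline are plausible stand-ins; absolute
  figures of merit (LOD/LOQ in µmol L⁻¹) scale with them and should not be
  compared against instrument values.
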