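---
title: "Myelin water fraction mapping and learning-curve analysis: models and methods"
author: "mwfr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin water fraction mapping and learning-curve analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwfr)
```

# The measurement model

Water in brain tissue relaxes at rates that depend on its micro-environment.
Multicomponent T2 relaxation imaging resolves three pools from a multi-echo
spin-echo decay: water trapped between myelin lipid bilayers (short T2,
15–40 ms), intra/extracellular water (intermediate, around 80 ms), and
cerebrospinal fluid (long, above 1500 ms). The **myelin water fraction**
(MWF) is the short-pool share of the total T2 spectrum amplitude — a
quantitative, histologically validated proxy for myelin content.

A voxel's echo train $y_i = y(TE_i)$ at echo times $TE_i = i\,\Delta TE$ is
modeled as a non-negative mixture over a fixed grid of $M$ T2 values,

$$ y_i \;=\; \sum_{j=1}^{M} x_j \, d_i(T_{2,j}, \beta) + \varepsilon_i,
   \qquad x_j \ge 0 , $$

where $d_i(T_2, \beta)$ is the decay of a single T2 species under refocusing
pulses of actual flip angle $\beta$, and the spectrum $x$ is the unknown.
The MWF is $\sum_{j \in \text{short}} x_j / \sum_j x_j$, with the short band
taken as the closed interval $[15, 40]$ ms, the intermediate band as
$(40, 200]$ ms, and the long band as $T_2 \ge 1500$ ms (descriptions of the
CSF pool sometimes quote "> 2 s"; this package uses the 1500 ms
methods-level edge throughout, and grid points falling on a band edge
belong to the lower band — a deterministic, documented convention).

# EPG signal model

Refocusing pulses are never exactly 180° in vivo (B1 inhomogeneity), and
imperfect pulses generate stimulated echoes that bias naive exponential
analysis. `epg_decay()` computes $d_i(T_2, \beta)$ with the extended phase
graph formalism: the magnetization is expanded in configuration states
$F_k$ (transverse, dephasing order $k$) and $Z_k$ (longitudinal), and each
echo interval applies half-interval relaxation, a gradient dephasing shift,
the refocusing rotation, a second shift and half-interval relaxation. The
echo amplitude is the magnitude of $F_0$, matching magnitude MRI data.

Modeling assumptions, each a deliberate choice:

* **Ideal 90° excitation in CPMG phase** — the excitation axis is 90° from
  the refocusing axis, so only the refocusing angle varies. This is the
  standard stimulated-echo-correction setting.
* **T1 fixed at 1000 ms.** T1 only enters through magnetization stored
  longitudinally between pulses, and multi-echo T2 data cannot usefully
  estimate it; 1000 ms is the conventional assumption in myelin-water EPG
  fitting. It is a configurable constant (`seq_params(t1 = )`), never an
  estimated parameter.
* **No T1 regrowth during the train** — only decay of the stored states is
  modeled; saturation effects from the repetition time are absorbed into
  the overall (arbitrary) signal scale.
* **State truncation at order $n_{\text{echoes}} + 1$**: higher dephasing
  orders cannot return to $F_0$ within the train, so they are exactly
  irrelevant.

At $\beta = 180°$ the recursion collapses to $\exp(-TE/T_2)$ exactly (to
machine precision, which the test suite asserts at $10^{-12}$). At other
angles the implementation is validated against a brute-force isochromat
simulation — 10,000 uniformly dephased spins propagated with explicit
rotation matrices — which shares no code with the EPG recursion; agreement
is at rounding-error level, far inside the $10^{-3}$ tolerance asserted.

One counter-intuitive but genuine consequence of stimulated pathways: for
very short T2 (e.g. 20 ms) a *lower* refocusing angle can *increase* the
summed echo amplitudes, because magnetization parked along $z$ decays at
the slow T1 rate rather than the fast T2 rate. The tests pin this behavior
down (monotone loss at T2 = 80 ms, reversal at T2 = 20 ms) rather than
assuming monotonicity everywhere.

# Spectrum estimation

## NNLS and its regularization

The spectrum solves the non-negative least-squares problem
$\min_{x \ge 0} \lVert A x - y \rVert^2$ with $A$ the EPG decay basis
(`decay_basis()`), via a Lawson–Hanson active-set solver written for this
package and verified in the tests against exhaustive enumeration of all
active sets on small systems and against an independent library
implementation. An all-zero signal returns the zero spectrum.

Plain NNLS spectra are spiky and unstable under noise, so `fit_voxel()`
uses minimum-energy (Tikhonov) regularization:

$$ \min_{x \ge 0} \; \lVert A x - y \rVert^2 + \mu^2 \lVert x \rVert^2 , $$

with $\mu$ chosen by bisection as the largest value whose *data* misfit
$\chi^2(\mu)$ stays within `chi2_factor` times the unregularized minimum
$\chi^2_{\min}$. The default `chi2_factor = 1.02` (a 2 % misfit inflation)
is the convention in the multicomponent T2 literature; whether the
original analyses used an energy or a curvature penalty is generally
unreported, and energy was chosen here as the simplest established option.
`chi2_factor = 1` reproduces the unregularized solution exactly, and the
bisection is scale-equivariant, so MWF is invariant to the overall signal
scale (asserted at $10^{-10}$).

Regularization trades variance for a known bias: smoothing spreads the
sharp myelin peak across the 40 ms band edge into the intermediate pool,
depressing MWF by roughly 0.02 at SNR 500 under the default settings (the
recovery experiment in the test suite and acceptance script measures this
directly; unregularized fits on the same data recover with roughly
-0.006 bias). Users who prioritize accuracy of the point estimate over map
smoothness can lower `chi2_factor`; the default follows the field.

## Flip-angle estimation

`estimate_flip_angle()` scans candidate angles (default 50°–180° in 1°
steps, covering realistic B1 droop), computes the unregularized NNLS misfit
with each angle's basis, takes the discrete minimizer, and refines it by
quadratic interpolation through the bracketing misfits, clipped to the
bracket and to $(0, 180]$. Ties resolve to the smaller angle
(deterministic). The refinement recovers noiseless off-grid angles to well
under a degree; under Rician noise at SNR 200 the median estimate is
within 3° of truth (both tested).

## Per-voxel composition and degenerate inputs

`fit_voxel()` estimates the angle, fits the regularized spectrum with that
angle's basis, and partitions it. Voxels whose peak signal does not exceed
the configurable `noise_floor` (default 0, which still catches all-zero
voxels) are flagged invalid and their MWF is `NA` — reported as missing,
never as 0, because a zero would silently bias ROI means downward.

# Volume mapping

`fit_volume()` applies the voxel fit across a masked 4D volume with a
shared precomputed EPG dictionary. Fitting involves no randomness, so
reruns are bit-identical, and voxels are independent, so results on a
sub-mask equal the restriction of a full-mask run (both are regression
tests). Masks are eroded with `erode_mask()` — one iteration, 6-connected
(face-adjacent) structuring element, the most conservative standard
erosion; whether original white-matter cleanups used 6- or 26-connectivity
is typically unstated, and 6 was chosen as the stricter convention. In
memory, missing voxels are `NaN`; on disk they are written as 0 with a
companion validity mask, since NIfTI viewers mishandle NaN. `roi_mean()`
excludes missing voxels from both numerator and denominator and raises an
error on an empty intersection.

# The learning-curve model

Motor skill acquisition is summarized by fitting movement time against
trial number with

$$ E(MT)_N = A + B e^{-\alpha N} , $$

where $A$ is the plateau movement time, $B$ the overall change from start
to plateau (positive when performance improves), and $\alpha$ the
per-trial acquisition rate. `fit_exponential()` exploits the fact that the
model is linear in $(A, B)$ given $\alpha$: the sum of squared errors is
profiled over $\alpha$ alone, evaluated on a multi-start grid
$\{5\times10^{-4}, 10^{-3}, 5\times10^{-3}, 10^{-2}, 5\times10^{-2},
10^{-1}\}$ and refined locally, with $A$ clamped at 0 and $\alpha$
restricted to $[0, 1]$. This profiled search is far more robust than
general nonlinear optimization on exponentials, which is notoriously
sensitive to the rate initialization; it recovers noiseless parameters to
$10^{-6}$ relative and, with noise of standard deviation $0.1 B$, the
median $\alpha$ over 100 replicates within 10 % (both tested).

Conventions and degenerate cases:

* By default only successful trials are fitted, and $N$ counts fitted
  trials sequentially from 1 (whether original analyses indexed by the
  successful-trial counter or the absolute counter is usually unstated;
  the sequential convention is documented and an explicit `N` argument
  allows the other choice). Renumbering $N \to N + k$ leaves $A$ and
  $\alpha$ invariant and rescales $B$ by $e^{\alpha k}$ — an algebraic
  identity the tests verify.
* A series with no detectable decay returns $B \approx 0$ with an
  `unidentifiable` flag: $\alpha$ is then arbitrary and must not be
  interpreted.
* Fewer than 3 usable trials is an error, not a fit.

`bin_fit()` splits sessions 1–9 (early acquisition) from session 10
(late), renumbers within each bin, and fits both independently; an empty
bin yields a captured error in its slot so the other bin still fits.

# Inferential layer

* `percent_change()`: $100 (post - pre)/pre$, undefined at $pre = 0$.
* `one_sample_t_from_summary()` / `one_sample_t()`:
  $t = (\bar{x} - \mu_0)/(s/\sqrt{n})$ with $n-1$ degrees of freedom,
  two-tailed. The summary form exists because group results are often
  reported only as mean ± SD with n, and it reproduces such printed t
  statistics exactly.
* `pearson()` / `cor_p_value()`: significance from
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, so a p-value
  can be recomputed from a reported $(r, n)$ pair alone.
* `icc()`: two-way ANOVA mean squares; single-measure **absolute
  agreement** by default — the conventional form for test–retest of a
  quantitative measure, sensitive to systematic session offsets — with
  **consistency** behind a flag. The form label travels with every result
  because the two can differ materially (a constant offset leaves
  consistency at 1 while agreement drops, a definitional contrast the
  tests assert). Missing cells are an error; nothing is imputed.

All tests are two-tailed at $\alpha = 0.05$ with no multiple-comparison
correction, mirroring common practice in small training studies; this is a
faithful-reproduction choice, not a statistical recommendation.

# Synthetic data: what it emulates, and what it does not

`make_phantom()` builds labeled block phantoms (default: one 8×8×4 block
per class) whose voxels decay as pool-fraction-weighted EPG mixtures under
a smooth flip-angle ramp (default 140°–180° across x), plus noise with
$\sigma = $ mean first-echo signal / SNR. Default tissue classes: white
matter 0.12/0.83/0.05 at 20/80/2000 ms (true MWF 0.12), grey matter
0.03/0.92/0.05, pure-CSF 2000 ms. Rician noise (magnitude of a complex
signal with Gaussian noise on both channels) is the default, being the
correct model for magnitude MRI; additive Gaussian (clamped at zero) is
retained for analytic checks. `make_trials()` emulates the training
schedule — 10 sessions × 5 blocks × 200 movements = 10,000 rows — with
exponential mean structure, Gaussian noise (floored at 1 ms to keep
movement times positive) and Bernoulli success at a default rate of 0.813.
`make_cohort()` draws per-subject ROI percent changes and a learning rate
with a prescribed true correlation. Every generator is a pure function of
its spec: identical seeds give identical bytes, and the caller's RNG
stream is left untouched.

What the generators deliberately do **not** emulate: brain anatomy and
partial-volume geometry, registration/segmentation errors (masks are
inputs here), k-space acquisition and reconstruction artifacts, motion,
exchange between water pools, and the adaptive difficulty progression of
the real task (the success rate is a flat schedule label). Passing
recovery tests therefore demonstrate correctness of the *estimators* under
the stated noise model — not that real-data MWF maps are unbiased, where
Rician floors at low SNR, unweighted least squares on magnitude data (a
documented limitation; no Rician bias correction is applied) and
partial-volume effects all matter.

# Numerical choices and problem sizes

* T2 grid: 40 log-spaced points, 15–2000 ms — spans all three bands;
  size/edges configurable.
* Regularization bisection: 60 iterations max, terminating when the
  achieved misfit is within 0.1 % of the target; the returned solution is
  always on the feasible (≤ target) side.
* Flip search: misfit on the 1° candidate grid, then one quadratic
  interpolation step; candidates configurable for speed (a 2° grid loses
  little accuracy).
* Erosion at volume borders: voxels on the array boundary always erode
  (no padding assumption).
* Test and validation problem sizes were chosen at desk scale: phantoms
  of a few hundred voxels fit in tens of seconds, the recovery sweep uses
  96 voxel fits across 12 conditions (true MWF 0.05–0.20, flip 140°–180°,
  SNR 500), the learning-curve Monte Carlo uses 100 replicates of 500
  trials, and the type-I calibration uses 5000 null replicates of n = 16.

# Known limitations

* Energy regularization at the conventional 2 % misfit inflation biases
  MWF low by about 0.02 at SNR 500 (measured by the package's own recovery
  experiment); this is inherent to the smoothing, not a solver defect.
* Rician bias is not corrected; at SNR ≥ 100 it is negligible for MWF but
  grows as late-echo signal approaches the noise floor.
* T1 is assumed, not estimated; gross T1 errors (factor ≫ 2) would perturb
  stimulated-echo amplitudes at low flip angles.
* The flip-angle search floor is 50°; voxels with more extreme B1 failure
  would rail at the boundary.
* `fit_volume()` runs serially; voxel independence makes parallel
  execution safe (results must be bit-identical), but no parallel backend
  is bundled.
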