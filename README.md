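# mwfr — myelin water fraction mapping and motor learning analysis

Studies of experience-dependent myelin plasticity ask two quantitative
questions at once: *how much myelin water does each white-matter voxel
carry*, and *how fast is a participant acquiring a motor skill*. This
package implements both measurement chains, plus the statistics that
connect them, for researchers analyzing multi-echo T2 relaxation MRI
alongside motor-training logs.

## The models at the core

**Myelin water fraction (MWF).** A voxel's multi-echo spin-echo decay is a
non-negative mixture over a log-spaced T2 grid,

    y(TE_i) = Σ_j x_j · d_i(T2_j, β) + ε_i ,   x_j ≥ 0 ,

where the decay basis `d_i(T2, β)` comes from the extended phase graph
(EPG) formalism, which models the stimulated echoes produced when the
refocusing flip angle β falls below 180° (B1 inhomogeneity). Per voxel the
package estimates β by misfit minimization over candidate angles, solves a
minimum-energy regularized non-negative least-squares (NNLS) problem for
the spectrum x (Lawson–Hanson active set; penalty weight set by bisection
so the misfit stays within a 2 % inflation of the unregularized minimum),
and reports

    MWF = Σ_{15 ms ≤ T2_j ≤ 40 ms} x_j / Σ_j x_j ,

the short-T2 (myelin water) share of the spectrum. Whole volumes are
fitted voxelwise into MWF / flip-angle / misfit maps, with one-voxel
6-connected mask erosion and missing-aware ROI means.

**Skill acquisition.** Movement-time series are fitted with the
exponential learning law

    E(MT)_N = A + B·exp(−α·N) ,

A the plateau movement time, B the overall change (positive when
performance improves), α the per-trial acquisition rate — profiled
nonlinear least squares with a multi-start rate grid, plus early (sessions
1–9) vs late (session 10) binning.

**Inference.** Percent change pre→post, one-sample t-tests (from raw
values or from printed mean ± SD with n), Pearson correlations with
p-values recomputable from (r, n) alone, and two-way single-measure ICC
(absolute agreement by default, consistency on request) for test–retest
and interrater reliability.

Synthetic generators (`make_phantom()`, `make_trials()`, `make_cohort()`)
produce multi-echo phantoms and behavioral logs with known ground truth,
so the entire pipeline is testable without any scanner data.

## Worked example

```r
library(mwfr)

## a small three-class phantom (WM true MWF 0.12, GM 0.03, CSF 0) with a
## 140-180 degree B1 ramp, Rician noise at SNR 500
ph <- make_phantom(phantom_spec(block_shape = c(4, 4, 2), snr = 500, seed = 42))
mask <- array(ph$truth$label > 0, dim(ph$truth$label))
maps <- fit_volume(ph$volume, mask)
roi_mean(maps$mwf, array(ph$truth$label == 1, dim(ph$truth$label)))
#> [1] 0.09770052

fit_voxel(ph$volume$data[2, 2, 1, ])
#> Voxelwise multicomponent T2 fit
#>   flip angle : 153.2 deg
#>   MWF        : 0.0943
#>   pools      : short 0.094, intermediate 0.857, long 0.049, other 0.000
#>   chi2       : 8.884e-05
```

The white-matter ROI mean of 0.098 against a truth of 0.12 shows the
documented ~0.02 downward bias of conventional energy-regularized NNLS
(see the methods vignette); the recovered flip angle tracks the simulated
B1 ramp (here truth ≈ 153.3° at that voxel).

```r
## learning curve on a synthetic 10,000-movement training log
tr <- make_trials(behavior_spec(seed = 7))   # truth A=1, B=2, alpha=0.01
fit_exponential(tr)
#> Exponential learning curve: MT(N) = A + B * exp(-alpha * N)
#>      A      B  alpha
#> 1.0020 2.0220 0.0125
#> trials: 8066, residual SSE: 328.2
```

A and B are recovered directly; alpha comes out 0.0125 rather than 0.0100
because only successful trials (81.3 % of 10,000) are fitted and renumbered
sequentially, which compresses the trial axis by the success rate
(0.0100 / 0.813 ≈ 0.0123) — the indexing convention is documented and
controllable via the `N` argument.

```r
## group statistics exactly as reported from summary data
one_sample_t_from_summary(8.30, 13.90, 16)
#> One-sample t-test: t(15) = 2.388, two-tailed p = 0.0305
#>   mean 8.3 (sd 13.9, n 16) vs null 0
cor_p_value(-0.615, 16)
#> [1] 0.01121775

## test-retest reliability of repeated ROI measurements
icc(cbind(c(0.041, 0.124, 0.169, 0.059, 0.153, 0.172),
          c(0.044, 0.126, 0.165, 0.056, 0.144, 0.169)))
#> ICC = 0.997 (two-way, single-measure, absolute-agreement; 6 subjects x 2 measurements)
```

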