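---
title: "Methods: detecting micro-scale functional modules with micromod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting micro-scale functional modules with micromod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators, parameter choices and
numerical decisions behind `micromod`, in the spirit of a methods section a
maintainer can audit. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis problem

A penetrating microelectrode array samples local field potentials (LFPs)
and spiking from a few mm² of cortex on a regular lattice (8×8 or 10×10 at
0.4 mm pitch; the 96-channel variant omits the four lattice corners, and
`drop_corners()` reproduces that convention). The question the pipeline
addresses is whether such a patch decomposes into functional modules:
groups of electrodes with dense directed functional connectivity inside
the group, sparse connectivity between groups, stable membership across
sessions recorded days apart, compact spatial footprints (~1.3 mm, the
scale of cortical columns), and — as independent functional evidence —
stimulus coding that is shared among neurons of the same module.

## 2. LFP preprocessing

The cleaning chain runs in a fixed order: electrode rejection → common
average reference → local detrend → line-noise regression → artifact
interpolation and block extraction. Each step is exposed separately;
`preprocess_session()` chains them.

* **Rejection.** Channels whose RMS amplitude or variance exceeds the
  across-channel mean by more than 3 SD are removed before referencing.
  The plain mean+3·SD rule self-masks when a single channel dominates a
  very small array; with the ≥ 64 channels of the target arrays a 100×
  variance channel is reliably flagged, and a second pass removes nothing.
* **Referencing.** Subtracting the per-sample mean across retained
  channels removes array-wide components (including instantaneous
  volume-conducted signal); afterwards the cross-channel mean is exactly
  zero.
* **Detrending.** A running local linear fit (window 0.5 s, step 0.25 s)
  is evaluated at window centers, linearly interpolated into a trend, and
  subtracted. Window and step are this package's defaults for the usual
  local-detrending step; with them a 0.5 Hz tone is attenuated by ≈ 17 dB
  (the test asserts ≥ 10 dB) while 40 Hz passes unchanged, meeting the
  goal of removing fluctuations below ~2 Hz. Both are configurable.
* **Line noise.** A sine+cosine pair at the line frequency and every
  harmonic below Nyquist is fitted by least squares per 30-s clip and
  subtracted. Before the regression the signal is
  resampled so the rate is an integer multiple of the line frequency
  (1000 → 1020 Hz for 60 Hz) and back. Resampling uses an exact,
  delay-free FFT rational resampler written for this package: polyphase
  resamplers introduce a group delay and imperfect anti-aliasing that
  corrupt the subtraction round trip (we measured a 5-sample shift and
  0.78 round-trip correlation on white noise with a standard polyphase
  implementation, versus > 0.999 for the FFT route).
* **Artifacts.** Samples beyond 4 scaled median absolute deviations
  (scale constant 1.4826, i.e. consistent with the Gaussian SD) are
  flagged, padded by 5 samples per side, and replaced by shape-preserving
  piecewise-cubic Hermite interpolation (`pracma::pchip`). PCHIP keeps the
  fill inside the envelope of the neighboring samples; R's
  `splinefun(method = "monoH.FC")` does not guarantee this on
  non-monotone data and was rejected after it overshot by ~3× in testing.
  A clip with more than 50% flagged samples is marked unusable. A
  constant clip (MAD = 0) is a no-op.
* **Blocks.** Each session is split into twenty 30-s clips; within each
  clip the 5-s window (1-sample stride) with the fewest interpolated
  samples is kept, ties broken by the earliest start so selection is
  deterministic and stimulus-agnostic.

## 3. Conditional Granger causality

**Time domain.** For target *x* and source *y*, `F = ln(var(ε′)/var(ε))`
compares the reduced VAR (past of all channels except *y*) with the full
VAR. Fitting is multi-realization least squares: lagged moment matrices
are pooled across blocks, never regressing across a block boundary, and
each block is demeaned channel-wise. The reduced-model residual variance
is computed through the partitioned-regression identity
`RSS_red − RSS_full = β̂ᵀ [(XᵀX)⁻¹]⁻¹_{jj} β̂`, which is algebraically
identical to re-fitting the reduced regression but costs one matrix
inversion for all N(N−1) pairs. F is clipped at 0 by construction and is
invariant to channel-wise rescaling.

The VAR order is a user choice; `select_var_order()` implements AIC over a
candidate range for data-driven selection. The pipeline default (8) equals
the generator's default order. Pooled estimation over blocks (rather than
per-block averaging) was chosen because blocks are short (5 s) relative to
the parameter count at 64 channels; the choice is exposed as
`gc.pooling` in the pipeline configuration.

**Significance.** Under the null, `n·F ~ χ²(p)`. Entries failing a
Bonferroni-corrected α = 0.05 over the N(N−1) ordered pairs are set
exactly to zero; significant entries keep their raw F. The χ² form (vs an
F-distribution variant) is the standard large-sample choice; with the
5-s blocks used throughout, the measured family-wise error over repeated
independent-channel simulations is at the nominal level (the asymptotic
null becomes mildly anti-conservative only when blocks are much shorter,
which the calibration test documents by using the default 5-s block length).

**Spectral decomposition.** `spectral_conditional_gc()` implements the
Geweke two-stage conditional construction: the full VAR gives the transfer
function and spectral density; for each source the reduced model is
recovered from the full model's source-omitted sub-spectrum by Wilson's
spectral factorization (implemented in C++, iterating the plus-operator
with FFTs until a 1e-9 relative tolerance, upper-triangular lag-0
convention, Cholesky initialization at the lag-0 covariance). The
conditional spectrum for target *x* follows from the transformed system
`Q = Ĝ⁻¹H`, splitting the (flat) reduced-innovation spectrum into the
source innovation's contribution — orthogonalized against the other
innovations, so the causal variance is the partial variance — and the
intrinsic remainder. Negative numerical values are clipped to zero and
counted.

Two numerical facts shape how the integral identity
`(1/2π)∮ f(ω) dω = F` should be checked, and both are documented
limitations rather than tunable knobs:

1. The two-stage construction integrates to F *exactly* only in special
   cases; the violation grows with coupling strength. In population
   (exact models, no estimation), we measured exact agreement for most
   pairs of a weakly-coupled trivariate system but ~4% error for one
   strongly-coupled pair. The identity test therefore uses a dense,
   weakly-coupled random VAR (`make_dense_var_truth()`, per-pair coupling
   scales 0.015–0.05), where every ordered pair has F well above the
   estimation floor and the identity holds to ~1.5% median relative error
   across seeds.
2. The time-domain reduced regression at order *p* is misspecified for
   the reduced sub-process (a VARMA), biasing `var(ε′)` upward, while the
   Wilson route corresponds to the infinite-order reduced model. Identity
   checks therefore fit at twice the generating order, which makes this
   gap negligible (≈ 0.06% median) without affecting the full model.
   Substituting regression-fitted reduced VARs *inside* the spectral
   construction was tried and rejected: the misspecified reduced filter
   corrupts the decomposition far more (order-of-magnitude larger
   violations).

**Bands.** Band values are `(1/|B|)∫_B f(ν) dν` by trapezoid with
edge interpolation, on the canonical bands delta 2–4, theta 4–8, alpha
8–16, beta 16–32, broadband gamma 70–150 Hz. With `normalize = TRUE` each
pair's spectrum is first scaled to unit area so that band values compare
relative frequency content irrespective of overall connection strength
(module detection otherwise biases within-module spectra upward at all
frequencies).

## 4. Multilayer modularity

Session networks are stacked chronologically; each electrode is linked to
itself in adjacent layers with uniform weight ω equal to the median
nonzero intra-layer weight (so interlayer links are on the scale of the
functional weights). The quality function uses the directed Leicht–Newman
null `P_ijs = k_out_i(s) · k_in_j(s) / m_s` per layer; interlayer links
enter only the ω term and the normalization μ, which counts every
intra-layer ordered edge once and every interlayer link in both
directions (matching the double appearance of the ω term in the sum).
`Q_ml ≤ 1` always; the diagonal −γP terms are included, so a single-layer
network with all nodes in one community scores exactly 0.

Optimization is a generalized Louvain over node–layer super-nodes on the
symmetrized modularity matrix: greedy local moves in random order
(including moves into an empty community, permitting splits), aggregation
to convergence, then node-level refinement sweeps on the original matrix,
alternating until quality stops improving. The refinement phase matters:
without it the classic merge-only heuristic missed the exhaustive optimum
on 2 of 20 random 6-node 2-layer instances; with it, best-of-500 restarts
matches exhaustive enumeration (restricted-growth DFS over all set
partitions, feasible to ~13 node-layer pairs) on every instance tested.
Restarts are seeded per restart index; ties in quality are broken by the
first restart that attains the maximum, and all restart qualities are
returned because near-degenerate optima are expected. The reported `Q_ml`
is always recomputed from the returned labels by `quality()`, so the two
cannot disagree.

Stationarity is the Jaccard index of co-classification between
consecutive layers (the co-assignment-correlation reading of "average
correlation between subsequent partitions"; a Pearson variant on the
co-assignment indicators was considered and gives the same ordering on
the cases tested — the Jaccard form is the default because it is bounded,
interpretable, and insensitive to community sizes). Normalized
persistence is the fraction of node–layer transitions that keep their
label. Both are invariant to community relabeling.

**Surrogates.** Degree-matched surrogate networks use directed double-edge
swaps `(a→b, c→d) → (a→d, c→b)`, rejecting self-loops and multi-edges;
one pass attempts |E| swaps and 100 passes are run per surrogate (500
surrogates by default). Edge weights travel with the out-going stub,
approximately preserving out-strength (`surrogate.weight_rule` in the
configuration). Degree sequences are verified exactly on every surrogate.
Surrogate multilayers are optimized with the same settings as the real
network.

## 5. Spatial geometry

Module diameter is `2 R_g` with `R_g` the RMS distance of member
electrodes to their centroid. Compactness is the fraction of electrodes
inside (or on) the module's convex hull that belong to the module.
Electrodes exactly on the hull boundary count as inside — lattice points
are routinely collinear with hull edges, and excluding them would cap
rectangular modules below the metric's stated maximum of 1. Degenerate
hulls (singletons, collinear modules) are handled as points/segments with
an absolute tolerance of 1e-9 on the cross-product tests. Both metrics
are invariant to rigid motions of the coordinates.

Boundary analysis: a module's boundary electrodes are its members on the
hull (all of them, not just vertices — the alternative is a configuration
noted in the code); those with at least one 4-neighbor (distance exactly
one pitch) inside and one outside the module form distance-matched
(boundary, inside) and (boundary, outside) pairs. GC contrasts average
the two directed weights of each unordered pair.

## 6. Decoding

Spike counts in a 200-ms boxcar sliding at 20 ms (bin centers −0.2 to
1.2 s around onset) are square-root transformed and z-scored per unit
against the square-root counts in non-overlapping 200-ms bins of the
task's baseline periods (2-s panels flanking each 60-image set). Units
with zero baseline SD are dropped with a warning.

The classifier is multinomial (softmax) logistic regression trained by
full-batch gradient descent from zero weights (learning rate 0.5 on
standardized features, maximum 300 iterations), with early stopping on a
validation set: per fold, a random quarter of the training trials forms
the early-stopping set, the remaining three quarters supply both the
gradient and the feature z-scoring parameters, and training stops when
the validation loss fails to improve for 10 iterations (best-validation
weights kept). This is repeated over 50 random early-stopping draws per
fold; weights are averaged across draws *in raw-feature space* (the
z-transform is folded into the weights first), because averaging in
standardized space would mix incompatible scalings. Hold-out folds are
every 20th trial, so they are uniformly spread across the session; only
correct trials are used. The overall classifier uses 18 bins (every third
bin from 0.1 s onward, 60-ms spacing) × units as predictors; the per-bin
mode uses one bin at a time to trace the accuracy time course.

Significance is a paired two-tailed t-test of the 20 fold accuracies
against a surrogate trained with identical machinery (same early-stopping
draw seeds) on shuffled training/early-stopping labels, hold-out labels
intact. Shuffle-within permutes hold-out unit identities inside the
module (a 1-unit module is the identity, flagged); shuffle-across
substitutes donor-module units, subsampling without replacement when the
donor is larger and resampling with replacement when smaller, fresh draws
per iteration (100 by default). Boundary response similarity correlates
two units' binned response curves (0–1.2 s) per trial and averages across
trials, restricted to units spiking in at least half of trials.

No-leak property: z-scoring and early stopping see only training data;
on label-independent features the hold-out accuracy stays inside the
binomial chance interval (tested).

## 7. The synthetic-data generator

The generator is a first-class module and defines the package's reference
simulation conditions:

* **Lattices** 8×8 (default) or 10×10 minus corners, 0.4 mm pitch.
* **Planted modules** are rectangular blocks (4-connected, convex), the
  tiling chosen to make blocks near-square and the block→label map
  shuffled by seed; the default target diameter is 1.3 mm, which a 4×4
  block at 0.4 mm pitch meets (2R_g = 1.265 mm).
* **LFP** is a stable VAR (default order 8, 1 kHz) with damped-oscillator
  coupling kernels: within-module ordered pairs couple through a kernel
  centered at 100 Hz (broadband gamma), across-module pairs at 8 Hz,
  giving the within/gamma vs across/low-frequency asymmetry the spectral
  analyses probe. Default coupling scales are 0.15 (within) and 0.05
  (across) — a 3:1 ratio — with densities 0.35/0.10, plus a directed ring
  through each module so no electrode is isolated from its own module
  (without the ring, low-density draws occasionally leave an electrode
  with no within-module edge, making exact recovery impossible in
  principle). If the companion spectral radius reaches 0.95 all
  cross-couplings are scaled down jointly, preserving the within:across
  ratio; an unstable tensor passed directly to the simulator is rejected
  with its radius in the message. Sessions are 20 independent 5-s blocks
  (fresh innovations, 500-sample burn-in per block); multiple sessions
  share one ground truth.
* **Spiking** units sit on random electrodes and inherit their
  electrode's module. Baseline rates are log-normal around 1.5 sp/s (the
  scale typical of human temporal-lobe units); each module prefers one of
  four stimulus categories with gain 3, and a unit's gain vector mixes
  its module's tuning with a random unit-specific tuning according to the
  within-module tuning correlation (default 0.8; 1 = identical tuning).
  Rates follow `baseline · (1 + (gain − 1) · exp(−(t − latency)²/2w²))`
  and spikes are drawn as an inhomogeneous Poisson process (exact
  thinning for gains < 1). Trials are balanced across categories, all
  marked correct, in sets of 60 flanked by 2-s baselines.

What the generator does *not* emulate — and hence what green tests do not
establish about real recordings: 1/f background spectra, volume
conduction and shared-noise structure beyond the common average,
nonstationarity within and across blocks, epileptiform artifacts with
temporal structure, spike-waveform variability and sorting errors,
behavioral response-time variability, and incorrect trials. Passing the
planted-recovery tests shows the pipeline is correct and well-calibrated
under its own model class, not that cortex is modular.

## 8. Problem sizes used by the test suite

Chosen as the package's own verification design: identity and calibration
checks use 16-channel systems (order-4 truths, 20×5-s blocks; the
family-wise-error simulation uses 200 independent-channel runs at 10×5-s
blocks); exhaustive-oracle equivalence uses 20 random 6-node, 2-layer
networks against best-of-500-restart Louvain; planted-partition recovery
uses the full 8×8 array with 4 modules, 3 sessions × 10 blocks, at 20
seeds; the functional-contrast battery runs 20 seeds of 10-channel
spectral systems and 16-unit decoding sessions (80 trials, 3
early-stopping draws, 10 shuffle iterations). The full-scale defaults
(20 blocks, 500 restarts, 50 draws, 100 iterations, 500 surrogates)
remain the exported defaults.

## 9. Known limitations

* The conditional spectral decomposition's integral identity is
  approximate at strong coupling (see §3); discrepancies surface in the
  identity diagnostics rather than being silently absorbed.
* The χ² null for edge significance is asymptotic; very short blocks make
  it anti-conservative. Block lengths of a few seconds at 1 kHz are safe.
* Compactness and boundary analysis assume a planar lattice; no
  across-depth geometry.
* The exhaustive modularity oracle is limited to ~13 node–layer pairs by
  Bell-number growth.
* Session I/O uses plain-text CSV/TSV/JSON containers; for multi-GB
  recordings a binary container would be preferable.
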