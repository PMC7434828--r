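---
title: "Invariant and selective complex-cell codes from group-orbit pooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant and selective complex-cell codes from group-orbit pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbipool)
```

## The model

A **simple cell** is a linear filter followed by a pointwise nonlinearity,
$s(x) = \sigma(w^\top x)$, and a **complex cell** sums a bank of $N$ simple
cells, $c(x) = \sum_{i=1}^N \sigma(w_i^\top x)$. The stimuli are assumed to
come structured into **orbits** of a finite orthogonal group
$\mathcal{G} \subset O(d)$: the input set is
$S = \{\, g\,x_q : g \in \mathcal{G},\ q = 1,\dots,Q \,\}$ for $Q$ distinct
base stimuli. Orbits formalize "the same object under nuisance
transformations" (shifts, rotations, reflections), and they partition the
input space into equivalence classes.

Three facts drive everything in this package:

1. **Solution-space equivariance.** For any unsupervised loss of the form
   $L(W, S) = \sum_{i,j} f(\sigma(w_i^\top x_j))$ — a class containing
   Hebbian, Oja, Földiák and ICA-style rules — the gradient satisfies
   $\nabla L(gW, S) = g\,\nabla L(W, S)$ whenever $S$ is a union of
   complete orbits. Hence if $w^*$ is reachable by the learning dynamics
   at a checkpoint that is a multiple of $|\mathcal{G}|$ presentations, so
   is $g\,w^*$ for every $g$: the solution set is a union of orbits.
   (`gradient_equivariance_residual()` measures the violation; it sits at
   float round-off on orbit-complete data and grows visibly when orbits
   are truncated, e.g. via `subsample_orbits()`.)

2. **Orbit pooling gives invariance.** If the bank's weights are the orbit
   $\{g\,\bar w\}$ of one template, then
   $c(gx) = \sum_i \sigma(x^\top g^\top g_i \bar w) = c(x)$ by closure of
   the group. For permutation groups the responses to $x$ and $gx$ are the
   same floating-point multiset, so with a Heaviside nonlinearity the
   invariance is *exact*, not approximate — the package asserts equality,
   not closeness (`invariance_residual()`).

3. **Threshold families give selectivity.** With a family of Heaviside
   nonlinearities $\sigma_z = H(\cdot - z)$, the complex response
   $c_z(x) = \sum_i H(x^\top g_i w - z)$ is the complemented, scaled
   empirical CDF of the simple-cell response set. The CDF is a maximal
   invariant for the permutation induced by the group action: two stimuli
   get the same threshold profile if and only if their response multisets
   coincide, i.e. (generically) iff they lie in the same orbit.
   `full_threshold_grid()` realizes this exactly at finite resolution by
   placing one threshold between every pair of consecutive distinct
   observed responses, plus two flanking ones; over that grid
   `signature_distance()` is zero iff the sorted response vectors agree.

## Learning and wiring

Training maximizes the total nonlinear response energy subject to an
orthonormality (Stiefel) constraint,
$$\max_U\ \|\sigma(U^\top S)\|_F^2 + \lambda\,\|\sigma(U^\top
S_\mathrm{new})\|_F^2 \quad \text{s.t.} \quad U^\top U = I,$$
by projected gradient ascent with a QR retraction
(`constrained_maximize()`). Ascent — Hebbian potentiation — is used
throughout: the online update rule and the experimental protocol describe
the same response-energy objective, and we treat the sign conventions
that appear alongside it as notation, not semantics. The plain online
form (full-batch ascent on $L$, `train_simple_cells()`) is also provided;
its epoch checkpoints land at multiples of $|\mathcal{G}|\,Q$
presentations, the schedule under which equivariance holds.

A single finite run produces *one* representative of each solution orbit,
not an orbit: empirically, learned frames on toy data sit far from any
exact orbit (residuals of order 1 under `is_weight_orbit()`). The wiring
step restores the structure the theory needs. The candidate pool is the
group-orbit closure of the learned columns (each $g\,u_i$ is an equally
valid solution by equivariance); then `aggregate_orbit()` repeats the
maximal-response selection
$\bar w = \arg\max_w \sum_j f(\sigma(w^\top s_j^\mathrm{new}))$,
excluding already-selected and near-duplicate candidates. Because the
pooled response is constant on weight orbits over orbit-complete
$S_\mathrm{new}$, the iterated argmax walks through the orbit of the best
template, and the wired complex cell is exactly invariant. This
train → closure → wiring chain is tested end to end.

### Why the frame has at most $d$ columns

An orthonormal frame $U \in \mathbb{R}^{d \times N}$ requires
$N \le d$. The dihedral group on $\mathbb{R}^6$ has order 12, so a
12-cell orthonormal frame cannot exist; training uses
$N_\mathrm{cells} = \min(d, |\mathcal{G}|)$ and the orbit closure in the
wiring step restores all $|\mathcal{G}|$ simple cells of the complex
cell. For the cyclic group on $\mathbb{R}^6$ and the patch-rotation group
the two numbers coincide anyway.

## Nonlinearities and numerical choices

* **Heaviside for evaluation, logistic for gradients.** The Heaviside
  derivative is degenerate, so all gradient computations use the logistic
  surrogate $\sigma_\beta(t) = (1 + e^{-\beta(t - z)})^{-1}$ with
  $\beta = 10$ by default; all signatures, distances and invariance
  checks use the exact Heaviside. $\beta = 10$ puts unit-norm responses
  (which lie in $[-1, 1]$ by Cauchy–Schwarz) well into the saturating
  regime without destroying the gradient signal.
* **Training threshold $z = 0$.** A threshold far below every activation
  makes all responses saturate at 1 and the response-energy objective
  constant — nothing can be learned there. The all-pass convention is
  still available (`big_negative_threshold()`) and is what makes the
  square loss equal $N_\mathrm{cells} \times R$ exactly, a property the
  tests use.
* **Boundary convention $H(0) = 1$.** Closed at zero, so a threshold
  below the minimum response yields the full count. Ties between random
  thresholds and responses have probability zero; midpoint grids avoid
  them by construction.
* **Cancellation-aware matching.** Orbit-completeness and
  weight-orbit checks match columns via the expanded quadratic form (for
  speed) but always recompute the residual of the matched pair from the
  column difference: the expanded form loses half the machine digits to
  cancellation near zero, which matters at the 1e-8 tolerances used.
* **Deterministic retraction.** The QR retraction fixes the signs of the
  diagonal of $R$, making the ascent path a pure function of the seed.
* **Tolerances.** Permutation-matrix groups are checked at 1e-10 or
  exactly; rotation matrices at 1e-8 (trigonometric round-off);
  backtracking step-halving guarantees monotone objective traces, which
  the tests assert rather than assume.

## The synthetic stimulus generators

`sample_base_points()` draws base stimuli uniformly from the unit ball
(Gaussian direction, radius $\propto U^{1/d}$ — exact and seedable);
`build_orbit_dataset()` expands them into full orbits and rejects base
points that collide in one orbit (a probability-zero event, checked
exhaustively up to $Q = 200$). The experimental presets use 100 training
orbits, 2 new-input orbits and a test set of orbits in dimension 6, with
the cyclic (order 6, abelian) and dihedral (order 12, non-abelian)
permutation groups.

Rotated natural-image patches are replaced by a synthetic stand-in:
`make_toy_patches()` generates smoothed Gaussian random fields on a polar
grid of `radius` rings × `n_angles` sectors plus a fixed center pixel
(`patch_rotation_group()`), so that every rotation is an **exact pixel
permutation** — the finite-orthogonal-group assumption holds with zero
residual, where raster-grid rotations would need interpolation and break
orthogonality. The `smoothness` parameter (Gaussian correlation length in
grid cells, default 1) emulates the spatial correlation of natural
patches; `smoothness = 0` gives white noise. Base patches are scaled to
unit norm so response ranges match the toy data.

What the stand-in does and does not show: it reproduces the *structural*
protocol (radius-10 patches, six rotation angles, 100 orbits) and the
qualitative effect that correlated, naturalistic stimuli produce markedly
more intra/inter distance overlap than isotropic toy stimuli — because
distinct smooth patches share low-frequency structure and their
finite-threshold codes collide more often. It does not reproduce any
numerical property of actual natural images, and passing tests on it says
nothing about pixel statistics, contrast normalization or interpolation
artifacts of real patches.

## Distance statistics and the finite-threshold analysis

The experiments compare intra-orbit with inter-orbit code distances
$\mathrm{dist}(x, y) = \sum_z |c_z(x) - c_z(y)|$. With full grids and a
wired orbit bank, intra distances are exactly 0 and inter distances are
positive integers — perfectly separated distributions. With the
finite-threshold code (10 random thresholds, the experimental regime)
selectivity is partially lost: some cross-orbit pairs collide at 0. The
overlap of the two log-distance histograms is summarized by the overlap
coefficient $\sum_b \min(p_\mathrm{intra}(b), p_\mathrm{inter}(b))$ with
a $10^{-12}$ floor before taking logs (`overlap_fraction()`); because it
is a collision statistic it has high variance across threshold draws, so
evaluations average it over 10 independent 10-threshold grids.

Two further measurements:

* **Similarity vs. threshold count.** The mean cosine similarity between
  cross-orbit codes as a function of the number of random thresholds
  rises to a plateau once the grid resolves the response sets. Two
  conventions matter and are documented in
  `cosine_similarity_curve()`: thresholds are drawn from the
  ensemble-wide response range, and a draw under which a stimulus has an
  all-zero code contributes similarity 0 (an empty code carries no
  agreement). Counting empty codes as missing instead makes the curve
  start near 1 at tiny $K$ (two positive count scalars always have
  cosine 1) and *decrease*, which is a statement about the positive-cone
  geometry of count vectors, not about selectivity. Single-pair curves
  are noise-dominated; `cosine_curve_report()` averages over 30
  cross-orbit pairs, mirroring the large-test-set protocol.
* **Hoeffding coverage.** With thresholds $z_q$ drawn uniformly in the
  response range, the per-threshold summand
  $d(z) = |c_z(x) - c_z(y)| / N_\mathrm{cells} \in [0, 1]$ has an exactly
  computable expectation (it is piecewise constant between observed
  responses), and the $Q$-threshold mean concentrates around it:
  $\Pr\{|\hat{\mathrm{dist}} - \mathrm{dist}| > \epsilon\}
  \le 2 e^{-Q\epsilon^2 / (2p)}$ with the standard range constant
  $p = (b - a)^2/4 = 1/4$. `hoeffding_coverage()` verifies the bound by
  Monte Carlo; normalizing the summand is what keeps the bound
  informative rather than vacuous.

## Worked example

```{r example}
G <- cyclic_permutation_group(6)
w <- sample_base_points(1, 6, seed = 1)[, 1]
bank <- orbit_bank(G, w / sqrt(sum(w^2)))

x <- sample_base_points(1, 6, seed = 2)[, 1]
gx <- as.numeric(G$elements[[4]] %*% x)  # same orbit
y <- sample_base_points(1, 6, seed = 3)[, 1]  # different orbit

grid <- full_threshold_grid(bank, cbind(x, gx, y))
c(intra = signature_distance(x, gx, bank, grid),
  inter = signature_distance(x, y, bank, grid))
```

The scripted experiments chain data generation, constrained learning,
orbit wiring and evaluation for all three presets:

```{r figure1, eval = FALSE}
fig <- run_figure1(seed = 1)
fig$comparison
```

## Problem sizes

The default scripted chain uses 100 training orbits, 2 new-input orbits,
a 200-orbit test set and 200 sampled pairs per class, with the
10-threshold overlap averaged over 10 grids and the similarity curve over
30 pairs × 50 replicate grids; the whole three-experiment chain takes a
few seconds on one CPU. These sizes were chosen so that every sampled
statistic is stable across seeds while the suite stays desk-scale; the
full 1000-orbit protocol is a single `Q_test` argument away.

## Limitations

* Only finite orthogonal groups are covered: no Lie groups, non-group
  deformations, or non-orthogonal actions.
* The maximal-invariant guarantee is exact for permutation groups;
  rotation groups inherit trigonometric round-off (residuals ≤ 1e-8).
* A single constrained-maximization run does not land on an orbit; the
  wiring step depends on the orbit closure of the learned columns. This
  is a faithful rendering of the theory (which constrains the solution
  *set*, not a particular run), but it means the pipeline's invariance
  is a property of the closure + wiring, not of raw gradient ascent.
* Moment-based pooling alternatives (mean, energy, max) are noted in the
  finite-threshold analysis but not implemented.
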