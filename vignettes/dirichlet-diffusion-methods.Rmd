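---
title: "Dirichlet diffusion score models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet diffusion score models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DirichletDiffusion)
```

## The model

Discrete sequences — DNA (k = 4), protein (k = 20), Sudoku cells
(k = 9) — are awkward for score-based diffusion models because the
standard forward processes live in unconstrained Euclidean space and
converge to Gaussians. This package implements a continuous-time
diffusion that lives on the probability simplex itself and converges to
a Dirichlet distribution, so that one-hot data diffuse from the
vertices of the simplex into flat noise without ever leaving the space
of category-probability vectors.

The univariate building block is the Jacobi diffusion on [0, 1],

$$dx = \tfrac{s}{2}\,[a(1-x) - b x]\,dt + \sqrt{s\,x(1-x)}\,dw,$$

whose stationary law is Beta(a, b). The diffusion coefficient vanishes
and the drift points inward at both endpoints, so trajectories are
confined to [0, 1]. Its generator has polynomial eigenfunctions
$R_n^{(a,b)}$ (Jacobi polynomials mapped to [0, 1], orthogonal under
the Beta(a, b) weight) with eigenvalues
$\lambda_n = -\tfrac12 s\,n(n - 1 + a + b)$, which gives a spectral
series for the transition density

$$p(x_t \mid x_0) = \mathcal{B}_{a,b}(x_t)\Big(1 + \sum_{n \ge 1}
e^{\lambda_n t}\, d_n\, R_n(x_0)\, R_n(x_t)\Big),$$

with $d_n = 1/\int_0^1 \mathcal{B}_{a,b} R_n^2$. Both the density and
its score $\partial_{x_t} \log p$ are evaluated analytically
(`transitionLogDensity`, `transitionScore`).

A k-category state is represented through the stick-breaking map
$x_1 = v_1,\ x_2 = (1-v_1)v_2,\ \ldots$ of k − 1 independent sticks.
With stick laws Beta(1, k−1), …, Beta(1, 1) the stationary law of x is
the flat Dirichlet (`flatStickBreaking`). A one-hot datum at category c
pins sticks 1..c (zeros then a one); sticks after the first 1 are
*undetermined* and are treated as stationary throughout — they never
need to be sampled at time zero, and their score is the stationary Beta
score at every t. Scores convert between v- and x-space through the
stick-breaking Jacobian (`scoreVToX` / `scoreXToV`).

Training is denoising score matching against the forward transition
scores, weighted by $GG^\top$ — in v-space the diagonal weight
$s_j v_j (1 - v_j)$ — which makes the loss invariant under any smooth
bijection of the state (checked numerically in the test suite by
computing the same loss in x-space). Because every one-hot coordinate
starts at exactly 0 or 1, forward samples and scores are pre-computed
once per (process, time, init) cell into a dictionary
(`buildCache`) and looked up during training.

Sampling integrates the reverse-time SDE per stick,

$$dx = \Big\{\tfrac{s}{2}[a(1-x) - bx] - s(1-2x)
 - s\,x(1-x)\,\hat s_\theta\Big\}dt + \sqrt{s\,x(1-x)}\,d\bar w,$$

from an exact stationary Dirichlet draw at T down to a small cutoff,
followed by argmax (default) or categorical discretization.
Likelihoods come from the probability-flow ODE (drift
$\tilde f = \tfrac{s}{2}[a(1-v)-bv] - \tfrac{s}{2}(1-2v) -
\tfrac{s}{2}v(1-v)\hat s_\theta$) with the instantaneous
change-of-variable trace accumulated by Hutchinson probes, and a
discrete-data ELBO that combines the forward-diffusion entropy at a
small time t0, the categorical emission $\prod_i x_{i,y_i}$, and the
ODE likelihood from t0 upward.

## Tunable parameters

* **(a, b) per stick** — fixed by the target stationary Dirichlet; the
  flat preset is the default and the only one used by the shipped
  tasks.
* **Speed factor s** (default 1) — rescales diffusion time. The
  literature also uses a speed proportional to the stationary shapes;
  because the exact intended normalization is ambiguous in print, s is
  exposed as a free parameter rather than hard-coding a second preset.
* **Time horizon T = 4, cutoff t0 = 0.01** — at T = 4 the slowest
  spectral mode $e^{\lambda_1 t}$ of every flat-preset stick has
  decayed below 1e-2, so the forward process is effectively stationary;
  t0 is bounded below by the truncation floor (below ~5e-3 the spectral
  series would need more than the capped 200 terms to converge at the
  1e-8 tolerance).
* **Time grid** — 100 log-spaced points in [t0, T] by default; training
  times are drawn uniformly over the grid, matching the pre-sampled
  dictionary strategy. Importance weighting over time is not
  implemented; uniform sampling is documented as the (tunable) default.
* **EM resolution** — 1000 steps per unit time for generic forward
  simulation, 200 for cache building (the spectral-vs-simulation
  agreement tests pass at 200–400), with states clamped to
  [1e-6, 1 − 1e-6]. Clamping is a numerical safeguard, not a
  reflection: the drift already points inward at the boundary.
* **Sampler steps** — 100 base reverse steps by default; quality
  (e.g. Sudoku validity) is non-decreasing in both the step count and
  the time-dilation factor.

## Numerical choices

* **Spectral truncation** is adaptive: terms are included until the
  bound $e^{\lambda_n t} d_n \max R_n^2 < 10^{-8}$, capped at 200.
  Truncation can make the tail of the density slightly negative; values
  are clipped at 1e-40 before logs, and material negativity (beyond
  1e-3) triggers a warning.
* **Score-network preconditioning.** The learned score is parameterized
  as stationary score + net(v, t)/t. Empirically the denoising target's
  deviation from the stationary score scales like 1/t as t goes to 0 and
  vanishes at the horizon, so this keeps the network body at order-one
  outputs across the whole time range; without it the small-t cells
  dominate the loss and training stalls.
* **Time dilation.** Implemented as a stretched-clock reverse
  integration: with factor c the reverse drift (score term included) is
  applied c times per unit of model time while the injected noise keeps
  its undilated per-substep scale, i.e. the integrator takes c substeps
  of size dt/c whose drift term uses c dt. This is an interpretation of
  the technique (the primary description of its exact form is not
  available to this implementation) and is validated by its documented
  qualitative effect — sample quality increases monotonically with c on
  the Sudoku task — rather than by formula. c = 1 recovers exact
  unbiased reverse diffusion.
* **Category order** in the stick-breaking map is the identity
  permutation. Results are order-invariant in distribution; the
  stationarity tests exercise every coordinate.
* **Degenerate inputs.** Inverse stick-breaking flags coordinates after
  an exhausted stick as undetermined instead of dividing by zero;
  Jacobian-based conversions require interior points and apply an
  epsilon-interior projection defensively.
* **ODE integration** uses `deSolve::lsoda` with rtol = atol = 1e-5,
  accumulating the trace alongside the state; Hutchinson probes are
  standard normal with directional derivatives by central finite
  differences (step 1e-5). For small stick dimension the exact
  Jacobian trace (2D drift evaluations per step) costs about the same
  as a handful of probes and removes the dominant Monte-Carlo variance
  of the ELBO, so the shipped ELBO evaluations use
  `exactTrace = TRUE`; probe-based estimation is the scalable path and
  is cross-checked against the exact trace in the test suite.

## The synthetic data generators

The package generates all of its own inputs:

* **i.i.d. categorical toys** — Bernoulli(p)-style positions used for
  end-to-end parameter-recovery checks (the default p = 0.7 with 2000
  evaluation samples matches the recovery tolerance ±0.03 used in the
  acceptance checks).
* **Sudoku** — a correct-by-construction randomized backtracking
  generator (the heuristic generator used to produce the original
  training streams is not reproducible from its description, and its
  printed ~0.3% sampler validity is therefore not a target here). The
  4×4 variant has exactly 288 valid grids, enumerated exhaustively as
  an exact support for distribution-level tests; the mixture score over
  that support is analytically computable, which gives an
  implementation-independent oracle for the whole reverse-sampling
  path.
* **Promoter-like records** — sequences with a PWM-planted motif
  upstream of a central "TSS" and a paired nonnegative signal profile
  built as Gaussian bumps keyed to the motif and TSS positions with
  multiplicative noise, normalized to a configurable expression level.
  These emulate only the *shape* of TSS-centered promoter data
  (sequence + per-position initiation signal). They do not reproduce
  genomic base composition, motif grammar, or the long-tailed dynamic
  range of real CAGE signal — so passing tests on them demonstrates
  that the conditional machinery works, not that the package reproduces
  human-promoter modeling results.

## Problem sizes used by the tests

The shipped test-and-acceptance surface is deliberately desk-scale:
the Bernoulli toy trains a per-position MLP (5000 Adam steps, batch
128) in about a minute of CPU; the mini-Sudoku model is a 4-block,
width-64, 4-head relational transformer over 16 cells trained for 4400
steps at effective batch 32 (several CPU-minutes); ELBO evaluations
use a handful of Monte-Carlo draws with the exact trace. Full-scale 9×9 Sudoku (20 blocks,
81 cells) and 1024-bp conditional promoter design are configured in
`inst/configs/` and run through the same code paths, but their
training budgets are far beyond interactive CPU use; their printed
accuracies are not recomputed at desk scale.

## Known limitations

* Conditional generation uses replacement inpainting: clamped
  positions are overwritten at every reverse substep with
  forward-diffused versions of their fixed values. Clamps are honored
  exactly in the output, but the unclamped positions receive the
  conditioning information only through the score model's view of the
  current state, and the completion quality plateaus below the
  unconditional sample quality on the mini-Sudoku task even when the
  sampler is driven by the exact mixture score. Resampling-style
  inpainting schedules that close this gap are not implemented.

* The 288-grid 4×4 Sudoku support is small enough that a
  moderate-capacity network can learn its score; success there shows
  the machinery is correct, not that 9×9 performance is reproduced.
* The ELBO's tightness degrades if t0 approaches the spectral floor
  from above and the forward EM draws are too coarse; the default
  (t0 = 0.01, 2000 EM steps per unit time) keeps the bias well inside
  the Monte-Carlo error of the shipped tests.
* Sampling efficiency: forward sampling for training needs k − 1
  univariate processes per position. The published shortcut that
  reduces this to a single univariate process is described only in
  material unavailable here; the pre-sampled dictionary makes this an
  efficiency gap, not a correctness gap.
* The conditional sequence architecture is a documented stand-in (a
  dilated convolutional residual stack); the original conditional
  promoter architecture is not printed in the available text.

## A worked toy example

```{r toy, eval = FALSE}
spec <- flatStickBreaking(2)
cache <- buildCache(spec, defaultTimeGrid(n = 60), nPerCell = 1000,
    seed = 7)
sampler <- function(n) matrix(1L + (runif(n * 4) < 0.7), n, 4)
model <- trainScoreModel(scoreMLP(2, seed = 11), sampler, cache, spec,
    trainingConfig(batchSize = 128, lr = 2e-3, steps = 3000, seed = 5))
set.seed(9)
out <- sampleReverse(model, spec, samplerConfig(nSteps = 200), 2000, 1)
mean(out$categories == 2)   # ~0.70: the generator's Bernoulli weight
```
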