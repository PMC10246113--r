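# DirichletDiffusion

Score-based generative diffusion for **discrete sequences** — DNA,
Sudoku grids, categorical toys — built on a continuous-time diffusion
that lives on the probability simplex and converges to a Dirichlet
stationary distribution. One-hot data diffuse from the simplex
vertices into flat noise; a learned score model reverses the process
to generate new sequences, optionally conditioned by inpainting or a
per-position signal track.

The package is aimed at researchers in regulatory genomics and
generative modeling who want a fully inspectable, CPU-scale R
implementation of simplex diffusion: every component — the spectral
transition density, the stick-breaking construction, the weighted
score-matching loss, the reverse SDE and probability-flow ODE — is
exposed as a documented function with property-based tests.

## The model

The univariate building block is the Jacobi diffusion on [0, 1],

```
dx = (s/2) [a(1-x) - b x] dt + sqrt(s x (1-x)) dw ,
```

with stationary law Beta(a, b) and spectral transition density

```
p(x_t | x_0) = B_ab(x_t) · (1 + Σ_{n≥1} exp(λ_n t) d_n R_n(x_0) R_n(x_t)),
λ_n = -(1/2) s n (n - 1 + a + b),
```

where `R_n` are Jacobi polynomials orthogonal under the Beta(a, b)
weight. A k-category variable is the stick-breaking image
`x1 = v1, x2 = (1-v1) v2, ...` of k−1 independent Jacobi sticks with
laws Beta(1, k−1), …, Beta(1, 1), which makes the stationary law of x
the flat Dirichlet. Training minimizes denoising score matching with
the GGᵀ weighting `s v (1-v)` (invariant under change of variables);
sampling integrates the reverse-time SDE with optional *time dilation*
to concentrate samples in high-density regions; likelihoods come from
the probability-flow ODE (Hutchinson trace) and a discrete-data ELBO.

## Worked example: a two-category toy

```r
library(DirichletDiffusion)

spec  <- flatStickBreaking(2)                      # Beta(1,1) stick
cache <- buildCache(spec, defaultTimeGrid(n = 60), # pre-sampled forward
    nPerCell = 1000, seed = 7)                     #   draws + scores
sampler <- function(n) matrix(1L + (runif(n * 4) < 0.7), n, 4)
model <- trainScoreModel(scoreMLP(2, seed = 11), sampler, cache, spec,
    trainingConfig(batchSize = 128, lr = 2e-3, steps = 3000, seed = 5))

set.seed(9)
out <- sampleReverse(model, spec, samplerConfig(nSteps = 200), 2000, 1)
mean(out$categories == 2)
#> [1] 0.7335
```

The generator emits category 2 with probability 0.7; reverse-diffusion
samples from the trained score recover that frequency to within a few
percent (0.7335 over 2000 draws above; the residual deviation combines
Monte-Carlo error with the small bias of the learned score). The same pipeline scales to
structured data: `scoreSudokuNet()` is a relational transformer whose
attention is biased by an exact binary encoding of shared
rows/columns/blocks, `inpaintSample()` solves puzzles by clamping
clues, and `scoreSequenceNet()` generates DNA conditioned on a
per-position signal profile (see the vignette and
`inst/configs/` for the full-scale 9×9 Sudoku and 1024-bp promoter
configurations).

A command-line front end ships in `inst/scripts/ddsm`
(`cache-build | train | sample | solve | likelihood`).

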