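# Shared oracles and lazily built fixtures. Heavy objects (caches,
# trained models) are built once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
    .fixtures[[name]]
}

# numeric quadrature of a density over [0,1]
quadIntegral <- function(f, lower = 0, upper = 1, rel.tol = 1e-9) {
    stats::integrate(f, lower, upper, rel.tol = rel.tol,
        subdivisions = 400L)$value
}

# KS test of samples against a density given by unnormalized log-density
ksAgainstDensity <- function(samples, logDensity) {
    cdf <- function(q) vapply(q, function(qq)
        stats::integrate(function(x) exp(logDensity(x)), 0, qq,
            rel.tol = 1e-8, subdivisions = 400L)$value, numeric(1))
    suppressWarnings(stats::ks.test(samples, cdf))
}

# equispaced points covering the bulk of a transition law (where the
# log-density is within logDrop of its maximum); score checks are
# meaningful only where the density is numerically representable
bulkGrid <- function(proc, x0, t, n = 10, logDrop = 12) {
    xs <- seq(0.02, 0.98, length.out = 400)
    ld <- transitionLogDensity(proc, x0, xs, t)
    keep <- xs[ld > max(ld) - logDrop]
    seq(min(keep), max(keep), length.out = n)
}

# exact two-point mixture score for k = 2 data {0, 1} with weights
# (w0, w1): d/dv log[w0 p(v|x0=0) + w1 p(v|x0=1)]
exactMixtureScore <- function(w0, t, proc = JacobiProcess(1, 1)) {
    function(v) {
        p0 <- exp(transitionLogDensity(proc, 0, v, t))
        p1 <- exp(transitionLogDensity(proc, 1, v, t))
        s0 <- transitionScore(proc, 0, v, t)
        s1 <- transitionScore(proc, 1, v, t)
        (w0 * p0 * s0 + (1 - w0) * p1 * s1) /
            (w0 * p0 + (1 - w0) * p1)
    }
}

# ScoreModel wrapping the exact mixture score (i.i.d. positions, k = 2)
exactMixtureModel <- function(w0, spec) {
    force(w0)
    forward <- function(params, v, t, condition = NULL, tape = NULL) {
        tt <- max(t[1], 0.005001)
        f <- exactMixtureScore(w0, tt)
        matrix(f(as.numeric(v)), nrow(v), ncol(v))
    }
    new("ScoreModel", params = list(), forward = forward, space = "v",
        meta = list(kind = "exact-mixture"))
}

# shared k = 2 cache and Bernoulli(0.7) toy model (category 2 has
# probability 0.7, i.e. stick v starts at 0 with probability 0.7)
toyCache <- function() fixture("toyCache", function()
    buildCache(flatStickBreaking(2), defaultTimeGrid(n = 60L),
        nPerCell = 1000L, seed = 7, nStepsPerUnit = 200))

toyBernoulliModel <- function() fixture("toyModel", function() {
    spec <- flatStickBreaking(2)
    sampler <- function(n)
        matrix(1L + (stats::runif(n * 4L) < 0.7), n, 4L)
    trainScoreModel(scoreMLP(2, hidden = 64L, seed = 11),
        sampler, toyCache(), spec,
        trainingConfig(batchSize = 128L, lr = 2e-3, steps = 5000L,
            seed = 5, lrDecay = 0.2))
})

# small random-weight k = 3 model with a nontrivial Jacobian, for
# trace-estimator comparisons
toyLikeK3Model <- function() fixture("k3model", function()
    scoreMLP(3, hidden = 16L, seed = 17))

# mini-Sudoku (4x4) cache and trained relational transformer
miniSudokuCache <- function() fixture("miniCache", function()
    buildCache(flatStickBreaking(4), defaultTimeGrid(n = 50L),
        nPerCell = 600L, seed = 7, nStepsPerUnit = 200))

miniSudokuModel <- function() fixture("miniModel", function() {
    spec <- flatStickBreaking(4)
    gmat <- t(sapply(enumerateMiniGrids(), gridToCategories))
    sampler <- function(n)
        gmat[sample.int(nrow(gmat), n, replace = TRUE), , drop = FALSE]
    trainScoreModel(scoreSudokuNet(2L, nBlocks = 4L, dModel = 64L,
        nHeads = 4L, seed = 11), sampler, miniSudokuCache(), spec,
        trainingConfig(batchSize = 16L, lr = 1.5e-3, steps = 4400L,
            seed = 5, accumulate = 2L, lrDecay = 0.2))
})

miniValidity <- function(categories) {
    mean(apply(categories, 1L, function(r)
        isValidGrid(categoriesToGrid(r))))
}
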