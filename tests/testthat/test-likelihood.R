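test_that("probability-flow drift matches the printed combination", {
    spec <- flatStickBreaking(2)  # a = b = s = 1
    v <- c(0.3)
    sc <- 2
    # (1/2)[1(1-v) - v] - (1/2)(1-2v) - (1/2)v(1-v)s = -(1/2)v(1-v)s
    expect_equal(pfODEDrift(spec, v, sc), -0.5 * 0.3 * 0.7 * 2)
    spec2 <- StickBreakingProcess(3, a = c(2, 1), b = c(1, 3),
        s = c(2, 1))
    v2 <- c(0.4, 0.7)
    s2 <- c(1, -1)
    manual <- c(
        0.5 * 2 * (2 * 0.6 - 1 * 0.4) - 0.5 * 2 * (1 - 0.8) -
            0.5 * 2 * 0.4 * 0.6 * 1,
        0.5 * 1 * (1 * 0.3 - 3 * 0.7) - 0.5 * 1 * (1 - 1.4) -
            0.5 * 1 * 0.7 * 0.3 * (-1))
    expect_equal(pfODEDrift(spec2, v2, s2), manual)
    # stationary score makes the drift vanish identically
    m <- stationaryScoreModel(spec2)
    vv <- matrix(c(0.2, 0.5), 1)
    expect_equal(pfODEDrift(spec2, drop(vv),
        drop(scoreEval(m, vv, 1))), c(0, 0), tolerance = 1e-12)
})

test_that("ODE likelihood of the stationary model is the stationary law", {
    spec <- flatStickBreaking(3)
    m <- stationaryScoreModel(spec)
    cfg <- likelihoodConfig(nProbes = 4L)
    v0 <- matrix(c(0.3, 0.6, 0.5, 0.2), 2, byrow = TRUE)
    ll <- odeLogLikelihood(m, v0, spec, cfg)
    expected <- c(dbeta(0.3, 1, 2, log = TRUE) + dbeta(0.6, 1, 1,
        log = TRUE), dbeta(0.5, 1, 2, log = TRUE) + dbeta(0.2, 1, 1,
        log = TRUE))
    expect_equal(ll, expected, tolerance = 1e-4)
    # x-space conversion: flat Dirichlet density is constant (k-1)!
    llx <- odeLogLikelihood(m, c(0.3, 0.6), spec, cfg, space = "x")
    expect_equal(llx, log(2), tolerance = 1e-4)
    expect_error(odeLogLikelihood(m, c(0, 0.5), spec, cfg), "interior")
    expect_error(likelihoodConfig(t0 = 1e-4), "floor")
})

test_that("Hutchinson trace agrees with the exact Jacobian trace", {
    spec <- flatStickBreaking(3)
    model <- toyLikeK3Model()
    v0 <- c(0.35, 0.55)
    set.seed(9)
    hutch <- odeLogLikelihood(model, v0, spec,
        likelihoodConfig(nProbes = 64L))
    exact <- odeLogLikelihood(model, v0, spec,
        likelihoodConfig(exactTrace = TRUE))
    expect_equal(hutch, exact, tolerance = 0.05)
})

test_that("the ELBO lower-bounds the model's discrete likelihood", {
    # with the stationary (noise-only) model the implied discrete law
    # is uniform: log p(y) = -L log k; the ELBO must not exceed it
    spec <- flatStickBreaking(2)
    m <- stationaryScoreModel(spec)
    set.seed(10)
    y <- c(1L, 2L, 2L)
    r <- discreteELBO(m, y, spec, likelihoodConfig(nProbes = 4L),
        nMC = 6L)
    expect_lt(r$elbo, -3 * log(2) + 3 * r$se + 0.05)
    expect_equal(r$nllBitsPerSymbol, -r$elbo / (3 * log(2)))
})

test_that("trained toy ELBO respects and tightens toward the entropy", {
    # Bernoulli(0.7): the best achievable expected log-likelihood per
    # symbol is -H = 0.7 log 0.7 + 0.3 log 0.3
    spec <- flatStickBreaking(2)
    m <- toyBernoulliModel()
    set.seed(11)
    L <- 8L
    y <- 1L + (runif(L) < 0.7)
    exact <- sum(ifelse(y == 2L, log(0.7), log(0.3)))
    r <- discreteELBO(m, y, spec,
        likelihoodConfig(exactTrace = TRUE), nMC = 6L)
    expect_lt(r$elbo, exact + 3 * r$se + 0.1)
})
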