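test_that("zero-noise reverse step equals the drift formula", {
    spec <- flatStickBreaking(3)
    v <- matrix(c(0.3, 0.6), 1)
    sc <- matrix(c(0.5, -1), 1)
    dt <- 0.01
    z <- matrix(0, 1, 2)
    got <- reverseStep(spec, v, t = 1, sc, dt, noise = z)
    a <- spec@a; b <- spec@b; s <- spec@s
    drift <- 0.5 * s * (a * (1 - v) - b * v) - s * (1 - 2 * v) -
        s * v * (1 - v) * sc
    expect_equal(got, pmin(pmax(v - drift * dt, 1e-6), 1 - 1e-6))
    expect_error(reverseStep(spec, v, 1, sc, -0.1), "positive")
})

test_that("reverse trajectories remain inside the unit cube", {
    spec <- flatStickBreaking(4)
    m <- stationaryScoreModel(spec)
    set.seed(2)
    v <- stationaryStickSample(spec, 50)
    t <- 4
    for (i in 1:40) {
        v <- reverseStep(spec, v, t, scoreEval(m, v, t), 0.05)
        t <- t - 0.05
        expect_true(all(v >= 0 & v <= 1))
    }
})

test_that("stationary-score sampling yields uniform categories", {
    # reversing from the stationary law with the stationary score keeps
    # the flat Dirichlet, whose argmax-discretization is uniform over k
    spec <- flatStickBreaking(3)
    m <- stationaryScoreModel(spec)
    set.seed(3)
    out <- sampleReverse(m, spec, samplerConfig(nSteps = 60), 600, 2)
    tab <- table(factor(out$categories, levels = 1:3))
    expect_gt(chisq.test(as.numeric(tab))$p.value, 0.01)
})

test_that("exact two-point mixture score recovers the data weights", {
    # core correctness: with the analytic score of the diffused
    # two-point distribution {v0=0 w.p. 0.7, v0=1 w.p. 0.3}, reverse
    # sampling reproduces the weights
    spec <- flatStickBreaking(2)
    m <- exactMixtureModel(0.7, spec)
    set.seed(4)
    out <- sampleReverse(m, spec, samplerConfig(nSteps = 120), 600, 1)
    fr <- mean(out$categories == 2)  # category 2 <=> stick started at 0
    expect_equal(fr, 0.7, tolerance = 3 * sqrt(0.21 / 600))
})

test_that("categorical discretization draws from the simplex point", {
    spec <- flatStickBreaking(3)
    m <- stationaryScoreModel(spec)
    set.seed(5)
    cfg <- samplerConfig(nSteps = 30, discretization = "categorical")
    out <- sampleReverse(m, spec, cfg, 50, 2)
    expect_true(all(out$categories %in% 1:3))
})

test_that("inpainting clamps exactly and reduces to free sampling", {
    spec <- flatStickBreaking(4)
    m <- stationaryScoreModel(spec)
    set.seed(6)
    # all positions clamped -> output equals the clamps
    out <- inpaintSample(m, spec, samplerConfig(nSteps = 30), 1:4,
        c(2L, 3L, 1L, 4L), 8, 4)
    expect_true(all(out$categories ==
        matrix(c(2L, 3L, 1L, 4L), 8, 4, byrow = TRUE)))
    # no clamps -> same code path as sampleReverse
    set.seed(7)
    a <- inpaintSample(m, spec, samplerConfig(nSteps = 30), integer(0),
        integer(0), 5, 4)
    set.seed(7)
    b <- sampleReverse(m, spec, samplerConfig(nSteps = 30), 5, 4)
    expect_identical(a$categories, b$categories)
    expect_error(inpaintSample(m, spec, samplerConfig(), c(1, 1),
        c(2, 3), 2, 4), "contradictory")
    expect_error(inpaintSample(m, spec, samplerConfig(), 9, 2, 2, 4),
        "out of range")
})

test_that("partial clamps steer unclamped positions", {
    # with the exact mixture score for two-point k=2 data, clamping a
    # position to a value keeps that value after discretization
    spec <- flatStickBreaking(2)
    m <- exactMixtureModel(0.5, spec)
    set.seed(8)
    out <- inpaintSample(m, spec, samplerConfig(nSteps = 60), 1L, 1L,
        40, 2)
    expect_true(all(out$categories[, 1] == 1L))
    expect_true(all(out$categories[, 2] %in% 1:2))
})
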