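test_that("stick-breaking transform maps to the simplex and back", {
    expect_equal(stickToSimplex(0.3), c(0.3, 0.7))
    expect_equal(stickToSimplex(c(1, 0.4, 0.9)), c(1, 0, 0, 0))
    expect_equal(stickToSimplex(c(0.2, 0.375)), c(0.2, 0.3, 0.5))
    set.seed(4)
    for (k in c(2, 3, 5, 9)) {
        v <- matrix(runif(6 * (k - 1), 0.05, 0.95), 6)
        x <- stickToSimplex(v)
        expect_equal(rowSums(x), rep(1, 6))
        expect_true(all(x >= 0))
        inv <- simplexToStick(x)
        expect_true(all(inv$determined))
        expect_equal(inv$v, v, tolerance = 1e-9)
    }
})

test_that("inverse transform flags undetermined dims on one-hot input", {
    r <- simplexToStick(c(0, 0, 1, 0))
    expect_equal(r$v, c(0, 0, 1))
    expect_true(all(r$determined))
    r <- simplexToStick(c(1, 0, 0, 0))
    expect_equal(r$v[1], 1)
    expect_true(all(is.na(r$v[2:3])))
    expect_equal(r$determined, c(TRUE, FALSE, FALSE))
    r <- simplexToStick(c(0.2, 0.3, 0.5))
    expect_equal(r$v, c(0.2, 0.375))
})

test_that("flat preset yields the Dir(1,...,1) stationary law", {
    s2 <- flatStickBreaking(2)
    expect_equal(c(s2@a, s2@b), c(1, 1))
    s4 <- flatStickBreaking(4)
    expect_equal(s4@a, c(1, 1, 1))
    expect_equal(s4@b, c(3, 2, 1))
    expect_error(flatStickBreaking(1), ">= 2")
    # stationary draws pushed through the transform have the Dirichlet
    # marginal Beta(1, k-1) in every coordinate
    set.seed(11)
    k <- 4
    x <- stickToSimplex(stationaryStickSample(flatStickBreaking(k),
        10000))
    for (i in seq_len(k)) {
        suppressWarnings(ks <- ks.test(x[, i],
            function(q) pbeta(q, 1, k - 1)))
        expect_gt(ks$p.value, 0.01)
    }
})

test_that("closed-form Jacobian log-determinant matches numerics", {
    set.seed(2)
    for (k in c(3, 5)) {
        v <- runif(k - 1, 0.1, 0.9)
        km1 <- k - 1
        J <- matrix(0, km1, km1)
        h <- 1e-6
        for (j in seq_len(km1)) {
            vp <- v; vp[j] <- v[j] + h
            vm <- v; vm[j] <- v[j] - h
            J[, j] <- (stickToSimplex(vp)[1:km1] -
                stickToSimplex(vm)[1:km1]) / (2 * h)
        }
        expect_equal(stickLogDetJacobian(v),
            as.numeric(determinant(J)$modulus), tolerance = 1e-6)
    }
})

test_that("score change-of-variable is an exact involution", {
    set.seed(3)
    for (k in c(2, 4, 6)) {
        v <- matrix(runif(4 * (k - 1), 0.1, 0.9), 4)
        sv <- matrix(rnorm(4 * (k - 1)), 4)
        sx <- scoreVToX(v, sv)
        expect_equal(scoreXToV(v, sx), sv, tolerance = 1e-9)
    }
    # k = 2: x = (v, 1 - v), no log-det term: scores coincide
    expect_equal(scoreVToX(0.4, 2.5), 2.5)
    # flat Dirichlet has zero x-space score on the interior; its v-space
    # image is the product of stationary Beta stick scores
    spec <- flatStickBreaking(5)
    v <- c(0.2, 0.4, 0.6, 0.8)
    sv <- scoreXToV(v, rep(0, 4))
    anal <- (spec@a - 1) / v - (spec@b - 1) / (1 - v)
    expect_equal(sv, anal, tolerance = 1e-9)
    expect_error(scoreVToX(c(0, 0.5), c(1, 1)), "interior")
})

test_that("forward simplex diffusion reaches the flat Dirichlet law", {
    spec <- flatStickBreaking(3)
    set.seed(8)
    cats <- sample(1:3, 3000, replace = TRUE)
    fs <- forwardSampleSimplex(spec, cats, t = 6, nStepsPerUnit = 150)
    x <- stickToSimplex(fs$v)
    # chi-square uniformity over barycentric bins
    bins <- pmin(floor(x[, 1] * 3), 2) * 3 + pmin(floor(x[, 2] * 3), 2)
    tab <- table(bins)
    # reference bin masses from an exact Dirichlet sampler
    ref <- stickToSimplex(stationaryStickSample(spec, 30000))
    rbins <- pmin(floor(ref[, 1] * 3), 2) * 3 +
        pmin(floor(ref[, 2] * 3), 2)
    rtab <- table(factor(rbins, levels = names(tab)))
    cs <- suppressWarnings(chisq.test(as.numeric(tab),
        p = as.numeric(rtab) / sum(rtab)))
    expect_gt(cs$p.value, 0.01)
})

test_that("forward diffusion structure follows the one-hot datum", {
    spec <- flatStickBreaking(4)
    set.seed(5)
    fs <- forwardSampleSimplex(spec, c(1, 2, 4), t = 0.5)
    expect_equal(fs$determined[1, ], c(TRUE, FALSE, FALSE))
    expect_equal(fs$determined[2, ], c(TRUE, TRUE, FALSE))
    expect_equal(fs$determined[3, ], c(TRUE, TRUE, TRUE))
    # undetermined dims carry the stationary Beta score at any t
    und <- which(!fs$determined)
    j <- 2
    vund <- fs$v[1, 2]
    expect_equal(fs$score[1, 2],
        (spec@a[2] - 1) / vund - (spec@b[2] - 1) / (1 - vund))
    expect_error(forwardSampleSimplex(spec, c(0, 5), 1), "1..k")
})
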