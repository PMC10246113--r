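test_that("stationary law is Beta(a, b) with unit mass", {
    expect_equal(stationaryLogDensity(JacobiProcess(1, 1), 0.37), 0)
    expect_equal(stationaryLogDensity(JacobiProcess(2, 2), 0.5),
        log(1.5))
    for (ab in list(c(1, 1), c(1, 3), c(2, 2))) {
        p <- JacobiProcess(ab[1], ab[2])
        expect_equal(quadIntegral(function(x)
            exp(stationaryLogDensity(p, x))), 1, tolerance = 1e-8)
    }
    expect_error(stationaryLogDensity(JacobiProcess(1, 1), 1.2),
        "must lie")
})

test_that("generator eigenvalues are 0 at n = 0 and strictly decreasing", {
    expect_identical(jacobiEigenvalue(0, JacobiProcess(3, 5, 2)), 0)
    expect_equal(jacobiEigenvalue(1, JacobiProcess(1, 1, 1)), -1)
    expect_equal(jacobiEigenvalue(2, JacobiProcess(1, 3, 2)), -10)
    lam <- jacobiEigenvalue(0:20, JacobiProcess(1.5, 0.8, 1.3))
    expect_true(all(diff(lam) < 0))
    expect_error(jacobiEigenvalue(-1, JacobiProcess(1, 1)), "nonnegative")
})

test_that("modified Jacobi polynomials are an orthogonal eigenbasis", {
    for (ab in list(c(1, 3), c(2, 2), c(1.5, 0.7))) {
        p <- JacobiProcess(ab[1], ab[2])
        expect_equal(jacobiPolynomial(0, p, c(0.1, 0.9)), c(1, 1))
        for (m in 0:3) for (n in 0:3) {
            I <- quadIntegral(function(x)
                exp(stationaryLogDensity(p, x)) *
                jacobiPolynomial(m, p, x) * jacobiPolynomial(n, p, x))
            target <- if (m == n) 1 / jacobiNormConst(n, p) else 0
            expect_equal(I, target, tolerance = 1e-8)
        }
    }
})

test_that("polynomials satisfy the generator eigenrelation", {
    # (s/2) x(1-x) R_n'' + (s/2)[a(1-x)-bx] R_n' = lambda_n R_n,
    # second derivative taken by central finite differences
    p <- JacobiProcess(1, 3, 2)
    h <- 1e-4
    xs <- seq(0.15, 0.85, by = 0.1)
    for (n in 1:4) {
        R <- function(x) jacobiPolynomial(n, p, x)
        d1 <- jacobiPolynomial(n, p, xs, deriv = 1L)
        d2 <- (R(xs + h) - 2 * R(xs) + R(xs - h)) / h^2
        gen <- 0.5 * p@s * xs * (1 - xs) * d2 +
            0.5 * p@s * (p@a * (1 - xs) - p@b * xs) * d1
        expect_equal(gen, jacobiEigenvalue(n, p) * R(xs),
            tolerance = 1e-5)
    }
})

test_that("transition density is normalized and approaches stationarity", {
    for (ab in list(c(1, 1), c(1, 3), c(2, 2))) {
        p <- JacobiProcess(ab[1], ab[2])
        for (t in c(0.25, 1, 4)) {
            I <- quadIntegral(function(x)
                exp(transitionLogDensity(p, 1, x, t)), rel.tol = 1e-8)
            expect_equal(I, 1, tolerance = 1e-3)
        }
    }
    # at large t every n >= 1 term has decayed: uniform for Beta(1,1)
    p11 <- JacobiProcess(1, 1)
    expect_equal(transitionLogDensity(p11, 0.2, 0.5, 100), 0,
        tolerance = 1e-10)
    expect_error(transitionLogDensity(p11, 0, 0.5, -1), "positive")
    expect_error(transitionLogDensity(p11, 0, 0.5, 1e-4), "floor")
})

test_that("Chapman-Kolmogorov holds across a time split", {
    p <- JacobiProcess(1, 3)
    t1 <- 0.4; t2 <- 0.6
    for (xt in c(0.25, 0.7)) {
        direct <- exp(transitionLogDensity(p, 1, xt, t1 + t2))
        conv <- quadIntegral(function(xm)
            exp(transitionLogDensity(p, 1, xm, t1) +
                vapply(xm, function(m) transitionLogDensity(p, m, xt,
                    t2), numeric(1))), rel.tol = 1e-7)
        expect_equal(conv, direct, tolerance = 1e-3)
    }
})

test_that("spectral density matches Euler-Maruyama simulation", {
    p <- JacobiProcess(1, 3)
    set.seed(42)
    for (t in c(0.25, 1)) {
        for (x0 in c(0, 1)) {
            xs <- forwardSampleEM(p, rep(x0, 2000), t,
                nStepsPerUnit = 400)
            ks <- ksAgainstDensity(xs, function(x)
                transitionLogDensity(p, x0, x, t))
            expect_gt(ks$p.value, 0.01)
        }
    }
})

test_that("analytic transition score matches finite differences", {
    h <- 1e-5
    for (ab in list(c(1, 1), c(1, 3), c(2, 2))) {
        p <- JacobiProcess(ab[1], ab[2])
        for (x0 in c(0, 1)) {
            for (t in c(0.05, 0.15, 0.4, 1, 3)) {
                xt <- bulkGrid(p, x0, t)
                sc <- transitionScore(p, x0, xt, t)
                fd <- (transitionLogDensity(p, x0, xt + h, t) -
                    transitionLogDensity(p, x0, xt - h, t)) / (2 * h)
                expect_equal(sc, fd, tolerance = 1e-4)
            }
        }
    }
    # stationary limits
    p11 <- JacobiProcess(1, 1)
    expect_equal(transitionScore(p11, 1, c(0.3, 0.8), 50), c(0, 0),
        tolerance = 1e-8)
    p22 <- JacobiProcess(2, 2)
    xt <- c(0.3, 0.6)
    expect_equal(transitionScore(p22, 1, xt, 50),
        1 / xt - 1 / (1 - xt), tolerance = 1e-6)
    expect_error(transitionScore(p11, 1, 0, 1), "interior")
})

test_that("EM sampler is boundary-confined, stationary and seeded", {
    p <- JacobiProcess(1, 3)
    set.seed(1)
    x <- forwardSampleEM(p, rep(0, 3000), t = 4, nStepsPerUnit = 200)
    expect_true(all(x >= 0 & x <= 1))
    # stationary mean a/(a+b) = 0.25
    expect_equal(mean(x), 0.25, tolerance = 3 * sd(x) / sqrt(3000))
    suppressWarnings(
        expect_gt(ks.test(x, function(q) pbeta(q, 1, 3))$p.value, 0.01))
    set.seed(99)
    a1 <- forwardSampleEM(p, c(0, 1), t = 1)
    set.seed(99)
    a2 <- forwardSampleEM(p, c(0, 1), t = 1)
    expect_identical(a1, a2)
    expect_error(forwardSampleEM(p, 0.5, 1, nStepsPerUnit = 0), ">= 1")
})
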