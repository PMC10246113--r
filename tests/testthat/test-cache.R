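test_that("cache cells hold confined samples with matching scores", {
    cache <- toyCache()
    for (key in names(cache@cells)) {
        for (ti in seq_along(cache@timeGrid)) {
            for (init in c("0", "1")) {
                cell <- cache@cells[[key]][[ti]][[init]]
                expect_true(all(cell$samples >= 0 & cell$samples <= 1))
                expect_true(all(is.finite(cell$scores)))
            }
        }
    }
    # spot-check: stored scores equal the spectral transition score at
    # the stored sample
    proc <- stickProcess(cache@spec, 1)
    ti <- 30L
    cell <- cache@cells[[1]][[ti]][["1"]]
    idx <- c(1, 50, 500)
    expect_equal(cell$scores[idx],
        transitionScore(proc, 1, cell$samples[idx],
            cache@timeGrid[ti]))
})

test_that("cache approaches stationarity at the horizon and is seeded", {
    cache <- toyCache()
    last <- length(cache@timeGrid)
    cell <- cache@cells[[1]][[last]][["0"]]
    set.seed(123)
    ref <- rbeta(2000, 1, 1)
    suppressWarnings(
        expect_gt(ks.test(cell$samples, ref)$p.value, 0.01))
    small <- function() buildCache(flatStickBreaking(2),
        defaultTimeGrid(n = 4L), nPerCell = 50L, seed = 3)
    expect_identical(small(), small())
    expect_error(buildCache(flatStickBreaking(2),
        timeGrid = c(1e-4, 1), nPerCell = 10L), "floor")
})

test_that("minibatches mirror each datum's determined structure", {
    cache <- fixture("k3cache", function()
        buildCache(flatStickBreaking(3), defaultTimeGrid(n = 20L),
            nPerCell = 800L, seed = 2))
    spec <- cache@spec
    set.seed(10)
    cats <- matrix(c(1L, 2L, 3L, 3L), 2, 2)
    mb <- drawMinibatch(cache, cats, tIndex = c(10L, 20L))
    expect_equal(dim(mb$v), c(2, 2, 2))
    expect_equal(mb$determined[1, 1, ], c(TRUE, FALSE))  # category 1
    expect_equal(mb$determined[1, 2, ], c(TRUE, TRUE))   # category 3
    expect_true(all(mb$v >= 0 & mb$v <= 1, na.rm = TRUE))
    # undetermined dims carry stationary Beta scores
    v12 <- mb$v[1, 1, 2]
    expect_equal(mb$score[1, 1, 2],
        (spec@a[2] - 1) / v12 - (spec@b[2] - 1) / (1 - v12))
    # time snapping
    mb2 <- drawMinibatch(cache, cats, t = cache@timeGrid[c(3, 7)] * 1.01)
    expect_equal(mb2$t, cache@timeGrid[c(3, 7)])
})

test_that("minibatch marginals follow the transition density", {
    cache <- toyCache()
    set.seed(20)
    cats <- matrix(2L, 400, 1)  # category 2 -> stick starts at 0
    ti <- 25L
    mb <- drawMinibatch(cache, cats, tIndex = rep(ti, 400))
    t <- cache@timeGrid[ti]
    proc <- stickProcess(cache@spec, 1)
    ks <- ksAgainstDensity(as.numeric(mb$v),
        function(x) transitionLogDensity(proc, 0, x, t))
    expect_gt(ks$p.value, 0.01)
})

test_that("cache round-trips through disk", {
    cache <- fixture("k3cache", function()
        buildCache(flatStickBreaking(3), defaultTimeGrid(n = 20L),
            nPerCell = 800L, seed = 2))
    path <- tempfile(fileext = ".rds")
    saveCache(cache, path)
    expect_identical(readCache(path), cache)
    unlink(path)
})
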