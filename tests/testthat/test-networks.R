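test_that("networks are pure functions with input-shaped output", {
    set.seed(1)
    for (m in list(scoreMLP(3, hidden = 8, seed = 2),
        scoreSequenceNet(6, k = 4, channels = 8,
            dilations = c(1L, 2L), seed = 3))) {
        km1 <- m@meta$k - 1L
        L <- if (is.null(m@meta$L)) 5L else m@meta$L
        v <- matrix(runif(3 * L * km1, 0.1, 0.9), 3)
        out1 <- scoreEval(m, v, c(0.5, 1, 2))
        out2 <- scoreEval(m, v, c(0.5, 1, 2))
        expect_identical(out1, out2)
        expect_equal(dim(out1), dim(v))
        expect_true(all(is.finite(out1)))
    }
    # sequence net accepts any length
    cn <- scoreSequenceNet(6, k = 4, channels = 8, dilations = 1L,
        seed = 3)
    v <- matrix(runif(2 * 11 * 3, 0.1, 0.9), 2)
    expect_equal(dim(scoreEval(cn, v, 1)), dim(v))
})

test_that("conditioning track changes the conditional net's output", {
    set.seed(2)
    cn <- scoreSequenceNet(8, k = 4, conditional = TRUE, channels = 8,
        dilations = 1L, seed = 4)
    v <- matrix(runif(2 * 8 * 3, 0.1, 0.9), 2)
    c1 <- matrix(0, 2, 8)
    c2 <- matrix(5, 2, 8)
    expect_false(isTRUE(all.equal(scoreEval(cn, v, 1, c1),
        scoreEval(cn, v, 1, c2))))
    expect_error(scoreEval(cn, v, 1), "condition")
})

test_that("Sudoku relative encoding marks shared rows, columns, blocks", {
    for (n in c(2L, 3L)) {
        k <- n * n
        enc <- sudokuRelativeEncoding(n)
        expect_equal(dim(enc), c(k^2, k^2, 3 * k))
        # symmetry in the two cell axes
        expect_equal(enc, aperm(enc, c(2, 1, 3)))
        # each cell relates to itself in exactly one row/column/block
        for (cell in c(1L, k^2 %/% 2L, k^2)) {
            self <- enc[cell, cell, ]
            expect_equal(sum(self[1:k]), 1)
            expect_equal(sum(self[(k + 1):(2 * k)]), 1)
            expect_equal(sum(self[(2 * k + 1):(3 * k)]), 1)
        }
        # row-mates share exactly the row bit (cells 1 and 2)
        expect_equal(sum(enc[1, 2, 1:k]), 1)
    }
    enc3 <- sudokuRelativeEncoding(3L)
    expect_equal(dim(enc3), c(81, 81, 27))
})

test_that("zeroing the relative-encoding projection leaves a plain
           permutation-equivariant transformer", {
    set.seed(5)
    m <- scoreSudokuNet(2L, nBlocks = 2L, dModel = 16L, seed = 6)
    km1 <- 3L
    v <- matrix(runif(16 * km1, 0.1, 0.9), 1)
    perm <- sample(16L)
    permCols <- as.integer(t(outer((perm - 1L) * km1, 1:km1, "+")))
    vp <- v[, permCols, drop = FALSE]
    # with the attention bias active, cell identity matters
    outB <- scoreEval(m, vp, 1)
    expect_false(isTRUE(all.equal(outB, scoreEval(m, v, 1)[, permCols,
        drop = FALSE], tolerance = 1e-8)))
    # ablated bias: the network commutes with any cell permutation
    for (nm in grep("^Wrel", names(m@params), value = TRUE))
        m@params[[nm]][] <- 0
    out1 <- scoreEval(m, v, 1)
    out2 <- scoreEval(m, vp, 1)
    expect_equal(out2, out1[, permCols, drop = FALSE],
        tolerance = 1e-10)
})

test_that("mini Sudoku net trains for a few steps on CPU", {
    set.seed(7)
    spec <- flatStickBreaking(4)
    cache <- miniSudokuCache()
    gmat <- t(sapply(enumerateMiniGrids()[1:50], gridToCategories))
    sampler <- function(n)
        gmat[sample.int(nrow(gmat), n, replace = TRUE), , drop = FALSE]
    m <- scoreSudokuNet(2L, nBlocks = 2L, dModel = 16L, seed = 8)
    m2 <- trainScoreModel(m, sampler, cache, spec,
        trainingConfig(batchSize = 8L, steps = 10L, seed = 1,
            logEvery = 5L))
    expect_equal(nrow(m2@meta$lossCurve), 2)
    expect_true(all(is.finite(m2@meta$lossCurve$loss)))
})
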