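# Reference score-model architectures: per-position MLP, dilated 1-D
# convolutional stack for sequences, relational transformer for Sudoku.
# All evaluate in v-space: input stick coordinates (batch x L*(k-1)),
# output scores of the same shape.

# sinusoidal features of log-time; t in (0, T], dim must be even
.timeFeatures <- function(t, dim = 8L) {
    z <- log(t)
    freq <- 2^(seq_len(dim %/% 2L) - 2L)
    cbind(outer(z, freq, function(a, f) sin(a * f)),
        outer(z, freq, function(a, f) cos(a * f)))
}

.glorot <- function(nin, nout, gain = 1) {
    matrix(stats::rnorm(nin * nout, sd = gain * sqrt(2 / (nin + nout))),
        nin, nout)
}

# wrap plain parameter matrices as tape leaves (or pass through when
# tape is NULL)
.leafify <- function(tp, params) {
    if (is.null(tp)) return(params)
    lapply(params, function(p) adLeaf(tp, p))
}

# reshape batch x (L*(k-1)) stick coordinates into (B*L) x (k-1) rows
# (position-major within each batch row) plus per-row time features
.unstackPositions <- function(v, t, km1, tdim) {
    B <- nrow(v)
    L <- ncol(v) %/% km1
    vm <- matrix(aperm(array(v, c(B, km1, L)), c(3L, 1L, 2L)),
        B * L, km1)
    tf <- .timeFeatures(rep(t, each = L, length.out = B * L), tdim)
    list(vm = vm, tf = tf, B = B, L = L, t = t)
}

.restackPositions <- function(m, B, L, km1) {
    matrix(aperm(array(m, c(L, B, km1)), c(2L, 3L, 1L)), B, L * km1)
}

# simplex coordinates for each position row: (B*L) x k
.rowsToSimplex <- function(vm) stickToSimplex(vm)

# stationary Beta stick scores for position rows: (B*L) x (k-1)
.statScoreRows <- function(spec, vm) {
    a <- matrix(spec@a, nrow(vm), ncol(vm), byrow = TRUE)
    b <- matrix(spec@b, nrow(vm), ncol(vm), byrow = TRUE)
    (a - 1) / vm - (b - 1) / (1 - vm)
}

# output preconditioning: the learned score is parameterized as
# stationary score + net(v, t) / t, because the denoising target's
# deviation from stationarity grows like 1/t as t -> 0 and vanishes at
# the horizon; the network then works at O(1) output scale at all times
.preconditionOut <- function(tape, rawOut, spec, u) {
    stat <- .statScoreRows(spec, u$vm)
    cmat <- matrix(rep(1 / rep(u$t, each = u$L, length.out = u$B * u$L),
        ncol(u$vm)), u$B * u$L, ncol(u$vm))
    adAdd(tape, adMul(tape, rawOut, cmat), stat)
}

#' Per-position multilayer perceptron score model
#'
#' A small fully connected network applied independently at every
#' sequence position: input the position's stick coordinates plus a
#' sinusoidal embedding of log t, two tanh hidden layers, linear output
#' of k - 1 v-space scores. Suitable for i.i.d. categorical toys where
#' positions are exchangeable and independent.
#'
#' The output is preconditioned as stationary score + net / t, so the
#' network body operates at order-one scale at every diffusion time.
#'
#' @param k number of categories.
#' @param hidden hidden layer width.
#' @param tdim time-embedding dimension (even).
#' @param seed integer seed for weight initialization.
#' @param spec the \code{\link{StickBreakingProcess}} whose stationary
#'   score anchors the output (default the flat preset for k).
#' @return a \code{\link{ScoreModel-class}}.
#' @examples
#' m <- scoreMLP(2)
#' scoreEval(m, matrix(0.5, 2, 1), t = c(1, 2))
#' @export
scoreMLP <- function(k, hidden = 64L, tdim = 8L, seed = 1L,
                     spec = flatStickBreaking(k)) {
    km1 <- k - 1L
    set.seed(seed)
    params <- list(
        W1 = .glorot(km1 + tdim, hidden), b1 = matrix(0, 1, hidden),
        W2 = .glorot(hidden, hidden), b2 = matrix(0, 1, hidden),
        W3 = .glorot(hidden, km1, gain = 0.1), b3 = matrix(0, 1, km1))
    forward <- function(params, v, t, condition = NULL, tape = NULL) {
        p <- .leafify(tape, params)
        u <- .unstackPositions(v, t, km1, tdim)
        h <- cbind(u$vm, u$tf)
        h <- adTanh(tape, adAddBias(tape, adMatmul(tape, h, p$W1), p$b1))
        h <- adTanh(tape, adAddBias(tape, adMatmul(tape, h, p$W2), p$b2))
        out <- adAddBias(tape, adMatmul(tape, h, p$W3), p$b3)
        out <- .preconditionOut(tape, out, spec, u)
        if (is.null(tape))
            return(.restackPositions(out, u$B, u$L, km1))
        list(out = out, params = p, B = u$B, L = u$L, km1 = km1)
    }
    new("ScoreModel", params = params, forward = forward, space = "v",
        meta = list(kind = "mlp", k = k, tdim = tdim, conditional = FALSE))
}

#' Dilated convolutional sequence score model
#'
#' A residual stack of dilated 1-D convolutions over sequence positions.
#' Each position is embedded from its simplex coordinates, the time
#' embedding and (optionally) a per-position conditioning signal; residual
#' blocks apply kernel-3 convolutions with increasing dilation so the
#' receptive field grows exponentially. Output is k - 1 v-space scores
#' per position. This is the documented stand-in architecture for
#' conditional sequence design.
#'
#' @param L sequence length.
#' @param k number of categories (4 for DNA).
#' @param conditional if TRUE the model consumes a per-position numeric
#'   conditioning track (batch x L).
#' @param channels hidden channel count.
#' @param dilations integer vector of per-block dilations.
#' @param tdim time-embedding dimension.
#' @param seed integer seed for initialization.
#' @return a \code{\link{ScoreModel-class}}.
#' @export
scoreSequenceNet <- function(L, k = 4L, conditional = FALSE,
                             channels = 32L, dilations = c(1L, 2L, 4L, 8L),
                             tdim = 8L, seed = 1L,
                             spec = flatStickBreaking(k)) {
    km1 <- k - 1L
    set.seed(seed)
    nin <- k + tdim + as.integer(conditional)
    params <- list(Win = .glorot(nin, channels),
        bin = matrix(0, 1, channels))
    for (i in seq_along(dilations)) {
        params[[sprintf("Wl%d", i)]] <- .glorot(channels, channels)
        params[[sprintf("Wc%d", i)]] <- .glorot(channels, channels)
        params[[sprintf("Wr%d", i)]] <- .glorot(channels, channels)
        params[[sprintf("bc%d", i)]] <- matrix(0, 1, channels)
    }
    params$Wout <- .glorot(channels, km1, gain = 0.1)
    params$bout <- matrix(0, 1, km1)
    forward <- function(params, v, t, condition = NULL, tape = NULL) {
        p <- .leafify(tape, params)
        u <- .unstackPositions(v, t, km1, tdim)
        feats <- cbind(.rowsToSimplex(u$vm), u$tf)
        if (conditional) {
            if (is.null(condition))
                stop("conditional model requires a condition track")
            condition <- rbind(condition)
            feats <- cbind(feats, as.numeric(t(condition)))
        }
        h <- adAddBias(tape, adMatmul(tape, feats, p$Win), p$bin)
        for (i in seq_along(dilations)) {
            d <- dilations[i]
            lft <- adShiftRows(tape, h, -d, u$L)
            rgt <- adShiftRows(tape, h, d, u$L)
            z <- adAdd(tape,
                adAdd(tape, adMatmul(tape, lft, p[[sprintf("Wl%d", i)]]),
                    adMatmul(tape, h, p[[sprintf("Wc%d", i)]])),
                adMatmul(tape, rgt, p[[sprintf("Wr%d", i)]]))
            z <- adTanh(tape, adAddBias(tape, z, p[[sprintf("bc%d", i)]]))
            h <- adAdd(tape, h, z)
        }
        out <- adAddBias(tape, adMatmul(tape, h, p$Wout), p$bout)
        out <- .preconditionOut(tape, out, spec, u)
        if (is.null(tape))
            return(.restackPositions(out, u$B, u$L, km1))
        list(out = out, params = p, B = u$B, L = u$L, km1 = km1)
    }
    new("ScoreModel", params = params, forward = forward, space = "v",
        meta = list(kind = "seqconv", k = k, L = L, tdim = tdim,
            conditional = conditional))
}

#' Binary relative positional encoding for Sudoku grids
#'
#' For an n^2 x n^2 grid (N = n^4 cells) returns an N x N x 3n^2 binary
#' array: entry (i, j, d) indicates that cells i and j share row d (first
#' n^2 slices), column d (next n^2) or n x n block d (last n^2). The
#' encoding is symmetric in the two cell axes, and every cell relates to
#' itself in exactly one row, one column and one block.
#'
#' @param n block size (2 for the 4x4 mini grid, 3 for standard Sudoku;
#'   n = 3 gives the 81 x 81 x 27 encoding).
#' @return binary array N x N x 3n^2.
#' @export
sudokuRelativeEncoding <- function(n = 3L) {
    k <- n * n
    N <- k * k
    row <- rep(seq_len(k), each = k)
    col <- rep(seq_len(k), times = k)
    blk <- (ceiling(row / n) - 1L) * n + ceiling(col / n)
    enc <- array(0, c(N, N, 3L * k))
    for (d in seq_len(k)) {
        enc[, , d] <- outer(row == d, row == d)
        enc[, , k + d] <- outer(col == d, col == d)
        enc[, , 2L * k + d] <- outer(blk == d, blk == d)
    }
    enc
}

#' Relational transformer score model for Sudoku
#'
#' Cells are tokens; each block applies pre-norm multi-head
#' self-attention followed by a tanh feed-forward layer, with residual
#' connections. The binary relative positional encoding
#' (\code{\link{sudokuRelativeEncoding}}) is projected by a learned
#' linear layer (one projection per head) and added to the attention
#' logits prior to the softmax, so each head can specialize to
#' row-, column- or block-mates while the network uses no
#' digit-identity prior. The full-size architecture uses 20 blocks over
#' 81 cells with the 27-dimensional encoding; the n = 2 mini variant
#' (16 cells, k = 4, 12-dimensional encoding) trains on CPU. Head count
#' and width are not pinned down by the published description; the
#' defaults here are documented, not claimed as faithful.
#'
#' @param n block size (2 mini, 3 full).
#' @param nBlocks number of transformer blocks (default 20 full-size).
#' @param dModel model width.
#' @param nHeads attention heads (dModel must be divisible by nHeads).
#' @param tdim time-embedding dimension.
#' @param seed integer seed for initialization.
#' @return a \code{\link{ScoreModel-class}}.
#' @export
scoreSudokuNet <- function(n = 3L, nBlocks = 20L, dModel = 64L,
                           nHeads = 4L, tdim = 8L, seed = 1L,
                           spec = flatStickBreaking(as.integer(n * n))) {
    k <- as.integer(n * n)
    N <- k * k
    km1 <- k - 1L
    nRel <- 3L * k
    if (dModel %% nHeads != 0L) stop("'dModel' must be divisible by 'nHeads'")
    dHead <- dModel %/% nHeads
    set.seed(seed)
    relEnc <- sudokuRelativeEncoding(n)
    relMats <- lapply(seq_len(nRel), function(d) relEnc[, , d])
    params <- list(Wemb = .glorot(k + tdim, dModel),
        bemb = matrix(0, 1, dModel))
    # one projection of the relative encoding per head; heads start
    # biased toward one relation family (rows / columns / blocks) so
    # that specialization does not depend on symmetry breaking by the
    # random init
    for (hd in seq_len(nHeads)) {
        w0 <- stats::rnorm(nRel, sd = 0.05)
        if (hd <= 3L)
            w0[((hd - 1L) * k + 1L):(hd * k)] <-
                w0[((hd - 1L) * k + 1L):(hd * k)] + 1
        params[[sprintf("Wrel%d", hd)]] <- matrix(w0, 1, nRel)
    }
    for (i in seq_len(nBlocks)) {
        params[[sprintf("g1_%d", i)]] <- matrix(1, 1, dModel)
        for (hd in seq_len(nHeads)) {
            params[[sprintf("Wq%d_%d", i, hd)]] <- .glorot(dModel, dHead)
            params[[sprintf("Wk%d_%d", i, hd)]] <- .glorot(dModel, dHead)
            params[[sprintf("Wv%d_%d", i, hd)]] <- .glorot(dModel, dHead)
            params[[sprintf("Wo%d_%d", i, hd)]] <- .glorot(dHead, dModel,
                gain = 0.5)
        }
        params[[sprintf("g2_%d", i)]] <- matrix(1, 1, dModel)
        params[[sprintf("Wf1_%d", i)]] <- .glorot(dModel, 2L * dModel)
        params[[sprintf("bf1_%d", i)]] <- matrix(0, 1, 2L * dModel)
        params[[sprintf("Wf2_%d", i)]] <- .glorot(2L * dModel, dModel,
            gain = 0.5)
        params[[sprintf("bf2_%d", i)]] <- matrix(0, 1, dModel)
    }
    params$gout <- matrix(1, 1, dModel)
    params$Wout <- .glorot(dModel, km1, gain = 0.1)
    params$bout <- matrix(0, 1, km1)
    forward <- function(params, v, t, condition = NULL, tape = NULL) {
        p <- .leafify(tape, params)
        u <- .unstackPositions(v, t, km1, tdim)
        if (u$L != N) stop(sprintf("expected %d cells, got %d", N, u$L))
        B <- u$B
        feats <- cbind(.rowsToSimplex(u$vm), u$tf)
        h <- adAddBias(tape, adMatmul(tape, feats, p$Wemb), p$bemb)
        relBias <- lapply(seq_len(nHeads), function(hd)
            adAxpy(tape, relMats, p[[sprintf("Wrel%d", hd)]]))
        scl <- 1 / sqrt(dHead)
        for (i in seq_len(nBlocks)) {
            h1 <- adRMSNorm(tape, h, p[[sprintf("g1_%d", i)]])
            o <- NULL
            for (hd in seq_len(nHeads)) {
                q <- adMatmul(tape, h1, p[[sprintf("Wq%d_%d", i, hd)]])
                kk <- adMatmul(tape, h1, p[[sprintf("Wk%d_%d", i, hd)]])
                vv <- adMatmul(tape, h1, p[[sprintf("Wv%d_%d", i, hd)]])
                att <- adBlockAttention(tape, q, kk, vv,
                    relBias[[hd]], B, scl)
                oh <- adMatmul(tape, att, p[[sprintf("Wo%d_%d", i, hd)]])
                o <- if (is.null(o)) oh else adAdd(tape, o, oh)
            }
            h <- adAdd(tape, h, o)
            h2 <- adRMSNorm(tape, h, p[[sprintf("g2_%d", i)]])
            z <- adTanh(tape, adAddBias(tape,
                adMatmul(tape, h2, p[[sprintf("Wf1_%d", i)]]),
                p[[sprintf("bf1_%d", i)]]))
            z <- adAddBias(tape, adMatmul(tape, z,
                p[[sprintf("Wf2_%d", i)]]), p[[sprintf("bf2_%d", i)]])
            h <- adAdd(tape, h, z)
        }
        h <- adRMSNorm(tape, h, p$gout)
        out <- adAddBias(tape, adMatmul(tape, h, p$Wout), p$bout)
        out <- .preconditionOut(tape, out, spec, u)
        if (is.null(tape))
            return(.restackPositions(out, B, u$L, km1))
        list(out = out, params = p, B = B, L = u$L, km1 = km1)
    }
    new("ScoreModel", params = params, forward = forward, space = "v",
        meta = list(kind = "sudoku", k = k, n = n, L = N,
            nBlocks = nBlocks, tdim = tdim, conditional = FALSE))
}

# transpose node (needed for attention Q K^T)
.adTransposed <- function(tp, a) {
    va <- .val(a)
    out <- t(va)
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) .acc(a, t(g)))
}

#' Analytic stationary score model
#'
#' A \code{ScoreModel} returning the exact stationary Beta score of each
#' stick dimension, independent of time. Useful as a reference: the
#' reverse SDE and probability-flow ODE driven by it leave the
#' stationary Dirichlet law invariant.
#'
#' @param spec a \code{\link{StickBreakingProcess}}.
#' @return a \code{\link{ScoreModel-class}}.
#' @export
stationaryScoreModel <- function(spec) {
    km1 <- spec@k - 1L
    forward <- function(params, v, t, condition = NULL, tape = NULL) {
        sc <- .specColumns(spec, ncol(v))
        a <- matrix(sc$a, nrow(v), ncol(v), byrow = TRUE)
        b <- matrix(sc$b, nrow(v), ncol(v), byrow = TRUE)
        out <- (a - 1) / v - (b - 1) / (1 - v)
        if (is.null(tape)) return(out)
        stop("the analytic stationary model is not trainable")
    }
    new("ScoreModel", params = list(), forward = forward, space = "v",
        meta = list(kind = "stationary", k = spec@k))
}
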