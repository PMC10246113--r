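#' Minimal reverse-mode autodiff engine
#'
#' Low-level tape-based automatic differentiation on numeric matrices,
#' used to train the score networks. \code{adTape} opens a tape,
#' \code{adLeaf} registers a parameter leaf, the \code{ad*} operations
#' record forward values plus backward closures, and
#' \code{adBackward} accumulates gradients into the leaves. Every
#' operation short-circuits to plain numeric evaluation when the tape
#' is \code{NULL}, and treats plain matrices as constants.
#' \code{adamInit}/\code{adamStep} implement the Adam optimizer over a
#' named list of parameter matrices.
#'
#' @param tp a tape from \code{adTape()} or \code{NULL}.
#' @param a,b,x,bias,gain nodes or constant matrices.
#' @param value numeric matrix for a leaf.
#' @param loss the scalar output node to differentiate.
#' @param c scalar constant multiplier.
#' @param eps numerical floor.
#' @param shift,block row shift and block length for
#'   \code{adShiftRows}.
#' @param mats list of constant matrices for \code{adAxpy}.
#' @param w weight node (1 x length(mats)).
#' @param B number of diagonal blocks for \code{adRepBlockDiag}.
#' @param params,grads,state,lr,beta1,beta2 Adam state and
#'   hyperparameters.
#' @return nodes (environments with \code{$value}/\code{$grad}) or, for
#'   tapeless calls, plain matrices; \code{adamStep} returns an updated
#'   \code{list(state, params)}.
#' @name autodiff-ops
NULL

# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape is an environment accumulating operation nodes in creation
# order; backward() walks the tape in reverse. Nodes are environments
# holding value/grad; plain numeric matrices passed to ops are treated as
# constants. Every op short-circuits to plain numeric evaluation when the
# tape is NULL, so network forward code has a single code path for
# training and inference.

#' @rdname autodiff-ops
#' @export
adTape <- function() {
    tp <- new.env(parent = emptyenv())
    tp$nodes <- vector("list", 256L)
    tp$n <- 0L
    tp
}

.adNode <- function(tp, value, back = NULL) {
    nd <- new.env(parent = emptyenv())
    nd$value <- value
    nd$grad <- NULL
    nd$back <- back
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes))
        tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$n]] <- nd
    nd
}

# leaf (parameter) node
#' @rdname autodiff-ops
#' @export
adLeaf <- function(tp, value) .adNode(tp, value)

.val <- function(x) if (is.environment(x)) x$value else x

.acc <- function(x, g) {
    if (is.environment(x))
        x$grad <- if (is.null(x$grad)) g else x$grad + g
    invisible(NULL)
}

#' @rdname autodiff-ops
#' @export
adBackward <- function(tp, loss) {
    loss$grad <- 1
    for (i in seq.int(tp$n, 1L)) {
        nd <- tp$nodes[[i]]
        if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd$grad)
    }
    invisible(NULL)
}

#' @rdname autodiff-ops
#' @export
adMatmul <- function(tp, a, b) {
    va <- .val(a); vb <- .val(b)
    out <- va %*% vb
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        .acc(a, g %*% t(vb))
        .acc(b, crossprod(va, g))
    })
}

#' @rdname autodiff-ops
#' @export
adAdd <- function(tp, a, b) {
    va <- .val(a); vb <- .val(b)
    out <- va + vb
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        .acc(a, g)
        .acc(b, g)
    })
}

#' @rdname autodiff-ops
#' @export
adSub <- function(tp, a, b) {
    va <- .val(a); vb <- .val(b)
    out <- va - vb
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        .acc(a, g)
        .acc(b, -g)
    })
}

#' @rdname autodiff-ops
#' @export
adMul <- function(tp, a, b) {
    va <- .val(a); vb <- .val(b)
    out <- va * vb
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        .acc(a, g * vb)
        .acc(b, g * va)
    })
}

#' @rdname autodiff-ops
#' @export
adScale <- function(tp, a, c) {
    va <- .val(a)
    out <- va * c
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) .acc(a, g * c))
}

# add a 1 x d bias row to every row of a
#' @rdname autodiff-ops
#' @export
adAddBias <- function(tp, a, bias) {
    va <- .val(a); vb <- .val(bias)
    out <- sweep(va, 2L, as.numeric(vb), "+")
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        .acc(a, g)
        .acc(bias, matrix(colSums(g), nrow = 1L))
    })
}

#' @rdname autodiff-ops
#' @export
adTanh <- function(tp, a) {
    out <- tanh(.val(a))
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) .acc(a, g * (1 - out^2)))
}

#' @rdname autodiff-ops
#' @export
adSumAll <- function(tp, a) {
    va <- .val(a)
    out <- sum(va)
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g)
        .acc(a, matrix(g, nrow(va), ncol(va))))
}

#' @rdname autodiff-ops
#' @export
adSoftmaxRows <- function(tp, a) {
    va <- .val(a)
    m <- va - va[cbind(seq_len(nrow(va)), max.col(va, "first"))]
    e <- exp(m)
    out <- e / rowSums(e)
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        .acc(a, out * (g - rowSums(g * out)))
    })
}

# row-wise RMS normalization with learnable per-column gain (1 x d)
#' @rdname autodiff-ops
#' @export
adRMSNorm <- function(tp, a, gain, eps = 1e-6) {
    va <- .val(a); vg <- as.numeric(.val(gain))
    d <- ncol(va)
    r <- sqrt(rowMeans(va^2) + eps)
    u <- va / r
    out <- sweep(u, 2L, vg, "*")
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        gg <- sweep(g, 2L, vg, "*")
        .acc(a, gg / r - va * (rowSums(gg * va) / (d * r^3)))
        .acc(gain, matrix(colSums(g * u), nrow = 1L))
    })
}

# shift rows by 'shift' within consecutive blocks of 'block' rows,
# zero-filling at block edges (1-D convolution building block)
#' @rdname autodiff-ops
#' @export
adShiftRows <- function(tp, a, shift, block) {
    va <- .val(a)
    n <- nrow(va)
    stopifnot(n %% block == 0L)
    pos <- ((seq_len(n) - 1L) %% block)
    src <- seq_len(n) - shift
    valid <- pos - shift >= 0L & pos - shift < block
    out <- matrix(0, n, ncol(va))
    out[valid, ] <- va[src[valid], ]
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        gb <- matrix(0, n, ncol(va))
        gb[src[valid], ] <- g[valid, ]
        .acc(a, gb)
    })
}

# weighted sum of fixed matrices: value = sum_i w_i * M_i with w a
# parameter node holding a 1 x m matrix
#' @rdname autodiff-ops
#' @export
adAxpy <- function(tp, mats, w) {
    vw <- as.numeric(.val(w))
    out <- 0
    for (i in seq_along(mats)) out <- out + vw[i] * mats[[i]]
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        gw <- vapply(mats, function(m) sum(m * g), numeric(1))
        .acc(w, matrix(gw, nrow = 1L))
    })
}

# replicate a small T x T matrix along the diagonal of a (B*T) x (B*T)
# matrix (off-diagonal blocks zero)
#' @rdname autodiff-ops
#' @export
adRepBlockDiag <- function(tp, a, B) {
    va <- .val(a)
    Tn <- nrow(va)
    out <- matrix(0, B * Tn, B * Tn)
    for (bi in seq_len(B)) {
        ix <- ((bi - 1L) * Tn + 1L):(bi * Tn)
        out[ix, ix] <- va
    }
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        gs <- matrix(0, Tn, Tn)
        for (bi in seq_len(B)) {
            ix <- ((bi - 1L) * Tn + 1L):(bi * Tn)
            gs <- gs + g[ix, ix]
        }
        .acc(a, gs)
    })
}

# fused batched self-attention over B independent blocks of T rows:
# for each block, out = softmax(Q K' * scl + rel) V, with a shared
# T x T additive bias 'rel'. Avoids materializing the (B*T) x (B*T)
# block-diagonal score matrix.
#' @rdname autodiff-ops
#' @export
adBlockAttention <- function(tp, q, k, v, rel, B, scl) {
    vq <- .val(q); vk <- .val(k); vv <- .val(v); vr <- .val(rel)
    Tn <- nrow(vq) %/% B
    out <- matrix(0, nrow(vq), ncol(vq))
    atts <- vector("list", B)
    for (bi in seq_len(B)) {
        ix <- ((bi - 1L) * Tn + 1L):(bi * Tn)
        s <- tcrossprod(vq[ix, , drop = FALSE],
            vk[ix, , drop = FALSE]) * scl + vr
        s <- s - s[cbind(seq_len(Tn), max.col(s, "first"))]
        e <- exp(s)
        a <- e / rowSums(e)
        atts[[bi]] <- a
        out[ix, ] <- a %*% vv[ix, , drop = FALSE]
    }
    if (is.null(tp)) return(out)
    .adNode(tp, out, function(g) {
        gq <- matrix(0, nrow(vq), ncol(vq))
        gk <- gq; gv <- gq
        gr <- matrix(0, Tn, Tn)
        for (bi in seq_len(B)) {
            ix <- ((bi - 1L) * Tn + 1L):(bi * Tn)
            a <- atts[[bi]]
            gO <- g[ix, , drop = FALSE]
            gv[ix, ] <- crossprod(a, gO)
            gA <- tcrossprod(gO, vv[ix, , drop = FALSE])
            gS <- a * (gA - rowSums(gA * a))
            gq[ix, ] <- gS %*% vk[ix, , drop = FALSE] * scl
            gk[ix, ] <- crossprod(gS, vq[ix, , drop = FALSE]) * scl
            gr <- gr + gS
        }
        .acc(q, gq); .acc(k, gk); .acc(v, gv); .acc(rel, gr)
    })
}

# ---- Adam optimizer on a named list of parameter matrices ----

#' @rdname autodiff-ops
#' @export
adamInit <- function(params) {
    list(m = lapply(params, function(p) p * 0),
        v = lapply(params, function(p) p * 0), t = 0L)
}

#' @rdname autodiff-ops
#' @export
adamStep <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    bc1 <- 1 - beta1^state$t
    bc2 <- 1 - beta2^state$t
    for (nm in names(params)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] -
            lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    }
    list(state = state, params = params)
}
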