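# Denoising score matching with the diffusion-weighted (G G^T) loss.

#' Diffusion-weighted denoising score-matching loss
#'
#' The squared score error weighted by the forward diffusion coefficient,
#' \eqn{\|s_\theta - s^*\|^2_{GG^T}}. In stick (v) space G is diagonal
#' with \eqn{G_{jj} = \sqrt{s_j v_j (1 - v_j)}}, so the weight is simply
#' \eqn{s_j v_j(1 - v_j)} per dimension; this weighting makes the loss
#' invariant under any differentiable bijection of the state, and with a
#' v-independent diagonal G it reduces to the classical \eqn{\lambda(t) =
#' g(t)^2} likelihood weighting. \code{space = "x"} evaluates the same
#' loss after change-of-variable to simplex coordinates (scores converted
#' with \code{\link{scoreVToX}}, weight matrix \eqn{J G G^T J^T}); the
#' two agree to numerical precision.
#'
#' @param spec a \code{\link{StickBreakingProcess}}.
#' @param v matrix (batch x L*(k-1)) of stick coordinates (interior).
#' @param modelScore,targetScore v-space score matrices of the same
#'   shape as \code{v}.
#' @param space \code{"v"} (default) or \code{"x"}.
#' @return nonnegative scalar, the batch-mean weighted loss.
#' @export
weightedDSMLoss <- function(spec, v, modelScore, targetScore,
                            space = c("v", "x")) {
    space <- match.arg(space)
    if (!all(dim(v) == dim(modelScore)) ||
        !all(dim(v) == dim(targetScore)))
        stop("score matrices must match the shape of 'v'")
    km1 <- spec@k - 1L
    L <- ncol(v) %/% km1
    if (space == "v") {
        w <- .stickWeights(spec, v)
        return(mean(rowSums(w * (modelScore - targetScore)^2)))
    }
    # x-space route: convert scores position-wise, weight with J G^2 J^T
    tot <- 0
    for (b in seq_len(nrow(v))) {
        for (l in seq_len(L)) {
            ix <- ((l - 1L) * km1 + 1L):(l * km1)
            vv <- v[b, ix]
            dV <- modelScore[b, ix] - targetScore[b, ix]
            J <- .stickJacobian(vv)
            # score differences transform linearly: dX = J^{-T} dV
            dX <- solve(t(J), dV)
            G2 <- spec@s * vv * (1 - vv)
            M <- J %*% (G2 * t(J))
            tot <- tot + drop(t(dX) %*% M %*% dX)
        }
    }
    tot / nrow(v)
}

# per-entry loss weights s_j v (1 - v), laid out like v
.stickWeights <- function(spec, v) {
    km1 <- spec@k - 1L
    L <- ncol(v) %/% km1
    sw <- matrix(rep(rep(spec@s, L), each = nrow(v)), nrow(v),
        km1 * L)
    sw * v * (1 - v)
}

#' Training configuration
#'
#' @param batchSize minibatch size per forward/backward pass.
#' @param lr Adam learning rate.
#' @param steps number of optimizer steps.
#' @param seed integer seed controlling batch order, time draws and
#'   cache lookups.
#' @param logEvery record the smoothed loss every this many steps.
#' @param accumulate number of minibatches whose gradients are averaged
#'   per optimizer step (effective batch = batchSize * accumulate;
#'   attention-style models cost quadratically in batchSize, so
#'   accumulation buys batch at linear cost).
#' @param lrDecay multiplicative learning-rate factor applied over the
#'   final 25\% of steps (1 = constant).
#' @return a list of class \code{ddsmTrainingConfig}.
#' @export
trainingConfig <- function(batchSize = 32L, lr = 1e-3, steps = 1000L,
                           seed = 1L, logEvery = 25L, accumulate = 1L,
                           lrDecay = 1) {
    stopifnot(batchSize >= 1, lr > 0, steps >= 1, accumulate >= 1,
        lrDecay > 0, lrDecay <= 1)
    structure(list(batchSize = as.integer(batchSize), lr = lr,
        steps = as.integer(steps), seed = as.integer(seed),
        logEvery = as.integer(logEvery),
        accumulate = as.integer(accumulate), lrDecay = lrDecay),
        class = "ddsmTrainingConfig")
}

#' Train a score model by denoising score matching
#'
#' Runs Adam on the diffusion-weighted DSM loss over minibatches
#' assembled from the pre-sampled forward-diffusion cache. Diffusion
#' times are drawn uniformly over the cache's time grid (matching the
#' pre-sampled dictionary strategy). Fully deterministic given the
#' config seed.
#'
#' @param model a \code{\link{ScoreModel-class}}.
#' @param dataSampler function(n) returning an integer matrix
#'   (n x positions) of category indices; may also return a list with
#'   elements \code{categories} and \code{condition} for conditional
#'   models.
#' @param cache a \code{\link{DiffusedSampleCache-class}} built for the
#'   same \code{spec}.
#' @param spec the \code{\link{StickBreakingProcess}}.
#' @param config a \code{\link{trainingConfig}}.
#' @return the trained model, with the recorded loss curve in
#'   \code{model@meta$lossCurve} (data.frame step/loss).
#' @export
trainScoreModel <- function(model, dataSampler, cache, spec,
                            config = trainingConfig()) {
    set.seed(config$seed)
    params <- model@params
    opt <- adamInit(params)
    nT <- length(cache@timeGrid)
    losses <- numeric(config$steps)
    curve <- list()
    for (step in seq_len(config$steps)) {
        grads <- NULL
        loss <- 0
        for (micro in seq_len(config$accumulate)) {
            batch <- dataSampler(config$batchSize)
            condition <- NULL
            if (is.list(batch) && !is.matrix(batch)) {
                condition <- batch$condition
                batch <- batch$categories
            }
            if (is.null(dim(batch))) batch <- matrix(batch, ncol = 1L)
            tIdx <- sample.int(nT, nrow(batch), replace = TRUE)
            mb <- drawMinibatch(cache, batch, tIdx)
            B <- dim(mb$v)[1L]
            L <- dim(mb$v)[2L]
            km1 <- dim(mb$v)[3L]
            # flatten to batch x (L * km1), position-major
            vmat <- matrix(aperm(mb$v, c(1L, 3L, 2L)), B, L * km1)
            smat <- matrix(aperm(mb$score, c(1L, 3L, 2L)), B, L * km1)
            w <- .stickWeights(spec, vmat)
            tp <- adTape()
            fw <- model@forward(params, vmat, mb$t, condition, tp)
            # loss rows are position-major: realign targets to
            # (B*L) x km1
            tRows <- .unstackPositions(smat, mb$t, km1, 2L)$vm
            wRows <- .unstackPositions(w, mb$t, km1, 2L)$vm
            d <- adSub(tp, fw$out, tRows)
            lossNode <- adScale(tp, adSumAll(tp,
                adMul(tp, adMul(tp, d, d), wRows)),
                1 / (B * config$accumulate))
            adBackward(tp, lossNode)
            loss <- loss + .val(lossNode)
            g <- lapply(fw$params, function(nd) nd$grad)
            grads <- if (is.null(grads)) g else
                mapply(function(x, y) if (is.null(y)) x else
                    if (is.null(x)) y else x + y, grads, g,
                    SIMPLIFY = FALSE)
        }
        if (!is.finite(loss))
            stop(sprintf(
                "non-finite loss at step %d (t range %.3g..%.3g)",
                step, min(mb$t), max(mb$t)))
        losses[step] <- loss
        lrNow <- config$lr * if (step > 0.75 * config$steps)
            config$lrDecay else 1
        upd <- adamStep(opt, params, grads, lr = lrNow)
        opt <- upd$state
        params <- upd$params
        if (step %% config$logEvery == 0L || step == config$steps) {
            lo <- max(1L, step - config$logEvery + 1L)
            curve[[length(curve) + 1L]] <-
                c(step = step, loss = mean(losses[lo:step]))
        }
    }
    model@params <- params
    model@meta$lossCurve <- as.data.frame(do.call(rbind, curve))
    model@meta$trainedSteps <- config$steps
    model
}
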