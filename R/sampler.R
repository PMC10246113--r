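# Reverse-time SDE sampling: unconditional, time-dilated, and
# inpainting-conditional; discretization of simplex samples to
# categories.

#' Sampler configuration
#'
#' @param nSteps base number of reverse integration steps.
#' @param timeDilation dilation factor c >= 1. Implemented as a
#'   stretched-clock integration: the reverse drift (including the score
#'   term) is applied c times per unit of model time while the injected
#'   noise keeps its undilated scale, driving samples toward
#'   high-density regions of the learned distribution. c = 1 is exact
#'   unbiased reverse diffusion.
#' @param tStart start time T of the reverse integration.
#' @param tEnd terminal (small) time, matching the likelihood cutoff.
#' @param discretization \code{"argmax"} (deterministic) or
#'   \code{"categorical"} (draw from the simplex point read as
#'   categorical probabilities).
#' @return list of class \code{ddsmSamplerConfig}.
#' @export
samplerConfig <- function(nSteps = 100L, timeDilation = 1,
                          tStart = 4, tEnd = 0.01,
                          discretization = c("argmax", "categorical")) {
    stopifnot(nSteps >= 1, timeDilation >= 1, tStart > tEnd, tEnd > 0)
    structure(list(nSteps = as.integer(nSteps),
        timeDilation = timeDilation, tStart = tStart, tEnd = tEnd,
        discretization = match.arg(discretization)),
        class = "ddsmSamplerConfig")
}

# per-column (a, b, s) vectors for a batch matrix laid out
# position-major: L repeats of the k-1 stick parameters
.specColumns <- function(spec, ncolV) {
    km1 <- spec@k - 1L
    L <- ncolV %/% km1
    list(a = rep(spec@a, L), b = rep(spec@b, L), s = rep(spec@s, L))
}

#' One Euler--Maruyama step of the reverse-time SDE
#'
#' Applies, per stick dimension, the reverse drift
#' \eqn{\frac{s}{2}[a(1-v) - bv] - s(1-2v) - s v(1-v)\,\hat s(v,t)}
#' over a backward time increment \code{dt}, with diffusion
#' \eqn{\sqrt{s v(1-v)}}; the state is clamped to the interior.
#'
#' @param spec a \code{\link{StickBreakingProcess}}.
#' @param v matrix (batch x L*(k-1)) of stick coordinates.
#' @param t current time.
#' @param scoreV v-space score matrix (model output), same shape.
#' @param dt positive backward step size.
#' @param noise optional pre-drawn standard normal matrix (same shape);
#'   pass a zero matrix for the deterministic drift-only variant.
#' @param driftScale drift multiplier used by time dilation (default 1).
#' @return updated v matrix.
#' @export
reverseStep <- function(spec, v, t, scoreV, dt, noise = NULL,
                        driftScale = 1) {
    if (dt <= 0) stop("'dt' must be positive")
    sc <- .specColumns(spec, ncol(v))
    a <- matrix(sc$a, nrow(v), ncol(v), byrow = TRUE)
    b <- matrix(sc$b, nrow(v), ncol(v), byrow = TRUE)
    s <- matrix(sc$s, nrow(v), ncol(v), byrow = TRUE)
    drift <- 0.5 * s * (a * (1 - v) - b * v) - s * (1 - 2 * v) -
        s * v * (1 - v) * scoreV
    g <- sqrt(pmax(s * v * (1 - v), 0))
    if (is.null(noise))
        noise <- matrix(stats::rnorm(length(v)), nrow(v), ncol(v))
    vNew <- v - driftScale * drift * dt + g * sqrt(dt) * noise
    pmin(pmax(vNew, .INTERIOR_EPS), 1 - .INTERIOR_EPS)
}

.discretize <- function(x, rule) {
    # x: batch x L x k
    B <- dim(x)[1L]
    L <- dim(x)[2L]
    out <- matrix(0L, B, L)
    for (b in seq_len(B)) {
        for (l in seq_len(L)) {
            p <- pmax(x[b, l, ], 0)
            out[b, l] <- if (rule == "argmax") which.max(p)
                else sample.int(length(p), 1L, prob = p / sum(p))
        }
    }
    out
}

# chunked driver: samples are independent, and attention-style models
# cost quadratically in the stacked batch, so integrate in chunks
.reverseIntegrateChunked <- function(model, spec, config, nSamples,
                                     positions, condition = NULL,
                                     clampFn = NULL, chunkSize = 16L) {
    starts <- seq(1L, nSamples, by = chunkSize)
    out <- NULL
    for (st in starts) {
        nn <- min(chunkSize, nSamples - st + 1L)
        cf <- if (is.null(clampFn)) NULL else
            function(v, t) clampFn(v, t, st:(st + nn - 1L))
        cond <- condition
        if (!is.null(cond) && !is.null(dim(cond)) &&
            nrow(cond) == nSamples)
            cond <- cond[st:(st + nn - 1L), , drop = FALSE]
        out <- rbind(out, .reverseIntegrate(model, spec, config, nn,
            positions, cond, cf))
    }
    out
}

# core reverse integrator shared by sampleReverse / inpaintSample;
# clampFn(v, t) optionally overwrites rows/dims at each substep
.reverseIntegrate <- function(model, spec, config, nSamples, positions,
                              condition = NULL, clampFn = NULL) {
    km1 <- spec@k - 1L
    D <- positions * km1
    v <- matrix(NA_real_, nSamples, D)
    for (l in seq_len(positions)) {
        ix <- ((l - 1L) * km1 + 1L):(l * km1)
        v[, ix] <- stationaryStickSample(spec, nSamples)
    }
    c0 <- config$timeDilation
    nSub <- max(1L, as.integer(round(c0)))
    dtModel <- (config$tStart - config$tEnd) / config$nSteps
    dtSub <- dtModel / nSub
    t <- config$tStart
    for (step in seq_len(config$nSteps)) {
        for (sub in seq_len(nSub)) {
            if (!is.null(clampFn)) v <- clampFn(v, t)
            sv <- scoreEval(model, v, t, condition)
            if (any(!is.finite(sv)))
                stop(sprintf("non-finite score at t = %.4g", t))
            # dilation: drift applied c times per unit model time,
            # noise at the undilated per-substep scale
            v <- reverseStep(spec, v, t, sv, dtSub, driftScale = c0)
            t <- max(t - dtSub, config$tEnd)
        }
    }
    if (!is.null(clampFn)) v <- clampFn(v, t)
    v
}

#' Sample from a trained Dirichlet diffusion model
#'
#' Initializes sticks at the exact stationary law (independent Beta
#' draws; no burn-in is needed), integrates the reverse SDE from
#' \code{tStart} down to \code{tEnd} with optional time dilation,
#' converts to simplex coordinates and discretizes to categories.
#'
#' @param model a trained \code{\link{ScoreModel-class}}.
#' @param spec the \code{\link{StickBreakingProcess}}.
#' @param config a \code{\link{samplerConfig}}.
#' @param nSamples number of samples.
#' @param positions sequence length (number of categorical variables).
#' @param condition optional conditioning input passed to the model.
#' @return list with \code{x} (array nSamples x positions x k),
#'   \code{categories} (integer matrix nSamples x positions) and
#'   \code{v} (terminal stick coordinates).
#' @export
sampleReverse <- function(model, spec, config, nSamples, positions,
                          condition = NULL) {
    v <- .reverseIntegrateChunked(model, spec, config, nSamples,
        positions, condition)
    km1 <- spec@k - 1L
    x <- array(NA_real_, c(nSamples, positions, spec@k))
    for (l in seq_len(positions)) {
        ix <- ((l - 1L) * km1 + 1L):(l * km1)
        x[, l, ] <- stickToSimplex(v[, ix, drop = FALSE])
    }
    list(x = x, categories = .discretize(x, config$discretization),
        v = v)
}

#' Conditional sampling by inpainting
#'
#' Clamped positions are replaced, at every reverse integration substep,
#' by forward-diffused versions of their fixed one-hot values at the
#' current time (simulated once as full forward trajectories and read
#' out at the reverse schedule's times); unclamped positions evolve by
#' the reverse SDE. After discretization the clamped positions are set
#' to the clamp values exactly.
#'
#' @inheritParams sampleReverse
#' @param clampPositions integer vector of positions to clamp (1-based).
#' @param clampValues integer vector of category values (same length).
#' @return as \code{\link{sampleReverse}}.
#' @export
inpaintSample <- function(model, spec, config, clampPositions,
                          clampValues, nSamples, positions,
                          condition = NULL) {
    if (length(clampPositions) != length(clampValues))
        stop("'clampPositions' and 'clampValues' must have equal length")
    if (any(duplicated(clampPositions)))
        stop("contradictory clamps: duplicated positions")
    if (any(clampPositions < 1 | clampPositions > positions))
        stop("clamp positions out of range")
    if (any(clampValues < 1 | clampValues > spec@k))
        stop("clamp values out of range")
    km1 <- spec@k - 1L
    nClamp <- length(clampPositions)
    if (nClamp > 0L) {
        # forward trajectories for every clamped stick dim, recorded at
        # the (increasing) set of times the reverse schedule will visit
        nSub <- max(1L, as.integer(round(config$timeDilation)))
        dtSub <- (config$tStart - config$tEnd) / (config$nSteps * nSub)
        revTimes <- config$tStart - dtSub * (0:(config$nSteps * nSub))
        revTimes <- pmax(revTimes, config$tEnd)
        fwdTimes <- sort(unique(revTimes))
        traj <- array(NA_real_, c(nSamples, nClamp * km1,
            length(fwdTimes)))
        colMap <- integer(nClamp * km1)
        ci <- 0L
        for (m in seq_len(nClamp)) {
            cat0 <- clampValues[m]
            for (j in seq_len(km1)) {
                ci <- ci + 1L
                colMap[ci] <- (clampPositions[m] - 1L) * km1 + j
                if (cat0 >= j) {
                    x0 <- rep(as.numeric(cat0 == j), nSamples)
                } else {
                    x0 <- stats::rbeta(nSamples, spec@a[j], spec@b[j])
                }
                traj[, ci, ] <- .emSimulate(spec@a[j], spec@b[j],
                    spec@s[j], x0, fwdTimes, nStepsPerUnit = 200)
            }
        }
        traj <- pmin(pmax(traj, .INTERIOR_EPS), 1 - .INTERIOR_EPS)
        clampFn <- function(v, t, rows) {
            ti <- which.min(abs(fwdTimes - t))
            v[, colMap] <- traj[rows, , ti]
            v
        }
    } else clampFn <- NULL
    v <- .reverseIntegrateChunked(model, spec, config, nSamples,
        positions, condition, clampFn)
    x <- array(NA_real_, c(nSamples, positions, spec@k))
    for (l in seq_len(positions)) {
        ix <- ((l - 1L) * km1 + 1L):(l * km1)
        x[, l, ] <- stickToSimplex(v[, ix, drop = FALSE])
    }
    cats <- .discretize(x, config$discretization)
    if (nClamp > 0L)
        cats[, clampPositions] <- matrix(clampValues, nSamples, nClamp,
            byrow = TRUE)
    list(x = x, categories = cats, v = v)
}
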