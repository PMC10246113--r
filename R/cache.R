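# Pre-sampled dictionary of forward-diffusion draws and scores from the
# two possible initial values (0 and 1) of each stick process.

.processKey <- function(a, b, s) sprintf("a=%g,b=%g,s=%g", a, b, s)

#' Default training time grid
#'
#' Log-spaced grid on \eqn{[t_{min}, T]}. The default horizon T = 4 (for
#' unit-speed presets) lets the slowest spectral mode \eqn{e^{\lambda_1 t}}
#' decay below 1e-2, so the forward process is effectively stationary at
#' the horizon.
#'
#' @param tMin lower end (default 0.01, matching the likelihood cutoff).
#' @param tMax horizon T (default 4).
#' @param n number of grid points (default 100).
#' @return increasing numeric vector.
#' @export
defaultTimeGrid <- function(tMin = 0.01, tMax = 4, n = 100L) {
    exp(seq(log(tMin), log(tMax), length.out = n))
}

#' Build a diffused-sample cache
#'
#' For each distinct Jacobi process in \code{spec}, each grid time and
#' each initial value in \{0, 1\}, simulates \code{nPerCell}
#' Euler--Maruyama trajectories and stores the endpoints together with
#' the spectral transition score at each endpoint. Deterministic given
#' \code{seed}.
#'
#' @param spec a \code{\link{StickBreakingProcess}}.
#' @param timeGrid increasing positive times, all at or above the
#'   spectral validity floor.
#' @param nPerCell draws per (process, time, init) cell.
#' @param seed integer seed.
#' @param nStepsPerUnit EM steps per unit time.
#' @return a \code{\link{DiffusedSampleCache-class}} object.
#' @examples
#' cache <- buildCache(flatStickBreaking(2),
#'     timeGrid = defaultTimeGrid(n = 5L), nPerCell = 50L, seed = 1)
#' cache
#' @export
buildCache <- function(spec, timeGrid = defaultTimeGrid(),
                       nPerCell = 1000L, seed = 1L,
                       nStepsPerUnit = 200) {
    if (any(timeGrid < .JACOBI_TMIN))
        stop("grid times below the spectral validity floor")
    if (any(diff(timeGrid) <= 0)) stop("'timeGrid' must be increasing")
    dimKey <- .processKey(spec@a, spec@b, spec@s)
    keys <- unique(dimKey)
    cells <- list()
    set.seed(seed)
    for (key in keys) {
        j <- match(key, dimKey)
        proc <- stickProcess(spec, j)
        perTime <- vector("list", length(timeGrid))
        for (ti in seq_along(timeGrid)) {
            t <- timeGrid[ti]
            cell <- list()
            for (init in c(0, 1)) {
                xs <- forwardSampleEM(proc, rep(init, nPerCell), t,
                    nStepsPerUnit)
                xs <- pmin(pmax(xs, .INTERIOR_EPS), 1 - .INTERIOR_EPS)
                cell[[as.character(init)]] <- list(
                    samples = xs,
                    scores = transitionScore(proc, init, xs, t))
            }
            perTime[[ti]] <- cell
        }
        cells[[key]] <- perTime
    }
    new("DiffusedSampleCache", spec = spec, timeGrid = timeGrid,
        cells = cells, dimKey = dimKey, nPerCell = as.integer(nPerCell),
        metadata = list(seed = seed, nStepsPerUnit = nStepsPerUnit,
            created = format(Sys.time(), "%Y-%m-%d")))
}

#' Assemble a training minibatch from the cache
#'
#' For a batch of one-hot data (given as category indices) and a batch of
#' grid times, assembles v-space forward samples and matching target
#' scores: determined stick dimensions are drawn uniformly without
#' replacement from the corresponding cache cell, undetermined dimensions
#' are fresh stationary Beta draws with their analytic stationary score.
#'
#' @param cache a \code{\link{DiffusedSampleCache-class}}.
#' @param categories integer matrix (batch x positions) of category
#'   indices in 1..k (a vector is treated as one position per element).
#' @param tIndex integer vector (length batch) of time-grid positions; if
#'   \code{t} is given instead, times are snapped to the nearest grid
#'   point.
#' @param t optional numeric times (alternative to \code{tIndex}).
#' @return list with arrays \code{v}, \code{score} of dim
#'   (batch x positions x (k-1)), logical \code{determined} of the same
#'   shape, and \code{t} (numeric, length batch).
#' @export
drawMinibatch <- function(cache, categories, tIndex = NULL, t = NULL) {
    spec <- cache@spec
    k <- spec@k
    km1 <- k - 1L
    if (is.null(dim(categories)))
        categories <- matrix(categories, ncol = length(categories))
    if (is.null(tIndex)) {
        if (is.null(t)) stop("supply 'tIndex' or 't'")
        tIndex <- vapply(t, function(x) which.min(abs(cache@timeGrid - x)),
            1L)
    }
    B <- nrow(categories)
    L <- ncol(categories)
    if (length(tIndex) != B) stop("'tIndex' must have one entry per row")
    v <- array(NA_real_, c(B, L, km1))
    sc <- array(NA_real_, c(B, L, km1))
    det <- array(FALSE, c(B, L, km1))
    for (bi in seq_len(B)) {
        ti <- tIndex[bi]
        for (j in seq_len(km1)) {
            cell0 <- cache@cells[[cache@dimKey[j]]][[ti]]
            isDet <- categories[bi, ] >= j
            det[bi, , j] <- isDet
            for (init in c(0, 1)) {
                sel <- isDet & ((categories[bi, ] == j) == (init == 1))
                nSel <- sum(sel)
                if (nSel == 0L) next
                cc <- cell0[[as.character(init)]]
                if (length(cc$samples) == 0L) stop("empty cache cell")
                idx <- sample.int(length(cc$samples),
                    min(nSel, length(cc$samples)),
                    replace = nSel > length(cc$samples))
                v[bi, sel, j] <- cc$samples[idx]
                sc[bi, sel, j] <- cc$scores[idx]
            }
            if (any(!isDet)) {
                xs <- stats::rbeta(sum(!isDet), spec@a[j], spec@b[j])
                xs <- pmin(pmax(xs, .INTERIOR_EPS), 1 - .INTERIOR_EPS)
                v[bi, !isDet, j] <- xs
                sc[bi, !isDet, j] <- .stationaryStickScore(spec, j, xs)
            }
        }
    }
    list(v = v, score = sc, determined = det, t = cache@timeGrid[tIndex])
}

#' Persist / restore a diffused-sample cache
#'
#' The cache is written as a single serialized container with the group
#' layout \code{cells[[processKey]][[timeIndex]][[init]]$\{samples,
#' scores\}} plus metadata.
#'
#' @param cache a \code{\link{DiffusedSampleCache-class}}.
#' @param path file path.
#' @return \code{readCache} returns the restored cache.
#' @export
saveCache <- function(cache, path) {
    saveRDS(cache, path)
    invisible(path)
}

#' @rdname saveCache
#' @export
readCache <- function(path) {
    obj <- readRDS(path)
    stopifnot(is(obj, "DiffusedSampleCache"))
    obj
}
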