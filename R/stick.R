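# Stick-breaking transform between the k-simplex and (k-1)-dim stick
# coordinates; multivariate forward diffusion; score change-of-variable.

.INTERIOR_EPS <- 1e-6

#' Stick-breaking transform
#'
#' Maps stick coordinates \eqn{v \in [0,1]^{k-1}} to a simplex point via
#' \eqn{x_1 = v_1, x_2 = (1-v_1)v_2, \ldots, x_k = \prod_j (1-v_j)}.
#' Operates row-wise on matrices.
#'
#' @param v numeric vector of length k - 1, or matrix (batch x (k-1)).
#' @return simplex point(s): vector of length k or matrix (batch x k).
#' @examples
#' stickToSimplex(c(0.3))        # k = 2
#' stickToSimplex(c(0.2, 0.375)) # (0.2, 0.3, 0.5)
#' @export
stickToSimplex <- function(v) {
    vec <- is.null(dim(v))
    v <- rbind(v)
    if (any(v < 0 | v > 1)) stop("'v' must lie in [0, 1]")
    km1 <- ncol(v)
    rem <- cbind(1, t(apply(cbind(1 - v), 1L, cumprod)))
    if (km1 == 1L) rem <- cbind(1, 1 - v)  # apply() drops dims for k = 2
    x <- cbind(v * rem[, seq_len(km1), drop = FALSE],
        rem[, km1 + 1L])
    dimnames(x) <- NULL
    if (vec) drop(x) else x
}

#' Inverse stick-breaking transform
#'
#' Maps a simplex point to stick coordinates
#' \eqn{v_i = x_i / (1 - \sum_{j<i} x_j)}. Once the stick is exhausted
#' (the first \eqn{v_i = 1}), later coordinates are undetermined; they are
#' returned as \code{NA} with \code{determined = FALSE}. For a one-hot
#' input at category c this yields \eqn{v_1 = \ldots = v_{c-1} = 0},
#' \eqn{v_c = 1} (when c < k) and undetermined coordinates after that.
#'
#' @param x numeric vector of length k summing to 1, or matrix
#'   (batch x k).
#' @return a list with \code{v} (matrix/vector, \code{NA} on undetermined
#'   dims) and \code{determined} (logical of the same shape).
#' @examples
#' simplexToStick(c(0, 0, 1, 0))
#' @export
simplexToStick <- function(x) {
    vec <- is.null(dim(x))
    x <- rbind(x)
    if (any(x < -1e-9)) stop("'x' must be nonnegative")
    if (any(abs(rowSums(x) - 1) > 1e-6)) stop("rows of 'x' must sum to 1")
    k <- ncol(x)
    v <- matrix(NA_real_, nrow(x), k - 1L)
    det <- matrix(FALSE, nrow(x), k - 1L)
    rem <- rep(1, nrow(x))
    for (j in seq_len(k - 1L)) {
        ok <- rem > 1e-12
        v[ok, j] <- pmin(pmax(x[ok, j] / rem[ok], 0), 1)
        det[, j] <- ok
        rem <- rem - x[, j]
    }
    if (vec) list(v = drop(v), determined = drop(det))
    else list(v = v, determined = det)
}

#' Log-determinant of the stick-breaking Jacobian
#'
#' For the map v -> (x_1, ..., x_{k-1}) the Jacobian is lower triangular
#' with \eqn{\log|\det \partial x / \partial v| =
#' \sum_j (k - 1 - j) \log(1 - v_j)}.
#'
#' @param v stick coordinates (vector or batch matrix), interior.
#' @return numeric vector of log-determinants (one per row).
#' @export
stickLogDetJacobian <- function(v) {
    v <- rbind(v)
    km1 <- ncol(v)
    unname(drop(log(1 - v) %*% (km1 - seq_len(km1))))
}

# lower-triangular Jacobian J[i,j] = dx_i/dv_j for one stick point
.stickJacobian <- function(v) {
    km1 <- length(v)
    J <- matrix(0, km1, km1)
    cp <- cumprod(c(1, 1 - v[-km1]))  # prod_{j<i}(1-v_j)
    for (i in seq_len(km1)) {
        J[i, i] <- cp[i]
        jj <- seq_len(i - 1L)
        if (length(jj))
            J[i, jj] <- -v[i] * cp[i] / (1 - v[jj])
    }
    J
}

#' Score change-of-variable between stick and simplex coordinates
#'
#' Converts between the gradient of a log-density in v-space and in
#' x-space (using the first k - 1 simplex coordinates as the chart), via
#' \eqn{\nabla_v \log p_v = J^T \nabla_x \log p_x + \nabla_v
#' \log|\det \partial x/\partial v|} with J the stick-breaking Jacobian.
#' The two functions are mutual inverses on interior points.
#'
#' @param v stick coordinates (vector or batch matrix), interior.
#' @param scoreV,scoreX score vectors/matrices matching \code{v}.
#' @return score in the other coordinate system, same shape as input.
#' @export
scoreVToX <- function(v, scoreV) {
    vec <- is.null(dim(v))
    v <- rbind(v)
    scoreV <- rbind(scoreV)
    if (any(v <= 0 | v >= 1))
        stop("'v' must be interior to (0, 1)^(k-1)")
    km1 <- ncol(v)
    out <- matrix(0, nrow(v), km1)
    for (r in seq_len(nrow(v))) {
        J <- .stickJacobian(v[r, ])
        dlogdet <- -(km1 - seq_len(km1)) / (1 - v[r, ])
        out[r, ] <- solve(t(J), scoreV[r, ] - dlogdet)
    }
    if (vec) drop(out) else out
}

#' @rdname scoreVToX
#' @export
scoreXToV <- function(v, scoreX) {
    vec <- is.null(dim(v))
    v <- rbind(v)
    scoreX <- rbind(scoreX)
    if (any(v <= 0 | v >= 1))
        stop("'v' must be interior to (0, 1)^(k-1)")
    km1 <- ncol(v)
    out <- matrix(0, nrow(v), km1)
    for (r in seq_len(nrow(v))) {
        J <- .stickJacobian(v[r, ])
        dlogdet <- -(km1 - seq_len(km1)) / (1 - v[r, ])
        out[r, ] <- drop(t(J) %*% scoreX[r, ]) + dlogdet
    }
    if (vec) drop(out) else out
}

# stationary Beta score of stick j: d/dv log Beta(a_j, b_j)(v)
.stationaryStickScore <- function(spec, j, v) {
    (spec@a[j] - 1) / v - (spec@b[j] - 1) / (1 - v)
}

#' Forward diffusion of one-hot data on the simplex
#'
#' Diffuses a batch of one-hot simplex points to time t. Stick dimensions
#' determined by the data (those up to and including the first v = 1) are
#' simulated with the univariate Jacobi diffusion from their exact 0/1
#' initial values; undetermined dimensions are drawn from their stationary
#' Beta laws (their density never leaves stationarity, so no initial draw
#' is needed). The returned v-space score combines spectral transition
#' scores on determined dimensions with stationary Beta scores on
#' undetermined ones.
#'
#' @param spec a \code{\link{StickBreakingProcess}}.
#' @param categories integer vector of category indices in 1..k (one
#'   datum per element).
#' @param t positive diffusion time (at or above the spectral floor).
#' @param nStepsPerUnit EM steps per unit time for determined dims.
#' @return list with matrices \code{v}, \code{score} and logical
#'   \code{determined}, each (length(categories) x (k-1)).
#' @examples
#' set.seed(1)
#' forwardSampleSimplex(flatStickBreaking(4), c(1, 3), t = 0.5)
#' @export
forwardSampleSimplex <- function(spec, categories, t,
                                 nStepsPerUnit = 1000) {
    k <- spec@k
    if (any(categories < 1 | categories > k))
        stop("'categories' must be in 1..k")
    n <- length(categories)
    km1 <- k - 1L
    v <- matrix(NA_real_, n, km1)
    sc <- matrix(NA_real_, n, km1)
    det <- matrix(FALSE, n, km1)
    for (j in seq_len(km1)) {
        proc <- stickProcess(spec, j)
        isDet <- categories >= j          # dims 1..min(c, k-1) determined
        init <- as.numeric(categories == j)  # v_c = 1, earlier sticks 0
        det[, j] <- isDet
        if (any(isDet)) {
            for (x0 in unique(init[isDet])) {
                sel <- isDet & init == x0
                xs <- forwardSampleEM(proc, rep(x0, sum(sel)), t,
                    nStepsPerUnit)
                xs <- pmin(pmax(xs, .INTERIOR_EPS), 1 - .INTERIOR_EPS)
                v[sel, j] <- xs
                sc[sel, j] <- transitionScore(proc, x0, xs, t)
            }
        }
        if (any(!isDet)) {
            xs <- stats::rbeta(sum(!isDet), spec@a[j], spec@b[j])
            xs <- pmin(pmax(xs, .INTERIOR_EPS), 1 - .INTERIOR_EPS)
            v[!isDet, j] <- xs
            sc[!isDet, j] <- .stationaryStickScore(spec, j, xs)
        }
    }
    list(v = v, score = sc, determined = det)
}

#' Draw from the stationary law of a stick-breaking process
#'
#' Independent Beta(a_j, b_j) draws per stick; for the flat preset the
#' push-forward through \code{\link{stickToSimplex}} is Dir(1, ..., 1).
#'
#' @param spec a \code{\link{StickBreakingProcess}}.
#' @param n number of draws.
#' @return matrix (n x (k-1)) of stick coordinates.
#' @export
stationaryStickSample <- function(spec, n) {
    km1 <- spec@k - 1L
    v <- matrix(0, n, km1)
    for (j in seq_len(km1))
        v[, j] <- stats::rbeta(n, spec@a[j], spec@b[j])
    pmin(pmax(v, .INTERIOR_EPS), 1 - .INTERIOR_EPS)
}
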