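# Univariate Jacobi diffusion: spectral transition density, scores,
# Euler-Maruyama simulation.

# floor below which the truncated spectral series is not trusted (the
# expansion converges slowly as t -> 0)
.JACOBI_TMIN <- 5e-3
# clip for truncated densities before taking logs
.DENSITY_FLOOR <- 1e-40

#' Stationary log-density of a Jacobi diffusion
#'
#' The stationary law is Beta(a, b).
#'
#' @param process a \code{\link{JacobiProcess}}.
#' @param x numeric vector of states in \eqn{[0,1]}.
#' @return numeric vector of log-densities.
#' @examples
#' stationaryLogDensity(JacobiProcess(2, 2), 0.5)  # log(1.5)
#' @export
stationaryLogDensity <- function(process, x) {
    if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
    stats::dbeta(x, process@a, process@b, log = TRUE)
}

#' Eigenvalues of the Jacobi diffusion generator
#'
#' \eqn{\lambda_n = -\frac{1}{2} s\, n (n - 1 + a + b)}; the spectrum is
#' 0 at n = 0 and strictly decreasing in n.
#'
#' @param n nonnegative integer vector of orders.
#' @param process a \code{\link{JacobiProcess}}.
#' @return numeric vector of eigenvalues.
#' @examples
#' jacobiEigenvalue(0:3, JacobiProcess(1, 1))
#' @export
jacobiEigenvalue <- function(n, process) {
    if (any(n < 0)) stop("'n' must be nonnegative")
    -0.5 * process@s * n * (n - 1 + process@a + process@b)
}

# values (and optionally first derivatives) of the classical Jacobi
# polynomials P_n^{(alpha,beta)}(y) for n = 0..nMax at points y in [-1,1],
# by the three-term recurrence; returns length(y) x (nMax+1) matrix
.classicalJacobiMatrix <- function(nMax, alpha, beta, y) {
    m <- matrix(0, length(y), nMax + 1L)
    m[, 1L] <- 1
    if (nMax >= 1L)
        m[, 2L] <- 0.5 * (alpha + beta + 2) * y + 0.5 * (alpha - beta)
    if (nMax >= 2L) {
        for (n in 2:nMax) {
            c1 <- 2 * n * (n + alpha + beta) * (2 * n + alpha + beta - 2)
            c2 <- (2 * n + alpha + beta - 1) *
                (2 * n + alpha + beta) * (2 * n + alpha + beta - 2)
            c3 <- (2 * n + alpha + beta - 1) * (alpha^2 - beta^2)
            c4 <- 2 * (n + alpha - 1) * (n + beta - 1) *
                (2 * n + alpha + beta)
            m[, n + 1L] <- ((c2 * y + c3) * m[, n] - c4 * m[, n - 1L]) / c1
        }
    }
    m
}

# R_n(x) = P_n^{(b-1, a-1)}(2x - 1): eigenfunctions of the generator,
# orthogonal on [0,1] w.r.t. the Beta(a,b) weight; deriv = 1 gives R_n'(x)
# via d/dy P_n^{(A,B)} = ((n + A + B + 1)/2) P_{n-1}^{(A+1,B+1)}
.jacobiPolyMatrix <- function(nMax, a, b, x, deriv = 0L) {
    alpha <- b - 1
    beta <- a - 1
    y <- 2 * x - 1
    if (deriv == 0L) return(.classicalJacobiMatrix(nMax, alpha, beta, y))
    out <- matrix(0, length(x), nMax + 1L)
    if (nMax >= 1L) {
        sub <- .classicalJacobiMatrix(nMax - 1L, alpha + 1, beta + 1, y)
        for (n in 1:nMax)
            # chain rule: d/dx = 2 d/dy
            out[, n + 1L] <- (n + alpha + beta + 1) * sub[, n]
    }
    out
}

#' Modified Jacobi polynomial
#'
#' \eqn{R_n^{(a,b)}(x)}, the order-n eigenfunction of the Jacobi diffusion
#' generator, orthogonal on \eqn{[0,1]} with respect to the Beta(a, b)
#' weight and normalized so that \eqn{R_0 \equiv 1} with
#' \eqn{\int B_{a,b} R_m R_n = \delta_{mn} / d_n} (see
#' \code{\link{jacobiNormConst}}).
#'
#' @param n single nonnegative integer order.
#' @param process a \code{\link{JacobiProcess}}.
#' @param x numeric vector in \eqn{[0,1]}.
#' @param deriv 0 for the value, 1 for the first derivative in x.
#' @return numeric vector.
#' @export
jacobiPolynomial <- function(n, process, x, deriv = 0L) {
    if (n < 0) stop("'n' must be nonnegative")
    if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]")
    .jacobiPolyMatrix(n, process@a, process@b, x, deriv)[, n + 1L]
}

#' Spectral normalization constants
#'
#' The constants \eqn{d_n = 1 / \int_0^1 B_{a,b}(x) R_n(x)^2 dx} entering
#' the transition-density expansion.
#'
#' @param n nonnegative integer vector of orders.
#' @param process a \code{\link{JacobiProcess}}.
#' @return numeric vector of d_n.
#' @export
jacobiNormConst <- function(n, process) {
    a <- process@a
    b <- process@b
    vapply(n, function(nn) {
        if (nn == 0L) return(1)
        exp(lbeta(a, b) + log(2 * nn + a + b - 1) +
            lgamma(nn + a + b - 1) + lgamma(nn + 1) -
            lgamma(nn + a) - lgamma(nn + b))
    }, numeric(1))
}

# adaptive truncation: smallest N (capped) such that the bound on the
# next term e^{lambda_n t} d_n max|R_n|^2 falls below tol; max|R_n| is
# attained at an endpoint when a,b >= 1/2 (checked on a grid otherwise)
.spectralOrder <- function(process, t, tol = 1e-8, cap = 200L) {
    a <- process@a
    b <- process@b
    xs <- if (a >= 0.5 && b >= 0.5) c(0, 1) else seq(0, 1, length.out = 41)
    vals <- .jacobiPolyMatrix(cap, a, b, xs)
    rmax <- apply(abs(vals), 2L, max)
    d <- jacobiNormConst(0:cap, process)
    lam <- jacobiEigenvalue(0:cap, process)
    bound <- exp(lam * t) * d * rmax^2
    idx <- which(bound < tol)
    idx <- idx[idx > 1L]
    if (length(idx) == 0L) return(cap)
    min(idx[1L] - 1L, cap)
}

# shared worker: returns list(S, dS) for the spectral sums
#   S(xt)  = 1 + sum_{n>=1} e^{lambda_n t} d_n R_n(x0) R_n(xt)
#   dS(xt) = sum_{n>=1} e^{lambda_n t} d_n R_n(x0) R_n'(xt)
.spectralSums <- function(process, x0, xt, t, nTerms = NULL,
                          withDeriv = FALSE) {
    if (t <= 0) stop("'t' must be positive")
    if (t < .JACOBI_TMIN)
        stop(sprintf(
            "t = %g is below the spectral validity floor (%g)", t,
            .JACOBI_TMIN))
    if (is.null(nTerms)) nTerms <- .spectralOrder(process, t)
    w <- exp(jacobiEigenvalue(0:nTerms, process) * t) *
        jacobiNormConst(0:nTerms, process) *
        drop(.jacobiPolyMatrix(nTerms, process@a, process@b, x0))
    Rt <- .jacobiPolyMatrix(nTerms, process@a, process@b, xt)
    out <- list(S = drop(Rt %*% w))
    if (withDeriv) {
        Rd <- .jacobiPolyMatrix(nTerms, process@a, process@b, xt,
            deriv = 1L)
        out$dS <- drop(Rd %*% w)
    }
    out
}

#' Spectral transition log-density of the Jacobi diffusion
#'
#' Evaluates \eqn{p(x_t | x_0) = B_{a,b}(x_t)\,[1 + \sum_{n\ge1}
#' e^{\lambda_n t} d_n R_n(x_0) R_n(x_t)]} with adaptive truncation. Small
#' truncation-induced negative values are clipped at a floor (with a
#' warning when the negativity is material); times below the spectral
#' validity floor are rejected.
#'
#' @param process a \code{\link{JacobiProcess}}.
#' @param x0 single initial state in \eqn{[0,1]}.
#' @param xt numeric vector of terminal states in \eqn{[0,1]}.
#' @param t positive diffusion time.
#' @param nTerms optional fixed truncation order (default adaptive).
#' @return numeric vector of log-densities at \code{xt}.
#' @examples
#' p <- JacobiProcess(1, 3)
#' transitionLogDensity(p, 1, c(0.2, 0.8), t = 0.5)
#' @export
transitionLogDensity <- function(process, x0, xt, t, nTerms = NULL) {
    if (length(x0) != 1L || x0 < 0 || x0 > 1)
        stop("'x0' must be a single value in [0, 1]")
    if (any(xt < 0 | xt > 1)) stop("'xt' must lie in [0, 1]")
    S <- .spectralSums(process, x0, xt, t, nTerms)$S
    if (any(S < -1e-3))
        warning("spectral truncation produced materially negative density; clamping")
    dens <- exp(stats::dbeta(xt, process@a, process@b, log = TRUE)) *
        pmax(S, 0)
    log(pmax(dens, .DENSITY_FLOOR))
}

#' Gradient of the transition log-density in the terminal state
#'
#' \eqn{\partial_{x_t} \log p(x_t | x_0)}, computed analytically from the
#' spectral expansion (the Beta-weight score plus the derivative of the
#' truncated series).
#'
#' @inheritParams transitionLogDensity
#' @return numeric vector of scores at \code{xt} (interior points only).
#' @export
transitionScore <- function(process, x0, xt, t, nTerms = NULL) {
    if (any(xt <= 0 | xt >= 1))
        stop("'xt' must be interior to (0, 1); the score diverges at 0/1")
    ss <- .spectralSums(process, x0, xt, t, nTerms, withDeriv = TRUE)
    a <- process@a
    b <- process@b
    (a - 1) / xt - (b - 1) / (1 - xt) +
        ss$dS / pmax(ss$S, .DENSITY_FLOOR)
}

# Euler-Maruyama simulation of a whole vector of trajectories, recording
# the state at each requested time; times must be increasing and > 0
.emSimulate <- function(a, b, s, x0, times, nStepsPerUnit = 1000,
                        eps = 1e-6) {
    stopifnot(all(diff(c(0, times)) > 0))
    x <- pmin(pmax(x0, eps), 1 - eps)
    out <- matrix(NA_real_, length(x0), length(times))
    tPrev <- 0
    for (i in seq_along(times)) {
        span <- times[i] - tPrev
        nSteps <- max(1L, ceiling(nStepsPerUnit * span))
        dt <- span / nSteps
        sqdt <- sqrt(dt)
        for (step in seq_len(nSteps)) {
            drift <- 0.5 * s * (a * (1 - x) - b * x)
            diff <- sqrt(pmax(s * x * (1 - x), 0))
            x <- x + drift * dt + diff * sqdt * stats::rnorm(length(x))
            x <- pmin(pmax(x, eps), 1 - eps)
        }
        out[, i] <- x
        tPrev <- times[i]
    }
    out
}

#' Forward Euler--Maruyama sample of the Jacobi diffusion
#'
#' Simulates \code{dx = (s/2)[a(1-x) - bx] dt + sqrt(s x(1-x)) dw} from
#' \code{x0} to time \code{t} with fixed-step Euler--Maruyama, clamping
#' every intermediate state to \eqn{[\epsilon, 1-\epsilon]} (the drift at
#' the boundaries points inward, so clamping is a numerical safeguard, not
#' a reflection). Uses the session RNG; set \code{set.seed()} for
#' reproducibility.
#'
#' @param process a \code{\link{JacobiProcess}}.
#' @param x0 numeric vector of initial states in \eqn{[0,1]} (one
#'   trajectory per element).
#' @param t positive terminal time.
#' @param nStepsPerUnit EM steps per unit of diffusion time (default 1000).
#' @param eps boundary clamp width.
#' @return numeric vector of terminal states, one per element of
#'   \code{x0}.
#' @examples
#' set.seed(1)
#' forwardSampleEM(JacobiProcess(1, 3), rep(0, 5), t = 1)
#' @export
forwardSampleEM <- function(process, x0, t, nStepsPerUnit = 1000,
                            eps = 1e-6) {
    if (t <= 0) stop("'t' must be positive")
    if (nStepsPerUnit < 1) stop("'nStepsPerUnit' must be >= 1")
    if (any(x0 < 0 | x0 > 1)) stop("'x0' must lie in [0, 1]")
    drop(.emSimulate(process@a, process@b, process@s, x0, t,
        nStepsPerUnit, eps))
}
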