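#' @import methods
NULL

#' Univariate Jacobi diffusion process
#'
#' An Ito diffusion on \eqn{[0,1]} with drift \eqn{\frac{s}{2}[a(1-x)-bx]}
#' and diffusion coefficient \eqn{\sqrt{s\,x(1-x)}}. Its stationary
#' distribution is Beta(a, b); the speed factor \code{s} rescales time
#' without changing the stationary law. The diffusion coefficient vanishes
#' at 0 and 1 while the drift points inward, so trajectories remain in
#' \eqn{[0,1]}.
#'
#' @slot a positive numeric, first stationary shape parameter.
#' @slot b positive numeric, second stationary shape parameter.
#' @slot s positive numeric, speed factor (default 1).
#'
#' @examples
#' jp <- JacobiProcess(a = 1, b = 3)
#' stationaryLogDensity(jp, 0.25)
#' @name JacobiProcess-class
#' @rdname JacobiProcess-class
#' @exportClass JacobiProcess
setClass("JacobiProcess",
    representation(a = "numeric", b = "numeric", s = "numeric"),
    prototype(a = 1, b = 1, s = 1))

setValidity("JacobiProcess", function(object) {
    msg <- character()
    for (sl in c("a", "b", "s")) {
        v <- slot(object, sl)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", sl))
    }
    if (length(msg)) msg else TRUE
})

#' @param a,b positive stationary shape parameters of the Beta(a, b)
#'   stationary law.
#' @param s positive speed factor. The preset \code{speed = "unit"} uses
#'   \code{s = 1}; any positive value may be supplied directly.
#' @return \code{JacobiProcess} returns a \code{JacobiProcess} object.
#' @rdname JacobiProcess-class
#' @export
JacobiProcess <- function(a, b, s = 1) {
    new("JacobiProcess", a = as.numeric(a), b = as.numeric(b),
        s = as.numeric(s))
}

setMethod("show", "JacobiProcess", function(object) {
    cat(sprintf(
        "JacobiProcess: dx = (s/2)[a(1-x) - bx] dt + sqrt(s x(1-x)) dw\n"))
    cat(sprintf("  a = %g, b = %g, s = %g  (stationary Beta(%g, %g))\n",
        object@a, object@b, object@s, object@a, object@b))
})

#' Multivariate simplex diffusion by stick-breaking construction
#'
#' A diffusion on the probability simplex with k categories, built from
#' k - 1 independent univariate Jacobi diffusions through the classical
#' stick-breaking map \eqn{x_1 = v_1, x_2 = (1-v_1)v_2, \ldots}. With the
#' stick laws Beta(1, k-1), Beta(1, k-2), ..., Beta(1, 1) the stationary
#' distribution of x is the flat Dirichlet Dir(1, ..., 1); see
#' \code{\link{flatStickBreaking}}.
#'
#' @slot k integer, number of categories (k >= 2).
#' @slot a,b,s numeric vectors of length k - 1 holding the per-stick
#'   Jacobi parameters, in stick order v_1, ..., v_{k-1}.
#'
#' @name StickBreakingProcess-class
#' @rdname StickBreakingProcess-class
#' @exportClass StickBreakingProcess
setClass("StickBreakingProcess",
    representation(k = "integer", a = "numeric", b = "numeric",
        s = "numeric"))

setValidity("StickBreakingProcess", function(object) {
    msg <- character()
    if (object@k < 2L) msg <- c(msg, "'k' must be >= 2")
    for (sl in c("a", "b", "s")) {
        v <- slot(object, sl)
        if (length(v) != object@k - 1L)
            msg <- c(msg, sprintf("'%s' must have length k - 1", sl))
        if (any(!is.finite(v)) || any(v <= 0))
            msg <- c(msg, sprintf("'%s' must be positive and finite", sl))
    }
    if (length(msg)) msg else TRUE
})

#' @param k integer number of categories.
#' @param a,b,s numeric vectors (recycled to length k - 1) of per-stick
#'   Jacobi parameters.
#' @return a \code{StickBreakingProcess}.
#' @rdname StickBreakingProcess-class
#' @export
StickBreakingProcess <- function(k, a, b, s = 1) {
    k <- as.integer(k)
    new("StickBreakingProcess", k = k,
        a = rep_len(as.numeric(a), k - 1L),
        b = rep_len(as.numeric(b), k - 1L),
        s = rep_len(as.numeric(s), k - 1L))
}

#' Flat-Dirichlet stick-breaking preset
#'
#' Returns the stick-breaking specification whose stationary law is the
#' flat Dirichlet Dir(1, ..., 1): stick j follows a Jacobi diffusion with
#' stationary Beta(1, k - j).
#'
#' @param k integer number of categories (k >= 2).
#' @param s positive speed factor shared by all sticks.
#' @return a \code{StickBreakingProcess}.
#' @examples
#' flatStickBreaking(4)
#' @export
flatStickBreaking <- function(k, s = 1) {
    k <- as.integer(k)
    if (k < 2L) stop("'k' must be >= 2")
    StickBreakingProcess(k, a = rep(1, k - 1L), b = seq(k - 1L, 1L), s = s)
}

setMethod("show", "StickBreakingProcess", function(object) {
    cat(sprintf("StickBreakingProcess with %d categories (%d sticks)\n",
        object@k, object@k - 1L))
    cat("  stick Beta(a, b) laws: ",
        paste(sprintf("(%g,%g)", object@a, object@b), collapse = " "),
        "\n", sep = "")
    cat(sprintf("  speed: %s\n", paste(unique(object@s), collapse = " ")))
})

#' @param object,spec a \code{StickBreakingProcess}.
#' @rdname StickBreakingProcess-class
#' @export
nCategories <- function(object) object@k

#' @param j stick index in 1..(k-1).
#' @return \code{stickProcess} returns the \code{JacobiProcess} of stick j.
#' @rdname StickBreakingProcess-class
#' @export
stickProcess <- function(spec, j) {
    JacobiProcess(spec@a[j], spec@b[j], spec@s[j])
}

#' Dictionary of pre-sampled forward-diffusion draws
#'
#' Because every one-hot datum starts each determined stick dimension at
#' exactly 0 or 1, forward-diffusion samples for training can be
#' pre-computed once per (process, time, init) cell and looked up during
#' training. Each cell stores \code{nPerCell} Euler--Maruyama endpoints
#' together with the spectral transition score evaluated at each endpoint.
#'
#' Cells are indexed by a process key \code{"a=..,b=..,s=.."}, then by
#' time-grid position, then by init (\code{"0"} or \code{"1"}); use
#' \code{\link{saveCache}} / \code{\link{readCache}} for on-disk
#' persistence.
#'
#' @slot spec the \code{StickBreakingProcess} the cache was built for.
#' @slot timeGrid increasing positive numeric vector of diffusion times.
#' @slot cells nested list \code{cells[[key]][[ti]][[init]]} with elements
#'   \code{samples} and \code{scores} (numeric vectors of length
#'   \code{nPerCell}).
#' @slot dimKey character vector mapping stick dimension to process key.
#' @slot nPerCell integer, draws per cell.
#' @slot metadata list (seed, EM steps per unit time, creation date).
#'
#' @name DiffusedSampleCache-class
#' @rdname DiffusedSampleCache-class
#' @exportClass DiffusedSampleCache
setClass("DiffusedSampleCache",
    representation(spec = "StickBreakingProcess", timeGrid = "numeric",
        cells = "list", dimKey = "character", nPerCell = "integer",
        metadata = "list"))

setValidity("DiffusedSampleCache", function(object) {
    if (any(diff(object@timeGrid) <= 0))
        return("'timeGrid' must be strictly increasing")
    if (any(object@timeGrid <= 0))
        return("'timeGrid' must be positive")
    TRUE
})

setMethod("show", "DiffusedSampleCache", function(object) {
    cat(sprintf(
        "DiffusedSampleCache: %d processes x %d times x 2 inits, %d draws/cell\n",
        length(object@cells), length(object@timeGrid), object@nPerCell))
    cat(sprintf("  time grid [%g, %g], k = %d\n", min(object@timeGrid),
        max(object@timeGrid), object@spec@k))
})

#' Learned score function
#'
#' A parameterized score field s_theta(v, t[, condition]) evaluated in
#' stick (v) space. The \code{forward} slot is a pure function of
#' (params, v, t, condition) that optionally records onto an autodiff tape
#' for training; \code{\link{scoreEval}} evaluates it numerically.
#'
#' @slot params named list of numeric parameter matrices.
#' @slot forward function(params, v, t, condition, tape); with
#'   \code{tape = NULL} it returns a numeric matrix of v-space scores with
#'   the shape of \code{v}, otherwise a list with the output node and the
#'   parameter leaf nodes.
#' @slot space character, the score's output space (always \code{"v"}).
#' @slot meta list describing the architecture (kind, k, positions, ...).
#'
#' @name ScoreModel-class
#' @rdname ScoreModel-class
#' @exportClass ScoreModel
setClass("ScoreModel",
    representation(params = "list", forward = "function",
        space = "character", meta = "list"),
    prototype(space = "v"))

setMethod("show", "ScoreModel", function(object) {
    np <- sum(vapply(object@params, length, 1L))
    cat(sprintf("ScoreModel <%s>: %d parameters, %s-space output\n",
        if (is.null(object@meta$kind)) "custom" else object@meta$kind,
        np, object@space))
})

#' Evaluate a score model
#'
#' @param model a \code{ScoreModel}.
#' @param v numeric matrix (batch x D) of stick coordinates.
#' @param t numeric vector of diffusion times (length 1 or nrow(v)).
#' @param condition optional conditioning input (architecture specific).
#' @return numeric matrix of v-space scores, same shape as \code{v}.
#' @export
scoreEval <- function(model, v, t, condition = NULL) {
    model@forward(model@params, v, t, condition, tape = NULL)
}

#' @return \code{modelParameters} returns the named list of parameter
#'   matrices.
#' @rdname ScoreModel-class
#' @param model a \code{ScoreModel}.
#' @export
modelParameters <- function(model) model@params
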