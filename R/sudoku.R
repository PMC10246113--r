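# Sudoku grids: backtracking generation, puzzles, validators,
# exhaustive enumeration of the 4x4 variant, string I/O.

.sudokuBlockIndex <- function(n) {
    k <- n * n
    row <- rep(seq_len(k), each = k)
    col <- rep(seq_len(k), times = k)
    (ceiling(row / n) - 1L) * n + ceiling(col / n)
}

#' Validate a Sudoku grid
#'
#' A grid is valid when each row, column and n x n block contains each
#' symbol 1..n^2 exactly once. Grids with blanks (0 or NA) are invalid.
#'
#' @param grid integer matrix n^2 x n^2.
#' @return logical.
#' @export
isValidGrid <- function(grid) {
    k <- nrow(grid)
    n <- as.integer(round(sqrt(k)))
    if (n * n != k || ncol(grid) != k) return(FALSE)
    if (any(is.na(grid)) || any(grid < 1L) || any(grid > k))
        return(FALSE)
    blk <- matrix(.sudokuBlockIndex(n), k, k, byrow = TRUE)
    for (i in seq_len(k)) {
        if (length(unique(grid[i, ])) != k) return(FALSE)
        if (length(unique(grid[, i])) != k) return(FALSE)
        if (length(unique(grid[blk == i])) != k) return(FALSE)
    }
    TRUE
}

# candidates consistent with partial grid at cell (r, c)
.sudokuCandidates <- function(grid, r, c, n) {
    k <- n * n
    br <- ((r - 1L) %/% n) * n + 1L
    bc <- ((c - 1L) %/% n) * n + 1L
    used <- c(grid[r, ], grid[, c],
        grid[br:(br + n - 1L), bc:(bc + n - 1L)])
    setdiff(seq_len(k), used[!is.na(used) & used > 0L])
}

# backtracking fill; candidate order randomized when shuffle = TRUE;
# countOnly > 0 counts solutions up to that many instead of returning one
.sudokuSolve <- function(grid, n, shuffle = FALSE, countOnly = 0L) {
    k <- n * n
    blanks <- which(is.na(grid) | grid == 0L)
    count <- 0L
    recurse <- function(g, idx) {
        if (idx > length(blanks)) {
            count <<- count + 1L
            return(if (countOnly > 0L) NULL else g)
        }
        cell <- blanks[idx]
        r <- ((cell - 1L) %% k) + 1L
        c <- ((cell - 1L) %/% k) + 1L
        cand <- .sudokuCandidates(g, r, c, n)
        if (shuffle && length(cand) > 1L) cand <- sample(cand)
        for (d in cand) {
            g[r, c] <- d
            res <- recurse(g, idx + 1L)
            if (!is.null(res)) return(res)
            if (countOnly > 0L && count >= countOnly) return(NULL)
        }
        g[r, c] <- 0L
        NULL
    }
    res <- recurse(grid, 1L)
    if (countOnly > 0L) count else res
}

#' Generate a complete valid Sudoku grid
#'
#' Randomized backtracking: cells are filled in order with candidate
#' digits tried in random order, guaranteeing a valid grid by
#' construction. Deterministic given the session RNG state.
#'
#' @param n block size (2 for 4x4, 3 for 9x9).
#' @return integer matrix n^2 x n^2, always valid.
#' @examples
#' set.seed(1)
#' isValidGrid(generateFullGrid(2))
#' @export
generateFullGrid <- function(n = 3L) {
    k <- as.integer(n * n)
    g <- matrix(0L, k, k)
    out <- .sudokuSolve(g, n, shuffle = TRUE)
    if (is.null(out)) stop("generation failed")  # cannot happen
    out
}

#' Make a puzzle by removing clues from a full grid
#'
#' @param grid a complete valid grid.
#' @param nClues number of filled cells to keep.
#' @param unique if TRUE, only removals that keep the solution unique
#'   are accepted (checked by exhaustive backtracking).
#' @param maxTries resampling attempts for the uniqueness-checked case.
#' @return integer matrix with 0 marking blanks.
#' @export
makePuzzle <- function(grid, nClues, unique = FALSE, maxTries = 200L) {
    k <- nrow(grid)
    n <- as.integer(round(sqrt(k)))
    nCells <- k * k
    if (nClues < 0L || nClues > nCells) stop("invalid 'nClues'")
    for (try in seq_len(maxTries)) {
        keep <- sample.int(nCells, nClues)
        puz <- matrix(0L, k, k)
        puz[keep] <- grid[keep]
        if (!unique) return(puz)
        if (.sudokuSolve(puz, n, countOnly = 2L) == 1L) return(puz)
    }
    stop("no uniqueness-preserving clue set found; increase 'nClues'")
}

#' Solve a puzzle by backtracking
#'
#' @param puzzle grid with 0/NA blanks.
#' @return a completed valid grid, or NULL if unsolvable.
#' @export
solveSudoku <- function(puzzle) {
    n <- as.integer(round(sqrt(nrow(puzzle))))
    .sudokuSolve(puzzle, n)
}

#' Does a grid solve a puzzle?
#'
#' TRUE when \code{grid} is completely valid and agrees with every clue
#' of \code{puzzle}. Only complete correctness counts; there is no
#' partial credit.
#'
#' @param puzzle grid with 0/NA blanks (the clues).
#' @param grid a candidate completed grid.
#' @return logical.
#' @export
solvesGrid <- function(puzzle, grid) {
    clue <- !is.na(puzzle) & puzzle > 0L
    isValidGrid(grid) && all(grid[clue] == puzzle[clue])
}

#' Enumerate all valid 4x4 grids
#'
#' Exhaustive backtracking over the 4x4 (n = 2) variant; there are
#' exactly 288 valid grids. Used as an exact support for testing whether
#' model samples fall inside the valid set.
#'
#' @return list of 288 integer 4x4 matrices.
#' @export
enumerateMiniGrids <- function() {
    out <- list()
    recurse <- function(g, cell) {
        if (cell > 16L) {
            out[[length(out) + 1L]] <<- g
            return(invisible(NULL))
        }
        r <- ((cell - 1L) %% 4L) + 1L
        c <- ((cell - 1L) %/% 4L) + 1L
        for (d in .sudokuCandidates(g, r, c, 2L)) {
            g[r, c] <- d
            recurse(g, cell + 1L)
        }
        invisible(NULL)
    }
    recurse(matrix(0L, 4L, 4L), 1L)
    out
}

#' Sudoku string I/O
#'
#' Grids are serialized row-major as n^4-character strings (81
#' characters for standard Sudoku), with \code{0} or \code{.} marking
#' blanks.
#'
#' @param grid integer matrix (0/NA = blank).
#' @return \code{sudokuToString}: a single string.
#' @export
sudokuToString <- function(grid) {
    g <- t(grid)
    g[is.na(g)] <- 0L
    paste(as.integer(g), collapse = "")
}

#' @rdname sudokuToString
#' @param s an n^4-character string (digits, with 0 or "." as blank).
#' @return \code{stringToSudoku}: an integer matrix with 0 blanks.
#' @export
stringToSudoku <- function(s) {
    ch <- strsplit(gsub("\\.", "0", s), "")[[1]]
    k <- as.integer(round(sqrt(length(ch))))
    if (k * k != length(ch)) stop("string length must be a square")
    matrix(as.integer(ch), k, k, byrow = TRUE)
}

#' @rdname sudokuToString
#' @param grids list of grids; \code{path} a file path.
#' @param path file to write to / read from (one grid string per line).
#' @export
writeSudokuStrings <- function(grids, path) {
    writeLines(vapply(grids, sudokuToString, character(1)), path)
    invisible(path)
}

#' @rdname sudokuToString
#' @export
readSudokuStrings <- function(path) {
    lapply(readLines(path), stringToSudoku)
}

#' Categories <-> grid helpers
#'
#' Model samples are category matrices (samples x 16 or x 81 cells,
#' row-major); these helpers convert a row to a grid and back.
#'
#' @param cats integer vector of length n^4 (row-major cell order).
#' @return \code{categoriesToGrid}: an integer matrix.
#' @export
categoriesToGrid <- function(cats) {
    k <- as.integer(round(sqrt(length(cats))))
    matrix(as.integer(cats), k, k, byrow = TRUE)
}

#' @rdname categoriesToGrid
#' @param grid integer matrix.
#' @export
gridToCategories <- function(grid) as.integer(t(grid))
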