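# Synthetic promoter-like sequences: PWM-planted motifs with paired
# per-position initiation-signal profiles, plus FASTA / track I/O.
# These emulate the shape of TSS-centered promoter data (sequence +
# CAGE-like signal); they are synthetic stand-ins, not genomic data.

.DNA <- c("A", "C", "G", "T")

#' Example position weight matrix
#'
#' A TATA-box-like probability matrix (4 x 8, rows A/C/G/T), used as the
#' default planted motif for the synthetic promoter generator.
#'
#' @return numeric matrix with columns summing to 1.
#' @export
examplePWM <- function() {
    consensus <- c("T", "A", "T", "A", "A", "A", "T", "A")
    w <- length(consensus)
    pwm <- matrix(0.02, 4, w, dimnames = list(.DNA, NULL))
    for (i in seq_len(w)) pwm[consensus[i], i] <- 0.94
    pwm
}

.samplePWM <- function(pwm) {
    paste(apply(pwm, 2L, function(p) sample(.DNA, 1L, prob = p)),
        collapse = "")
}

#' Generate synthetic promoter-like records
#'
#' Each record is a length-L sequence over A/C/G/T with its "TSS" at the
#' center, and a matching nonnegative per-position signal profile.
#' Background bases are i.i.d. with the given composition; each record
#' plants \code{nMotifs} PWM draws at random positions upstream of the
#' center. The profile is a sum of Gaussian bumps keyed to the planted
#' motif positions (shifted downstream toward the TSS) plus one bump at
#' the TSS and multiplicative noise, rescaled so it integrates to
#' \code{expressionLevel}.
#'
#' @param nRecords number of records.
#' @param L sequence length (default 1024).
#' @param pwm probability matrix (4 x width, rows A/C/G/T) or NULL for
#'   motif-free background.
#' @param nMotifs planted motifs per record.
#' @param expressionLevel target integral of each profile.
#' @param baseComposition background base probabilities (A, C, G, T).
#' @param bumpSd standard deviation of the profile bumps in bp.
#' @param noiseSd multiplicative log-normal noise sd on the profile.
#' @return list with \code{sequences} (character vector),
#'   \code{profiles} (matrix nRecords x L), \code{motifPositions}
#'   (list of integer vectors of motif start positions).
#' @examples
#' set.seed(1)
#' rec <- generatePromoterLike(2, L = 128)
#' nchar(rec$sequences)
#' @export
generatePromoterLike <- function(nRecords, L = 1024L, pwm = examplePWM(),
                                 nMotifs = 1L, expressionLevel = 100,
                                 baseComposition = rep(0.25, 4),
                                 bumpSd = 15, noiseSd = 0.1) {
    seqs <- character(nRecords)
    profiles <- matrix(0, nRecords, L)
    motifPos <- vector("list", nRecords)
    tss <- L %/% 2L
    w <- if (is.null(pwm)) 0L else ncol(pwm)
    pos <- seq_len(L)
    for (i in seq_len(nRecords)) {
        base <- sample(.DNA, L, replace = TRUE, prob = baseComposition)
        starts <- integer(0)
        if (!is.null(pwm) && nMotifs > 0L) {
            lo <- max(1L, tss - 120L)
            hi <- max(lo, tss - w - 5L)
            starts <- sort(sample(lo:hi, nMotifs))
            for (st in starts) {
                m <- strsplit(.samplePWM(pwm), "")[[1]]
                base[st:(st + w - 1L)] <- m
            }
        }
        seqs[i] <- paste(base, collapse = "")
        motifPos[[i]] <- starts
        prof <- stats::dnorm(pos, mean = tss, sd = bumpSd)
        for (st in starts)
            prof <- prof + 0.5 * stats::dnorm(pos, mean = st + w + 20L,
                sd = bumpSd)
        prof <- prof * exp(stats::rnorm(L, sd = noiseSd))
        profiles[i, ] <- prof / sum(prof) * expressionLevel
    }
    list(sequences = seqs, profiles = profiles,
        motifPositions = motifPos)
}

#' Scan a sequence with a PWM
#'
#' Log-odds scan against a uniform background; returns start positions
#' scoring at or above \code{threshold} (in log2-odds units).
#'
#' @param sequence a character string over A/C/G/T.
#' @param pwm probability matrix (4 x width, rows A/C/G/T).
#' @param threshold minimum log2-odds score (the default 4 bits recovers
#'   essentially all draws of \code{\link{examplePWM}} while background
#'   positions score far below 0 on average).
#' @return integer vector of match start positions.
#' @export
scanPWM <- function(sequence, pwm, threshold = 4) {
    chars <- strsplit(sequence, "")[[1]]
    idx <- match(chars, .DNA)
    w <- ncol(pwm)
    lods <- log2(pmax(pwm, 1e-6) / 0.25)
    n <- length(idx) - w + 1L
    if (n < 1L) return(integer(0))
    scores <- vapply(seq_len(n), function(st) {
        sum(lods[cbind(idx[st:(st + w - 1L)], seq_len(w))])
    }, numeric(1))
    which(scores >= threshold)
}

#' Sequence and track I/O
#'
#' FASTA via Biostrings; profiles as two-column (position, signal)
#' tab-delimited tracks, one file per record or a wide matrix form.
#'
#' @param sequences character vector of sequences.
#' @param path output file.
#' @param names optional FASTA record names.
#' @export
writeSequencesFASTA <- function(sequences, path, names = NULL) {
    if (is.null(names))
        names <- sprintf("seq_%d", seq_along(sequences))
    x <- Biostrings::DNAStringSet(sequences)
    names(x) <- names
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' @rdname writeSequencesFASTA
#' @return \code{readSequencesFASTA}: named character vector.
#' @export
readSequencesFASTA <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
}

#' @rdname writeSequencesFASTA
#' @param profile numeric vector (one per-position signal track).
#' @export
writeProfileTSV <- function(profile, path) {
    utils::write.table(
        data.frame(position = seq_along(profile), signal = profile),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSequencesFASTA
#' @return \code{readProfileTSV}: numeric vector of signal values.
#' @export
readProfileTSV <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t")
    df$signal[order(df$position)]
}

#' Encode sequences as category matrices
#'
#' @param sequences character vector over A/C/G/T.
#' @return integer matrix (n x L) with A=1, C=2, G=3, T=4.
#' @export
sequencesToCategories <- function(sequences) {
    t(vapply(sequences,
        function(s) match(strsplit(s, "")[[1]], .DNA),
        integer(nchar(sequences[1])), USE.NAMES = FALSE))
}

#' @rdname sequencesToCategories
#' @param cats integer matrix (n x L) of categories 1..4.
#' @return \code{categoriesToSequences}: character vector.
#' @export
categoriesToSequences <- function(cats) {
    apply(cats, 1L, function(r) paste(.DNA[r], collapse = ""))
}
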