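# Progressive star alignment over affine-gap pairwise global alignment.
#
# The oligo panels this package aligns are small (typically ~12 sequences
# of 4-10 letters), so a plain R implementation of Gotoh's three-state
# recursion is ample and keeps the tie-break fully specified: at every
# choice point the preference order is match/mismatch, then gap in the
# second sequence, then gap in the first, which places unavoidable gaps
# as early as possible in the first sequence of each pair.
# A gap of length L costs gapOpen + (L - 1) * gapExtend.

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch alignment with Gotoh's affine-gap recursion and a
#' deterministic tie-break (match preferred, then a gap in `b`, then a
#' gap in `a`). Identity scoring by default.
#'
#' @param a,b character scalars (no gap characters).
#' @param match,mismatch per-position scores.
#' @param gapOpen score of the first position of a gap (negative).
#' @param gapExtend score of each further gapped position (negative).
#' @return A list with `a`, `b` (aligned strings of equal length) and
#'   `score`.
#' @export
alignPair <- function(a, b, match = 1, mismatch = -1, gapOpen = -2,
                      gapExtend = -1) {
    stopifnot(is.character(a), is.character(b),
              length(a) == 1L, length(b) == 1L, nchar(a) > 0, nchar(b) > 0)
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    NEG <- -1e9
    # state matrices: M diagonal, X gap in b (consumes a), Y gap in a
    M <- matrix(NEG, n + 1L, m + 1L)
    X <- matrix(NEG, n + 1L, m + 1L)
    Y <- matrix(NEG, n + 1L, m + 1L)
    M[1L, 1L] <- 0
    for (i in seq_len(n))
        X[i + 1L, 1L] <- gapOpen + (i - 1L) * gapExtend
    for (j in seq_len(m))
        Y[1L, j + 1L] <- gapOpen + (j - 1L) * gapExtend
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (av[i] == bv[j]) match else mismatch
            M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
            X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gapOpen,
                                     X[i, j + 1L] + gapExtend,
                                     Y[i, j + 1L] + gapOpen)
            Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gapOpen,
                                     X[i + 1L, j] + gapOpen,
                                     Y[i + 1L, j] + gapExtend)
        }
    }
    score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
    eq <- function(x, y) abs(x - y) < 1e-9
    # traceback; preference order M > X > Y at every tie
    state <- if (eq(M[n + 1L, m + 1L], score)) "M"
             else if (eq(X[n + 1L, m + 1L], score)) "X" else "Y"
    i <- n; j <- m
    ra <- character(0); rb <- character(0)
    while (i > 0L || j > 0L) {
        if (i == 0L) {            # only gaps in a remain
            ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
        } else if (j == 0L) {     # only gaps in b remain
            ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
        } else if (state == "M") {
            s <- if (av[i] == bv[j]) match else mismatch
            prev <- M[i + 1L, j + 1L] - s
            ra <- c(av[i], ra); rb <- c(bv[j], rb)
            state <- if (eq(M[i, j], prev)) "M"
                     else if (eq(X[i, j], prev)) "X" else "Y"
            i <- i - 1L; j <- j - 1L
        } else if (state == "X") {
            cur <- X[i + 1L, j + 1L]
            ra <- c(av[i], ra); rb <- c("-", rb)
            state <- if (eq(M[i, j + 1L] + gapOpen, cur)) "M"
                     else if (eq(X[i, j + 1L] + gapExtend, cur)) "X"
                     else "Y"
            i <- i - 1L
        } else {
            cur <- Y[i + 1L, j + 1L]
            ra <- c("-", ra); rb <- c(bv[j], rb)
            state <- if (eq(M[i + 1L, j] + gapOpen, cur)) "M"
                     else if (eq(X[i + 1L, j] + gapOpen, cur)) "X"
                     else "Y"
            j <- j - 1L
        }
    }
    list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
         score = score)
}

# merge a new pairwise alignment of the center into the running master
# alignment ("once a gap, always a gap")
.merge_star <- function(masterCenter, masterRows, pairCenter, pairOther) {
    mc <- strsplit(masterCenter, "")[[1]]
    pc <- strsplit(pairCenter, "")[[1]]
    po <- strsplit(pairOther, "")[[1]]
    i <- 1L; j <- 1L
    ops <- character(0)  # "B" both advance, "M" gap in pair side, "P" gap in master side
    while (i <= length(mc) || j <= length(pc)) {
        if (i <= length(mc) && mc[i] == "-") {
            if (j <= length(pc) && pc[j] == "-") {
                ops <- c(ops, "B"); i <- i + 1L; j <- j + 1L
            } else {
                ops <- c(ops, "M"); i <- i + 1L
            }
        } else if (j <= length(pc) && pc[j] == "-") {
            ops <- c(ops, "P"); j <- j + 1L
        } else {
            ops <- c(ops, "B"); i <- i + 1L; j <- j + 1L
        }
    }
    expand <- function(row, gapOn) {
        rv <- strsplit(row, "")[[1]]
        out <- character(length(ops)); k <- 1L
        for (t in seq_along(ops)) {
            if (ops[t] == gapOn) out[t] <- "-"
            else { out[t] <- rv[k]; k <- k + 1L }
        }
        paste(out, collapse = "")
    }
    newMasterRows <- vapply(masterRows, expand, character(1), gapOn = "P")
    newCenter <- expand(masterCenter, "P")
    newOther <- expand(pairOther, "M")
    list(center = newCenter, rows = newMasterRows, other = newOther)
}

#' Progressive star alignment of pseudo-amino-acid sequences
#'
#' Aligns a set of equal-alphabet letter strings by the star heuristic:
#' the center sequence maximizing the summed pairwise alignment score is
#' chosen (ties to the first in input order), every other sequence is
#' aligned to it with [alignPair()], and pairwise gap patterns are merged
#' under "once a gap, always a gap". The result is deterministic for a
#' fixed parameter set and input order. `mode = "gapless"` stacks
#' equal-length sequences column-wise without aligning.
#'
#' @param seqs named character vector (or [Biostrings::AAStringSet]) of
#'   sequences; at least one, no gap characters.
#' @param match,mismatch,gapOpen,gapExtend scoring, see [alignPair()].
#' @param mode `"auto"` (align) or `"gapless"` (require equal lengths).
#' @return A named character vector of aligned sequences of equal length,
#'   in input order.
#' @export
alignPseudoSequences <- function(seqs, match = 1, mismatch = -1,
                                 gapOpen = -2, gapExtend = -1,
                                 mode = c("auto", "gapless")) {
    mode <- match.arg(mode)
    if (is(seqs, "XStringSet")) {
        nm <- names(seqs)
        seqs <- as.character(seqs)
        names(seqs) <- nm
    }
    stopifnot(is.character(seqs))
    if (length(seqs) == 0L) stop("no sequences to align")
    if (any(!nzchar(seqs))) stop("empty sequence in input")
    if (any(grepl("-", seqs, fixed = TRUE)))
        stop("input sequences must not contain gap characters")
    if (any(grepl("[^A-Z]", seqs)))
        stop("sequences must be uppercase letter strings over one alphabet")
    if (mode == "gapless") {
        if (length(unique(nchar(seqs))) != 1L)
            stop("gapless mode requires equal-length sequences")
        return(seqs)
    }
    n <- length(seqs)
    if (n == 1L) return(seqs)
    scores <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
            sc <- alignPair(seqs[[i]], seqs[[j]], match, mismatch,
                            gapOpen, gapExtend)$score
            scores[i, j] <- sc; scores[j, i] <- sc
        }
    }
    center <- which.max(rowSums(scores))  # ties -> first index
    order_rest <- setdiff(seq_len(n), center)
    masterCenter <- seqs[[center]]
    rows <- list()  # aligned non-center rows, keyed by original index
    for (k in order_rest) {
        pa <- alignPair(seqs[[center]], seqs[[k]],
                        match, mismatch, gapOpen, gapExtend)
        merged <- .merge_star(masterCenter,
                              vapply(rows, identity, character(1),
                                     USE.NAMES = FALSE),
                              pa$a, pa$b)
        masterCenter <- merged$center
        if (length(rows))
            rows[] <- as.list(merged$rows)
        rows[[as.character(k)]] <- merged$other
    }
    out <- character(n)
    out[center] <- masterCenter
    for (k in order_rest) out[k] <- rows[[as.character(k)]]
    names(out) <- names(seqs)
    out
}
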