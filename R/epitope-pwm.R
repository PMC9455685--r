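# IC50-weighted position-weight-matrix inference of antibody-bound HS
# epitopes: oligos are translated to pseudo-amino-acid sequences, each
# sequence enters the multiple sequence file in reference/IC50 copies
# (stronger inhibitors -- lower IC50 -- are represented more often), the
# copy-weighted alignment is summarized column-wise into frequencies and
# information content, and the matrix is back-translated to HS codes.

#' Copy count of an oligo in the IC50-weighted MSF
#'
#' The number of times an oligo's sequence is placed in the weighted
#' multiple sequence file is `reference / IC50`, rounded half away from
#' zero, with a floor of one copy so every measured oligo stays
#' represented. An IC50 of 25 ug/ml yields 4 copies; an IC50 of 1 yields
#' 100. The count is non-increasing in the IC50.
#'
#' @param ic50 numeric vector of IC50 values (ug/ml), all `> 0`.
#' @param reference dimensionless reference the IC50 is related to
#'   (default 100).
#' @return Integer vector of copy counts, all `>= 1`.
#' @examples
#' ic50ToCopies(c(25, 1, 50))  # 4 100 2
#' @export
ic50ToCopies <- function(ic50, reference = 100) {
    stopifnot(is.numeric(ic50), is.numeric(reference),
              length(reference) == 1L, reference > 0)
    if (any(!is.finite(ic50)) || any(ic50 <= 0))
        stop("IC50 values must be finite and > 0")
    # round half away from zero (base round() rounds half to even)
    as.integer(pmax(1, floor(reference / ic50 + 0.5)))
}

.check_ic50_records <- function(oligoIds, records) {
    stopifnot(is.data.frame(records),
              all(c("oligo_id", "ic50") %in% colnames(records)))
    dup <- unique(records$oligo_id[duplicated(records$oligo_id)])
    if (length(dup))
        stop("duplicate IC50 record(s) for oligo(s): ",
             paste(dup, collapse = ", "))
    missing <- setdiff(oligoIds, records$oligo_id)
    if (length(missing))
        stop("missing IC50 record(s) for oligo(s): ",
             paste(missing, collapse = ", "))
    records[match(oligoIds, records$oligo_id), , drop = FALSE]
}

#' Build the IC50-weighted multiple sequence file
#'
#' Translates each oligo to its pseudo-amino-acid sequence, aligns the
#' set with [alignPseudoSequences()], and attaches the copy count
#' [ic50ToCopies()] derived from each oligo's inhibition potency, so that
#' oligos with lower IC50 contribute proportionally more to the position
#' weight matrix.
#'
#' @param oligos list of [HSOligo-class] objects with unique ids.
#' @param records data.frame with columns `oligo_id` and `ic50`
#'   (ug/ml), exactly one row per oligo.
#' @param map an [AlphabetMap-class]; built from `oligos` when missing.
#' @param reference weighting reference, see [ic50ToCopies()].
#' @param mode alignment mode passed to [alignPseudoSequences()].
#' @param ... further alignment parameters for [alignPseudoSequences()].
#' @return A [WeightedMSF-class].
#' @export
buildWeightedMSF <- function(oligos, records, map = buildAlphabet(oligos),
                             reference = 100, mode = "auto", ...) {
    if (is(oligos, "HSOligo")) oligos <- list(oligos)
    stopifnot(length(oligos) >= 1L)
    ids <- vapply(oligos, oligoId, character(1))
    if (anyDuplicated(ids))
        stop("oligo ids must be unique")
    records <- .check_ic50_records(ids, records)
    copies <- ic50ToCopies(records$ic50, reference)
    seqs <- vapply(oligos, toPseudoSequence, character(1), map = map)
    names(seqs) <- ids
    aligned <- if (length(seqs) > 1L || mode == "gapless")
        alignPseudoSequences(seqs, mode = mode, ...)
    else seqs
    new("WeightedMSF", ids = ids, aligned = unname(aligned),
        copies = copies, alphabet = map)
}

#' @describeIn WeightedMSF-class aligned sequences, named by oligo id.
#' @param x a `WeightedMSF`.
#' @export
alignedSequences <- function(x) {
    stopifnot(is(x, "WeightedMSF"))
    structure(x@aligned, names = x@ids)
}

#' @describeIn WeightedMSF-class integer copy counts, named by oligo id.
#' @export
copyCounts <- function(x) {
    stopifnot(is(x, "WeightedMSF"))
    structure(x@copies, names = x@ids)
}

setMethod("show", "WeightedMSF", function(object) {
    cat(sprintf("WeightedMSF: %d sequences, %d columns, %d total copies\n",
                length(object@ids),
                if (length(object@aligned)) nchar(object@aligned[1]) else 0L,
                sum(object@copies)))
    for (i in seq_along(object@ids))
        cat(sprintf("  %-12s %s  x%d\n", object@ids[i], object@aligned[i],
                    object@copies[i]))
})

#' Compute the position weight matrix of a weighted MSF
#'
#' Column frequencies are copy-weighted letter counts divided by the
#' copy-weighted non-gap total of the column; the result equals naive
#' counting over the sequence multiset in which each sequence is
#' physically duplicated its copy-count times. Per-column information
#' content is `I_j = log2(K) - H_j` with `H_j` the Shannon entropy of the
#' column's letter frequencies and `K` the alphabet size; the optional
#' small-sample correction subtracts `e_n = (K - 1) / (2 ln(2) n)` with
#' `n` the column's copy-weighted non-gap count (clamped at 0). Columns
#' with no non-gap mass get zero frequency and information and are
#' flagged in `allGap`.
#'
#' @param msf a [WeightedMSF-class].
#' @param smallSampleCorrection apply the entropy bias correction
#'   (default `FALSE`).
#' @return A [PositionWeightMatrix-class].
#' @export
computePWM <- function(msf, smallSampleCorrection = FALSE) {
    stopifnot(is(msf, "WeightedMSF"), length(msf@ids) >= 1L)
    letters <- msf@alphabet@letters
    K <- length(letters)
    L <- nchar(msf@aligned[1])
    chars <- do.call(rbind, strsplit(msf@aligned, ""))
    w <- as.numeric(msf@copies)
    freq <- matrix(0, K, L, dimnames = list(letters, NULL))
    gapFraction <- numeric(L)
    allGap <- logical(L)
    info <- numeric(L)
    total <- sum(w)
    for (j in seq_len(L)) {
        col <- chars[, j]
        gapw <- sum(w[col == .GAP])
        gapFraction[j] <- gapw / total
        nonGap <- total - gapw
        if (nonGap <= 0) {
            allGap[j] <- TRUE
            next
        }
        counts <- vapply(letters, function(a) sum(w[col == a]), numeric(1))
        p <- counts / nonGap
        freq[, j] <- p
        pp <- p[p > 0]
        H <- -sum(pp * log2(pp))
        I <- log2(K) - H
        if (smallSampleCorrection)
            I <- I - (K - 1) / (2 * log(2) * nonGap)
        info[j] <- max(0, I)
    }
    new("PositionWeightMatrix", freq = freq, info = info,
        gapFraction = gapFraction, allGap = allGap, alphabet = msf@alphabet)
}

#' @describeIn PositionWeightMatrix-class the K x L frequency matrix.
#' @param x a `PositionWeightMatrix`.
#' @export
pwmFrequencies <- function(x) {
    stopifnot(is(x, "PositionWeightMatrix")); x@freq
}

#' @describeIn PositionWeightMatrix-class per-column information content
#'   in bits.
#' @export
informationContent <- function(x) {
    stopifnot(is(x, "PositionWeightMatrix")); x@info
}

#' @describeIn PositionWeightMatrix-class per-column copy-weighted gap
#'   fraction.
#' @export
gapFraction <- function(x) {
    stopifnot(is(x, "PositionWeightMatrix")); x@gapFraction
}

#' @describeIn PositionWeightMatrix-class per-column consensus letter
#'   (`NA` for all-gap columns; frequency ties resolved to the
#'   alphabetically first letter).
#' @export
consensusLetters <- function(x) {
    stopifnot(is(x, "PositionWeightMatrix"))
    vapply(seq_len(ncol(x@freq)), function(j) {
        if (x@allGap[j]) return(NA_character_)
        rownames(x@freq)[which.max(x@freq[, j])]
    }, character(1))
}

setMethod("show", "PositionWeightMatrix", function(object) {
    cat(sprintf(
        "PositionWeightMatrix: %d letters x %d columns (max %.2f bits)\n",
        nrow(object@freq), ncol(object@freq), log2(nrow(object@freq))))
    cat("  consensus:", paste(consensusLetters(object), collapse = ""), "\n")
    cat("  information (bits):",
        paste(sprintf("%.2f", object@info), collapse = " "), "\n")
})

#' Back-translate a position weight matrix to HS codes
#'
#' Replaces each pseudo-amino-acid letter by its 11-digit disaccharide
#' code, leaving frequencies, gap fractions and information content
#' untouched, and attaches logo heights (`frequency x column
#' information`), which therefore sum per column to the column's
#' information content.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param map an [AlphabetMap-class]; defaults to the matrix's own map.
#' @return An [HSLogo-class].
#' @export
pwmToHSLogo <- function(pwm, map = pwm@alphabet) {
    stopifnot(is(pwm, "PositionWeightMatrix"), is(map, "AlphabetMap"))
    used <- rownames(pwm@freq)[rowSums(pwm@freq) > 0]
    unmapped <- setdiff(used, map@letters)
    if (length(unmapped))
        stop("letter(s) with nonzero frequency not in the alphabet map: ",
             paste(unmapped, collapse = ", "))
    keep <- rownames(pwm@freq) %in% map@letters
    freq <- pwm@freq[keep, , drop = FALSE]
    rownames(freq) <- .code_for_letter(map, rownames(freq))
    heights <- freq * rep(pwm@info, each = nrow(freq))
    new("HSLogo", freq = freq, heights = heights, info = pwm@info,
        gapFraction = pwm@gapFraction)
}

#' @describeIn HSLogo-class tidy per-column data.frame of codes,
#'   frequencies and stacked heights.
#' @param x an `HSLogo`.
#' @export
logoTable <- function(x) {
    stopifnot(is(x, "HSLogo"))
    L <- ncol(x@freq)
    out <- do.call(rbind, lapply(seq_len(L), function(j) {
        nz <- x@freq[, j] > 0
        if (!any(nz)) return(NULL)
        data.frame(position = j, code = rownames(x@freq)[nz],
                   frequency = x@freq[nz, j], height = x@heights[nz, j],
                   row.names = NULL)
    }))
    if (is.null(out))
        out <- data.frame(position = integer(), code = character(),
                          frequency = numeric(), height = numeric())
    out
}

setMethod("show", "HSLogo", function(object) {
    cat(sprintf("HSLogo: %d disaccharide codes x %d columns\n",
                nrow(object@freq), ncol(object@freq)))
    cat("  information (bits):",
        paste(sprintf("%.2f", object@info), collapse = " "), "\n")
})

#' Log-odds match score of an oligo against a position weight matrix
#'
#' Scores every ungapped window placement of the oligo's pseudo-sequence
#' against the matrix columns and returns the best window sum of
#' `log2(p / (1/K))`, with column probabilities floored at a pseudocount
#' so absent letters score `log2(pseudocount * K)` per position. When the
#' oligo is shorter than the matrix it slides within the matrix;
#' otherwise the matrix slides along the oligo. The score is invariant
#' under any relabeling of the alphabet applied consistently to matrix
#' and oligo.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param oligo an [HSOligo-class], or a pseudo-sequence letter string.
#' @param map map used to translate `oligo`; defaults to the matrix's.
#' @param pseudocount probability floor (default `1e-3`).
#' @return Single numeric match score in bits.
#' @export
scoreOligo <- function(pwm, oligo, map = pwm@alphabet, pseudocount = 1e-3) {
    stopifnot(is(pwm, "PositionWeightMatrix"))
    seq <- if (is(oligo, "HSOligo")) toPseudoSequence(oligo, map)
           else as.character(oligo)
    letters <- strsplit(seq, "")[[1]]
    stopifnot(length(letters) >= 1L)
    K <- nrow(pwm@freq)
    L <- ncol(pwm@freq)
    n <- length(letters)
    idx <- match(letters, rownames(pwm@freq))
    perPos <- function(colj, li) {
        p <- if (is.na(li)) 0 else pwm@freq[li, colj]
        log2(max(p, pseudocount) * K)
    }
    w <- min(n, L)
    starts_seq <- seq_len(max(1L, n - w + 1L))
    starts_col <- seq_len(max(1L, L - w + 1L))
    best <- -Inf
    for (ss in starts_seq) {
        for (sc in starts_col) {
            s <- sum(vapply(seq_len(w) - 1L, function(o)
                perPos(sc + o, idx[ss + o]), numeric(1)))
            if (s > best) best <- s
        }
    }
    best
}
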