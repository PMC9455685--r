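# Independent oracles and fixture builders shared across test files.

# Exhaustive affine-gap global alignment score by recursion over edit
# operations (no dynamic programming), for tiny strings only.
align_score_oracle <- function(a, b, match = 1, mismatch = -1,
                               gapOpen = -2, gapExtend = -1) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    rec <- function(i, j, last) {
        if (i > length(av) && j > length(bv)) return(0)
        best <- -Inf
        if (i <= length(av) && j <= length(bv)) {
            s <- if (av[i] == bv[j]) match else mismatch
            best <- max(best, s + rec(i + 1L, j + 1L, "M"))
        }
        if (i <= length(av)) {
            g <- if (identical(last, "X")) gapExtend else gapOpen
            best <- max(best, g + rec(i + 1L, j, "X"))
        }
        if (j <= length(bv)) {
            g <- if (identical(last, "Y")) gapExtend else gapOpen
            best <- max(best, g + rec(i, j + 1L, "Y"))
        }
        best
    }
    rec(1L, 1L, "none")
}

# Naive PWM: physically duplicate each sequence its copy-count times,
# then count letters column by column.
pwm_oracle <- function(aligned, copies, letters) {
    rows <- rep(aligned, copies)
    chars <- do.call(rbind, strsplit(rows, ""))
    L <- ncol(chars)
    K <- length(letters)
    freq <- matrix(0, K, L, dimnames = list(letters, NULL))
    info <- numeric(L)
    gapf <- numeric(L)
    allgap <- logical(L)
    for (j in seq_len(L)) {
        col <- chars[, j]
        gapf[j] <- mean(col == "-")
        ng <- col[col != "-"]
        if (!length(ng)) { allgap[j] <- TRUE; next }
        for (k in seq_len(K))
            freq[k, j] <- sum(ng == letters[k]) / length(ng)
        p <- freq[, j][freq[, j] > 0]
        info[j] <- max(0, log2(K) + sum(p * log2(p)))
    }
    list(freq = freq, info = info, gapf = gapf, allgap = allgap)
}

# Build a WeightedMSF directly from aligned strings, copies and an
# alphabet drawn from the 48-state code space.
make_msf <- function(aligned, copies, nLetters) {
    all48 <- vapply(allDisaccharides(), encodeDisaccharide, character(1))
    map <- alphabetFromCodes(sort(all48)[seq_len(nLetters)])
    new("WeightedMSF", ids = sprintf("s%02d", seq_along(aligned)),
        aligned = aligned, copies = as.integer(copies), alphabet = map)
}

# Random aligned instance over the first nLetters letters of the map.
random_msf <- function(nSeq, L, nLetters, gapProb = 0.2,
                       maxCopies = 5L) {
    letters <- HSglycotyper:::.PSEUDO_LETTERS[seq_len(nLetters)]
    aligned <- vapply(seq_len(nSeq), function(i)
        paste(ifelse(stats::runif(L) < gapProb, "-",
                     sample(letters, L, replace = TRUE)), collapse = ""),
        character(1))
    make_msf(aligned, sample.int(maxCopies, nSeq, replace = TRUE),
             nLetters)
}

# Fraction of planted-epitope columns whose inferred per-column argmax
# matches the ground-truth consensus, maximized over contiguous windows.
recovered_fraction <- function(pwm, truthLetters) {
    cons <- consensusLetters(pwm)
    L <- length(truthLetters)
    n <- length(cons)
    best <- 0
    for (s in seq_len(n - L + 1L))
        best <- max(best,
                    mean(cons[s:(s + L - 1L)] == truthLetters,
                         na.rm = TRUE))
    best
}

# Small three-type oligo fixtures used across hs_code and pwm tests.
toy_oligos <- function() {
    list(parseHSStructure("GlcA-GlcNAc-IdoA2S-GlcNS6S", id = "a"),
         parseHSStructure("IdoA2S-GlcNS6S-GlcA-GlcNS", id = "b"),
         parseHSStructure("GlcA-GlcNS-GlcA-GlcNAc", id = "c"))
}
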