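# Quintuplet coding of HS disaccharides.
#
# Eleven digits describe one disaccharide. The layout fixes the five
# modifiable sites of the quintuplet code in dedicated digit fields and
# pads with constant structural digits; it is defined only here, so the
# digit semantics can be revised in one place without touching callers.
#
#   pos  1  uronic-acid ring marker, constant "1"
#   pos  2  epimer: 1 = GlcA, 2 = IdoA
#   pos  3  2-O-sulfation: 0/1
#   pos  4  reserved, constant "0"
#   pos  5  glycosidic linkage marker, constant "4" (1->4 linked)
#   pos  6  glucosamine ring marker, constant "2"
#   pos  7  N-position state: 0 = NH2 (unsubstituted), 1 = NAc, 2 = NS
#   pos  8  3-O-sulfation: 0/1
#   pos  9  reserved, constant "0"
#   pos 10  6-O-sulfation: 0/1
#   pos 11  glycosidic linkage marker, constant "4"

.CODE_WIDTH <- 11L
.FIXED_DIGITS <- c(`1` = "1", `4` = "0", `5` = "4", `6` = "2", `9` = "0",
                   `11` = "4")
.EPIMER_DIGIT <- c(GlcA = "1", IdoA = "2")
.NSTATE_DIGIT <- c(NH2 = "0", NAc = "1", NS = "2")

# 20-letter amino-acid alphabet used for pseudo-sequences
.PSEUDO_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.GAP <- "-"

.flag_digit <- function(x) ifelse(x, "1", "0")

#' Encode an HS disaccharide as an 11-digit quintuplet code
#'
#' Writes the five modifiable sites of a disaccharide -- uronic-acid
#' epimer and 2-O-sulfation, glucosamine N-state, 3-O- and 6-O-sulfation
#' -- into fixed digit fields of an 11-digit string. Distinct
#' disaccharides always yield distinct codes, and concatenating unit
#' codes encodes a chain.
#'
#' @param d an [HSDisaccharide-class].
#' @return An 11-character digit string.
#' @seealso [decodeDisaccharide()] for the inverse, [encodeOligo()] for
#'   chains.
#' @examples
#' encodeDisaccharide(HSDisaccharide("IdoA", "NS", s2 = TRUE, s6 = TRUE))
#' @export
encodeDisaccharide <- function(d) {
    stopifnot(is(d, "HSDisaccharide"))
    digits <- character(.CODE_WIDTH)
    digits[as.integer(names(.FIXED_DIGITS))] <- .FIXED_DIGITS
    digits[2L] <- .EPIMER_DIGIT[[d@epimer]]
    digits[3L] <- .flag_digit(d@s2)
    digits[7L] <- .NSTATE_DIGIT[[d@nstate]]
    digits[8L] <- .flag_digit(d@s3)
    digits[10L] <- .flag_digit(d@s6)
    paste(digits, collapse = "")
}

#' Decode an 11-digit quintuplet code
#'
#' Inverse of [encodeDisaccharide()]. Malformed input -- wrong length, a
#' constant structural digit altered, or an undefined value in a variable
#' field -- raises an error naming the offending field.
#'
#' @param code an 11-character digit string.
#' @return An [HSDisaccharide-class].
#' @export
decodeDisaccharide <- function(code) {
    stopifnot(is.character(code), length(code) == 1L)
    if (nchar(code) != .CODE_WIDTH)
        stop("code must have exactly ", .CODE_WIDTH, " digits, got ",
             nchar(code))
    digits <- strsplit(code, "")[[1]]
    if (!all(digits %in% as.character(0:9)))
        stop("code must contain digits 0-9 only")
    for (i in names(.FIXED_DIGITS)) {
        pos <- as.integer(i)
        if (digits[pos] != .FIXED_DIGITS[[i]])
            stop(sprintf(
                "structural digit at position %d must be '%s', got '%s'",
                pos, .FIXED_DIGITS[[i]], digits[pos]))
    }
    .decode_field <- function(pos, map, field) {
        hit <- names(map)[map == digits[pos]]
        if (!length(hit))
            stop(sprintf(
                "undefined value '%s' in the %s field (digit %d)",
                digits[pos], field, pos))
        hit
    }
    .decode_flag <- function(pos, field) {
        if (!digits[pos] %in% c("0", "1"))
            stop(sprintf(
                "undefined value '%s' in the %s field (digit %d)",
                digits[pos], field, pos))
        digits[pos] == "1"
    }
    HSDisaccharide(
        epimer = .decode_field(2L, .EPIMER_DIGIT, "epimer"),
        nstate = .decode_field(7L, .NSTATE_DIGIT, "N-state"),
        s2 = .decode_flag(3L, "2-O-sulfation"),
        s3 = .decode_flag(8L, "3-O-sulfation"),
        s6 = .decode_flag(10L, "6-O-sulfation"))
}

#' Encode an oligosaccharide as a concatenated code string
#'
#' @param o an [HSOligo-class].
#' @return A digit string of length `11 * length(o@units)`, non-reducing
#'   to reducing end.
#' @export
encodeOligo <- function(o) {
    stopifnot(is(o, "HSOligo"))
    paste(vapply(o@units, encodeDisaccharide, character(1)), collapse = "")
}

#' Decode a concatenated code string into an oligosaccharide
#'
#' @param code a digit string whose length is a multiple of 11.
#' @param id label for the resulting oligo.
#' @return An [HSOligo-class].
#' @export
decodeOligo <- function(code, id = "oligo") {
    stopifnot(is.character(code), length(code) == 1L)
    n <- nchar(code)
    if (n == 0L || n %% .CODE_WIDTH != 0L)
        stop("code length must be a positive multiple of ", .CODE_WIDTH,
             ", got ", n)
    starts <- seq(1L, n, by = .CODE_WIDTH)
    units <- lapply(starts, function(s)
        decodeDisaccharide(substr(code, s, s + .CODE_WIDTH - 1L)))
    HSOligo(id, units)
}

#' Enumerate all 48 representable disaccharides
#'
#' The full product space of the five coded sites: 2 epimers x 3 N-states
#' x 2 x 2 x 2 sulfation flags.
#'
#' @return A list of 48 distinct [HSDisaccharide-class] objects.
#' @export
allDisaccharides <- function() {
    grid <- expand.grid(epimer = c("GlcA", "IdoA"),
                        nstate = c("NAc", "NS", "NH2"),
                        s2 = c(FALSE, TRUE), s3 = c(FALSE, TRUE),
                        s6 = c(FALSE, TRUE),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(grid)), function(i)
        HSDisaccharide(grid$epimer[i], grid$nstate[i], grid$s2[i],
                       grid$s3[i], grid$s6[i]))
}

# -- human-readable structure dialect ---------------------------------------
#
# One disaccharide is written  <UA><GlcN>  joined by "-" (or an en dash),
# and disaccharides are joined the same way, e.g.
#   "IdoA2S-GlcNS6S-GlcA-GlcNAc"
# UA token:    (GlcA|IdoA)(2S)?
# GlcN token:  Glc(NAc|NS|NH2)(3S)?(6S)?   (3S before 6S)
# Tokens must alternate UA, GlcN, UA, GlcN, ...; unknown tokens are
# errors, never guesses.

.UA_RE <- "^(GlcA|IdoA)(2S)?$"
.GLCN_RE <- "^Glc(NAc|NS|NH2)(3S)?(6S)?$"

#' Parse the human-readable HS structure dialect
#'
#' Parses strings such as `"IdoA2S-GlcNS6S-GlcA-GlcNAc"` into an oligo.
#' Tokens are dash-separated and must alternate between a uronic-acid
#' token (`GlcA`/`IdoA`, optional `2S`) and a glucosamine token
#' (`GlcNAc`/`GlcNS`/`GlcNH2`, optional `3S` then `6S`). Unknown tokens
#' raise an error.
#'
#' @param structure character scalar in the dialect above.
#' @param id label for the oligo.
#' @return An [HSOligo-class].
#' @export
parseHSStructure <- function(structure, id = "oligo") {
    stopifnot(is.character(structure), length(structure) == 1L)
    s <- gsub("–", "-", trimws(structure))  # accept en dash
    tokens <- strsplit(s, "-", fixed = TRUE)[[1]]
    if (length(tokens) == 0L || length(tokens) %% 2L != 0L)
        stop("structure must contain an even number of dash-separated ",
             "tokens (uronic acid, glucosamine, ...): '", structure, "'")
    units <- vector("list", length(tokens) %/% 2L)
    for (k in seq_along(units)) {
        ua <- tokens[2L * k - 1L]
        gn <- tokens[2L * k]
        mua <- regmatches(ua, regexec(.UA_RE, ua))[[1]]
        if (!length(mua))
            stop("unknown uronic-acid token '", ua, "' in '", structure, "'")
        mgn <- regmatches(gn, regexec(.GLCN_RE, gn))[[1]]
        if (!length(mgn))
            stop("unknown glucosamine token '", gn, "' in '", structure, "'")
        units[[k]] <- HSDisaccharide(
            epimer = mua[2], nstate = mgn[2],
            s2 = nzchar(mua[3]), s3 = nzchar(mgn[3]), s6 = nzchar(mgn[4]))
    }
    HSOligo(id, units)
}

#' Format a disaccharide or oligo in the structure dialect
#'
#' @param x an [HSDisaccharide-class] or [HSOligo-class].
#' @return A character scalar in the dialect accepted by
#'   [parseHSStructure()].
#' @export
formatHSStructure <- function(x) {
    fmt1 <- function(d)
        paste0(d@epimer, if (d@s2) "2S", "-Glc", d@nstate,
               if (d@s3) "3S", if (d@s6) "6S")
    if (is(x, "HSDisaccharide")) return(fmt1(x))
    stopifnot(is(x, "HSOligo"))
    paste(vapply(x@units, fmt1, character(1)), collapse = "-")
}

# -- pseudo-amino-acid alphabet ---------------------------------------------

#' Build the pseudo-amino-acid alphabet for a set of oligos
#'
#' Collects the distinct disaccharide codes across the set, sorts them
#' lexicographically and assigns letters of the standard 20-letter
#' amino-acid alphabet in fixed order. The map is therefore bijective and
#' identical for any ordering of the same input set.
#'
#' @param oligos list of [HSOligo-class] objects (a single oligo is
#'   accepted).
#' @return An [AlphabetMap-class].
#' @export
buildAlphabet <- function(oligos) {
    if (is(oligos, "HSOligo")) oligos <- list(oligos)
    stopifnot(length(oligos) >= 1L)
    codes <- unlist(lapply(oligos, function(o)
        vapply(o@units, encodeDisaccharide, character(1))))
    codes <- sort(unique(codes))
    if (length(codes) > length(.PSEUDO_LETTERS))
        stop("the data contain ", length(codes), " distinct disaccharide ",
             "types; at most ", length(.PSEUDO_LETTERS),
             " fit the pseudo-amino-acid alphabet")
    new("AlphabetMap", codes = codes,
        letters = .PSEUDO_LETTERS[seq_along(codes)])
}

#' Build an alphabet map directly from code strings
#'
#' @param codes character vector of 11-digit disaccharide codes.
#' @return An [AlphabetMap-class] over the sorted unique codes.
#' @export
alphabetFromCodes <- function(codes) {
    codes <- sort(unique(as.character(codes)))
    bad <- nchar(codes) != .CODE_WIDTH
    if (any(bad))
        stop("not 11-digit codes: ", paste(codes[bad], collapse = ", "))
    if (length(codes) > length(.PSEUDO_LETTERS))
        stop("the data contain ", length(codes), " distinct disaccharide ",
             "types; at most ", length(.PSEUDO_LETTERS),
             " fit the pseudo-amino-acid alphabet")
    new("AlphabetMap", codes = codes,
        letters = .PSEUDO_LETTERS[seq_along(codes)])
}

#' @describeIn AlphabetMap-class the 11-digit codes, sorted.
#' @param x an `AlphabetMap`.
#' @export
alphabetCodes <- function(x) { stopifnot(is(x, "AlphabetMap")); x@codes }

#' @describeIn AlphabetMap-class the assigned letters, parallel to
#'   `alphabetCodes(x)`.
#' @export
alphabetLetters <- function(x) { stopifnot(is(x, "AlphabetMap")); x@letters }

.letter_for_code <- function(map, code) {
    i <- match(code, map@codes)
    if (anyNA(i)) {
        missing <- unique(code[is.na(i)])
        stop("disaccharide code(s) not in the alphabet map: ",
             paste(missing, collapse = ", "))
    }
    map@letters[i]
}

.code_for_letter <- function(map, letter) {
    i <- match(letter, map@letters)
    if (anyNA(i)) {
        missing <- unique(letter[is.na(i)])
        stop("letter(s) not in the alphabet map: ",
             paste(missing, collapse = ", "))
    }
    map@codes[i]
}

#' Translate an oligo into its pseudo-amino-acid sequence
#'
#' @param o an [HSOligo-class].
#' @param map an [AlphabetMap-class] covering every unit of `o`.
#' @return A character scalar with one letter per disaccharide.
#' @seealso [fromPseudoSequence()] for the inverse.
#' @export
toPseudoSequence <- function(o, map) {
    stopifnot(is(o, "HSOligo"), is(map, "AlphabetMap"))
    codes <- vapply(o@units, encodeDisaccharide, character(1))
    paste(.letter_for_code(map, codes), collapse = "")
}

#' Back-translate a pseudo-sequence into a code string
#'
#' Gap characters are dropped. `fromPseudoSequence(toPseudoSequence(o, m),
#' m)` always equals `encodeOligo(o)`.
#'
#' @param seq letter string over `map` (gaps allowed).
#' @param map an [AlphabetMap-class].
#' @return The concatenated 11-digit-per-unit code string.
#' @export
fromPseudoSequence <- function(seq, map) {
    stopifnot(is.character(seq), length(seq) == 1L, is(map, "AlphabetMap"))
    letters <- strsplit(seq, "")[[1]]
    letters <- letters[letters != .GAP]
    if (!length(letters)) return("")
    paste(.code_for_letter(map, letters), collapse = "")
}

#' Pseudo-sequences for a set of oligos
#'
#' @param oligos list of [HSOligo-class] objects.
#' @param map an [AlphabetMap-class]; built from `oligos` when missing.
#' @return A named [Biostrings::AAStringSet] of pseudo-sequences.
#' @export
pseudoSequences <- function(oligos, map = buildAlphabet(oligos)) {
    if (is(oligos, "HSOligo")) oligos <- list(oligos)
    seqs <- vapply(oligos, toPseudoSequence, character(1), map = map)
    names(seqs) <- vapply(oligos, function(o) o@id, character(1))
    Biostrings::AAStringSet(seqs)
}

setMethod("show", "HSDisaccharide", function(object) {
    cat("HSDisaccharide:", formatHSStructure(object),
        sprintf("[%s]\n", encodeDisaccharide(object)))
})

setMethod("show", "HSOligo", function(object) {
    cat(sprintf("HSOligo '%s' (%d units)\n  %s\n", object@id,
                length(object@units), formatHSStructure(object)))
})

setMethod("show", "AlphabetMap", function(object) {
    cat(sprintf("AlphabetMap with %d disaccharide types\n",
                length(object@codes)))
    if (length(object@codes))
        cat(sprintf("  %s = %s\n", object@letters, object@codes), sep = "")
})

#' @describeIn HSOligo-class number of disaccharide units.
#' @param x an `HSOligo`.
#' @export
setMethod("length", "HSOligo", function(x) length(x@units))

#' @describeIn HSOligo-class the oligo's disaccharide units.
#' @export
oligoUnits <- function(x) { stopifnot(is(x, "HSOligo")); x@units }

#' @describeIn HSOligo-class the oligo's label.
#' @export
oligoId <- function(x) { stopifnot(is(x, "HSOligo")); x@id }
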