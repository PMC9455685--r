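#' @import methods
#' @importFrom S4Vectors metadata
NULL

#' HSDisaccharide: one heparan sulfate chain unit
#'
#' An HS disaccharide is a hexuronic acid (GlcA or its C5 epimer IdoA)
#' linked to a glucosamine. Five sites can be modified: the epimer state
#' and 2-O-sulfation of the uronic acid, and the N-position state
#' (N-acetyl, N-sulfate or unsubstituted amine), 3-O-sulfation and
#' 6-O-sulfation of the glucosamine. The 2 x 3 x 2 x 2 x 2 = 48
#' combinations span the representable chemical space.
#'
#' @slot epimer `"GlcA"` or `"IdoA"`.
#' @slot nstate `"NAc"` (N-acetyl), `"NS"` (N-sulfate) or `"NH2"`
#'   (unsubstituted).
#' @slot s2,s3,s6 logical sulfation flags for 2-O (uronic acid), 3-O and
#'   6-O (glucosamine).
#' @export
setClass("HSDisaccharide",
    representation(epimer = "character", nstate = "character",
                   s2 = "logical", s3 = "logical", s6 = "logical"))

setValidity("HSDisaccharide", function(object) {
    msg <- character()
    if (length(object@epimer) != 1L || !object@epimer %in% c("GlcA", "IdoA"))
        msg <- c(msg, "'epimer' must be \"GlcA\" or \"IdoA\"")
    if (length(object@nstate) != 1L || !object@nstate %in% c("NAc", "NS", "NH2"))
        msg <- c(msg, "'nstate' must be \"NAc\", \"NS\" or \"NH2\"")
    for (s in c("s2", "s3", "s6"))
        if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be TRUE or FALSE", s))
    if (length(msg)) msg else TRUE
})

#' Construct an HSDisaccharide
#'
#' @param epimer `"GlcA"` or `"IdoA"`.
#' @param nstate `"NAc"`, `"NS"` or `"NH2"`.
#' @param s2,s3,s6 logical sulfation flags (2-O on the uronic acid,
#'   3-O and 6-O on the glucosamine).
#' @return An [HSDisaccharide-class] object.
#' @examples
#' HSDisaccharide("IdoA", "NS", s2 = TRUE, s6 = TRUE)
#' @export
HSDisaccharide <- function(epimer, nstate, s2 = FALSE, s3 = FALSE,
                           s6 = FALSE) {
    new("HSDisaccharide", epimer = epimer, nstate = nstate,
        s2 = as.logical(s2), s3 = as.logical(s3), s6 = as.logical(s6))
}

#' HSOligo: an ordered HS oligosaccharide
#'
#' An oligosaccharide of one or more disaccharide units, ordered from the
#' non-reducing to the reducing end. Unit order is preserved through every
#' encoding and translation round trip.
#'
#' @slot id single character label.
#' @slot units list of [HSDisaccharide-class] objects.
#' @export
setClass("HSOligo", representation(id = "character", units = "list"))

setValidity("HSOligo", function(object) {
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        return("'id' must be a single non-empty string")
    if (length(object@units) < 1L)
        return("an oligo must contain at least one disaccharide")
    ok <- vapply(object@units, is, logical(1), class2 = "HSDisaccharide")
    if (!all(ok))
        return("all units must be HSDisaccharide objects")
    TRUE
})

#' Construct an HSOligo
#'
#' @param id single character label.
#' @param units list of [HSDisaccharide-class] objects, non-reducing to
#'   reducing end.
#' @return An [HSOligo-class] object.
#' @export
HSOligo <- function(id, units) {
    if (is(units, "HSDisaccharide")) units <- list(units)
    new("HSOligo", id = as.character(id), units = units)
}

#' AlphabetMap: disaccharide codes as pseudo-amino-acid letters
#'
#' A bijection between 11-digit disaccharide code strings and single
#' letters of the standard 20-letter amino-acid alphabet, so that HS
#' oligosaccharides can be fed through protein sequence-alignment
#' machinery. Codes are sorted lexicographically and assigned letters in a
#' fixed order, making the map deterministic for a given set of oligos.
#'
#' @slot codes character vector of 11-digit codes, lexicographically
#'   sorted.
#' @slot letters character vector of the same length, single letters.
#' @export
setClass("AlphabetMap",
    representation(codes = "character", letters = "character"))

setValidity("AlphabetMap", function(object) {
    msg <- character()
    if (length(object@codes) != length(object@letters))
        msg <- c(msg, "'codes' and 'letters' must have equal length")
    if (anyDuplicated(object@codes))
        msg <- c(msg, "'codes' must be unique")
    if (anyDuplicated(object@letters))
        msg <- c(msg, "'letters' must be unique")
    if (is.unsorted(object@codes, strictly = TRUE) &&
        length(object@codes) > 1L)
        msg <- c(msg, "'codes' must be lexicographically sorted")
    if (length(object@codes) > 20L)
        msg <- c(msg, "at most 20 disaccharide types are representable")
    if (length(msg)) msg else TRUE
})

#' WeightedMSF: an IC50-weighted aligned sequence set
#'
#' A multiple sequence file in which each oligo's pseudo-amino-acid
#' sequence appears with an integer copy count proportional to its
#' inhibition potency (reference / IC50), so that stronger binders
#' dominate the downstream position weight matrix.
#'
#' @slot ids oligo labels.
#' @slot aligned equal-length aligned pseudo-sequences; `-` marks gaps.
#' @slot copies integer copy counts, all `>= 1`.
#' @slot alphabet the [AlphabetMap-class] the letters are written in.
#' @export
setClass("WeightedMSF",
    representation(ids = "character", aligned = "character",
                   copies = "integer", alphabet = "AlphabetMap"))

setValidity("WeightedMSF", function(object) {
    msg <- character()
    n <- length(object@ids)
    if (length(object@aligned) != n || length(object@copies) != n)
        msg <- c(msg, "'ids', 'aligned' and 'copies' lengths differ")
    if (n > 0L && length(unique(nchar(object@aligned))) != 1L)
        msg <- c(msg, "aligned sequences must have equal length")
    if (n > 0L && any(object@copies < 1L))
        msg <- c(msg, "copy counts must be >= 1")
    if (length(msg)) msg else TRUE
})

#' PositionWeightMatrix: per-column letter frequencies and information
#'
#' Column-wise letter frequencies of a (copy-weighted) aligned sequence
#' set, with per-column Shannon information content in bits relative to a
#' uniform background over the alphabet, and the per-column gap fraction.
#' Frequencies are taken over non-gap mass, so each informative column
#' sums to 1; all-gap columns carry zero frequency and are flagged.
#'
#' @slot freq K x L matrix, rows named by alphabet letters, columns by
#'   position; each non-degenerate column sums to 1.
#' @slot info numeric length-L information content (bits), in
#'   `[0, log2(K)]`.
#' @slot gapFraction numeric length-L copy-weighted gap fraction.
#' @slot allGap logical length-L flag for columns with no non-gap mass.
#' @slot alphabet the [AlphabetMap-class] the rows refer to.
#' @export
setClass("PositionWeightMatrix",
    representation(freq = "matrix", info = "numeric",
                   gapFraction = "numeric", allGap = "logical",
                   alphabet = "AlphabetMap"))

setValidity("PositionWeightMatrix", function(object) {
    msg <- character()
    L <- ncol(object@freq)
    if (length(object@info) != L || length(object@gapFraction) != L ||
        length(object@allGap) != L)
        msg <- c(msg, "'info', 'gapFraction' and 'allGap' must match ncol(freq)")
    cs <- colSums(object@freq)
    if (L > 0L && any(abs(cs - ifelse(object@allGap, 0, 1)) > 1e-8))
        msg <- c(msg, "column frequencies must sum to 1 (0 for all-gap columns)")
    K <- nrow(object@freq)
    if (L > 0L && K > 0L &&
        any(object@info < -1e-8 | object@info > log2(K) + 1e-8))
        msg <- c(msg, "information content must lie in [0, log2(K)]")
    if (length(msg)) msg else TRUE
})

#' HSLogo: a position weight matrix back-translated to HS codes
#'
#' The epitope description in the HS coding system: per column, each
#' 11-digit disaccharide code with its frequency and its scaled logo
#' height (frequency times column information), so that heights per
#' column sum to the column's information content.
#'
#' @slot freq K x L matrix with 11-digit code rownames.
#' @slot heights K x L matrix; `heights = freq * rep(info, each = K)`.
#' @slot info numeric length-L information content (bits).
#' @slot gapFraction numeric length-L gap fraction.
#' @export
setClass("HSLogo",
    representation(freq = "matrix", heights = "matrix", info = "numeric",
                   gapFraction = "numeric"))

#' MFIExperiment: scFv x population binding intensities
#'
#' Mean fluorescence intensities of an scFv panel across cell populations
#' with replicates, wrapped over a [SummarizedExperiment]: rows are scFvs,
#' columns are population x replicate samples (`colData` columns
#' `population` and `replicate`), and the single assay `mfi` holds the
#' non-negative intensities. The designated negative-control scFv (an
#' antibody with no known HS epitope) is recorded in the metadata.
#'
#' @slot controlScfv label of the negative-control scFv, or `NA` when none
#'   is designated.
#' @slot normalization `"raw"`, `"subtract"` or `"ratio"`.
#' @export
setClass("MFIExperiment",
    contains = "SummarizedExperiment",
    representation(controlScfv = "character", normalization = "character"))

setValidity("MFIExperiment", function(object) {
    msg <- character()
    if (!"mfi" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'mfi' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("population", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must have 'population' and 'replicate'")
    else {
        a <- SummarizedExperiment::assay(object, "mfi")
        if (any(a < 0, na.rm = TRUE))
            msg <- c(msg, "intensities must be non-negative")
    }
    if (length(object@normalization) != 1L ||
        !object@normalization %in% c("raw", "subtract", "ratio"))
        msg <- c(msg, "'normalization' must be raw, subtract or ratio")
    if (length(msg)) msg else TRUE
})

#' GlycotypeProfiles: summarized per-population binding profiles
#'
#' One row per population, one column per scFv, each entry the
#' summarized, normalized binding of that scFv to that population. A
#' population's row is its glycotype.
#'
#' @slot values populations x scFvs numeric matrix.
#' @slot normalization `"raw"`, `"percentile"`, `"subtract"` or `"ratio"`.
#' @export
setClass("GlycotypeProfiles",
    representation(values = "matrix", normalization = "character"))

#' GateResult: high/low fractionation of per-cell intensities
#'
#' Labels cells as `high` (top fraction by intensity), `low` (bottom
#' fraction) or `ungated`, in the cells' input order.
#'
#' @slot labels factor with levels high/low/ungated, one per cell.
#' @slot thresholds named numeric: `highMin` (smallest high value) and
#'   `lowMax` (largest low value); `NA` when the class is empty.
#' @slot fractions named numeric: requested `high` and `low` fractions.
#' @export
setClass("GateResult",
    representation(labels = "factor", thresholds = "numeric",
                   fractions = "numeric"))

#' SignatureSet: an up/down gene signature with housekeeping genes
#'
#' @slot up,down disjoint character vectors of gene labels.
#' @slot housekeeping character vector used for per-cell normalization.
#' @export
setClass("SignatureSet",
    representation(up = "character", down = "character",
                   housekeeping = "character"))

setValidity("SignatureSet", function(object) {
    if (length(intersect(object@up, object@down)))
        return("'up' and 'down' gene sets must be disjoint")
    TRUE
})

#' Construct a SignatureSet
#'
#' @param up,down disjoint character vectors of gene labels.
#' @param housekeeping character vector of housekeeping gene labels.
#' @return A [SignatureSet-class].
#' @export
SignatureSet <- function(up, down, housekeeping = character()) {
    new("SignatureSet", up = as.character(up), down = as.character(down),
        housekeeping = as.character(housekeeping))
}
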