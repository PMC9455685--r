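# Gene-signature scoring: the signed log-p statistic fed to preranked
# GSEA, top-N up/down lineage signatures, per-cell module scores with
# housekeeping normalization, and efficiency-corrected (Pfaffl) qPCR
# quantification.

#' Signed log-p enrichment score for preranked GSEA
#'
#' `-log10(p_adj) * sign(log2FC)`: genes are ranked by how significant
#' they are, with the sign of the fold-change carrying the direction.
#' `p_adj = 1` maps to 0, and `sign(0) = 0`. Values below `floor`
#' (default `1e-300`) are clamped to the floor and flagged in the
#' `"clamped"` attribute; non-positive p-values are a domain error unless
#' `clampZero = TRUE`, in which case they are clamped too.
#'
#' @param padj numeric adjusted p-values in `(0, 1]`.
#' @param log2fc numeric log2 fold-changes (only the sign is used).
#' @param floor smallest representable p-value before clamping.
#' @param clampZero treat `padj <= 0` as below-floor rather than erroring.
#' @return Numeric scores, with a logical `"clamped"` attribute.
#' @examples
#' signedLogPScore(c(0.01, 1), c(2, -3))  #  2  0
#' @export
signedLogPScore <- function(padj, log2fc, floor = 1e-300,
                            clampZero = FALSE) {
    stopifnot(is.numeric(padj), is.numeric(log2fc),
              length(padj) == length(log2fc))
    if (any(padj > 1, na.rm = TRUE))
        stop("adjusted p-values must be <= 1")
    nonpos <- !is.na(padj) & padj <= 0
    if (any(nonpos) && !clampZero)
        stop("adjusted p-values must be > 0 (set clampZero = TRUE to clamp)")
    clamped <- nonpos | (!is.na(padj) & padj < floor)
    p <- pmax(padj, floor)
    score <- -log10(p) * sign(log2fc)
    attr(score, "clamped") <- clamped
    score
}

#' Select the top up- and downregulated genes
#'
#' Ranks genes by the signed log-p score and keeps the `n` strongest in
#' each direction (largest positive scores up, most negative down). Ties
#' at the cutoff are broken by lexicographic gene label, so the selection
#' does not depend on input row order.
#'
#' @param table data.frame with columns `gene`, `padj` and `log2fc`, or
#'   `gene` and `score`.
#' @param n signature size per direction (default 20).
#' @param housekeeping optional housekeeping genes to carry along.
#' @return A [SignatureSet-class].
#' @export
selectTopGenes <- function(table, n = 20, housekeeping = character()) {
    stopifnot(is.data.frame(table), "gene" %in% colnames(table))
    if (!"score" %in% colnames(table)) {
        stopifnot(all(c("padj", "log2fc") %in% colnames(table)))
        table$score <- as.numeric(signedLogPScore(table$padj, table$log2fc))
    }
    gene <- as.character(table$gene)
    score <- table$score
    pick <- function(direction) {
        sel <- if (direction == "up") score > 0 else score < 0
        if (sum(sel) < n)
            stop(sprintf(
                "only %d %sregulated genes available, %d requested",
                sum(sel), direction, n))
        g <- gene[sel]
        s <- abs(score[sel])
        g[order(-s, g)][seq_len(n)]
    }
    SignatureSet(up = pick("up"), down = pick("down"),
                 housekeeping = housekeeping)
}

#' @describeIn SignatureSet-class the upregulated gene labels.
#' @param x a `SignatureSet`.
#' @export
upGenes <- function(x) { stopifnot(is(x, "SignatureSet")); x@up }

#' @describeIn SignatureSet-class the downregulated gene labels.
#' @export
downGenes <- function(x) { stopifnot(is(x, "SignatureSet")); x@down }

#' @describeIn SignatureSet-class the housekeeping gene labels.
#' @export
housekeepingGenes <- function(x) {
    stopifnot(is(x, "SignatureSet")); x@housekeeping
}

setMethod("show", "SignatureSet", function(object) {
    cat(sprintf("SignatureSet: %d up / %d down / %d housekeeping genes\n",
                length(object@up), length(object@down),
                length(object@housekeeping)))
})

#' Per-cell lineage module score
#'
#' Each cell's expression is divided by that cell's mean housekeeping
#' expression, and the score is the mean of the normalized up-signature
#' genes minus the mean of the normalized down-signature genes. Because
#' the housekeeping normalization cancels any per-cell scale factor, the
#' score is invariant to multiplying a cell's whole profile by a positive
#' constant. Cells with zero mean housekeeping expression get `NA` and
#' are flagged.
#'
#' @param expr genes x cells numeric matrix with gene rownames (cell
#'   colnames optional).
#' @param signature a [SignatureSet-class] with non-empty housekeeping
#'   genes; all signature and housekeeping genes must be rows of `expr`.
#' @param zscale z-scale the scores across cells before returning
#'   (default `FALSE`; convenient when mapping scores onto an
#'   embedding).
#' @return Numeric per-cell scores (named when `expr` has colnames), with
#'   a logical `"undefined"` attribute marking zero-housekeeping cells.
#' @export
moduleScore <- function(expr, signature, zscale = FALSE) {
    stopifnot(is.matrix(expr), is.numeric(expr),
              is(signature, "SignatureSet"))
    if (!length(signature@housekeeping))
        stop("housekeeping genes are required for normalization")
    needed <- c(signature@up, signature@down, signature@housekeeping)
    missing <- setdiff(needed, rownames(expr))
    if (length(missing))
        stop("gene(s) absent from the expression matrix: ",
             paste(missing, collapse = ", "))
    hk <- colMeans(expr[signature@housekeeping, , drop = FALSE])
    undefined <- hk == 0
    hk[undefined] <- NA_real_
    up <- colMeans(expr[signature@up, , drop = FALSE]) / hk
    down <- colMeans(expr[signature@down, , drop = FALSE]) / hk
    score <- up - down
    if (zscale)
        score <- (score - mean(score, na.rm = TRUE)) /
            stats::sd(score, na.rm = TRUE)
    attr(score, "undefined") <- undefined
    score
}

#' Efficiency-corrected qPCR expression ratio (Pfaffl model)
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, where each `dCt` is
#' `Ct(control) - Ct(sample)` and the amplification efficiencies lie in
#' `(1, 2]` (2 = perfect doubling per cycle). With both efficiencies at
#' 2 the ratio reduces to the familiar `2^ddCt` form.
#'
#' @param eTarget,eRef amplification efficiencies in `(1, 2]`.
#' @param dCtTarget,dCtRef `Ct(control) - Ct(sample)` for the target and
#'   the reference (housekeeping, e.g. Gapdh) gene.
#' @return Numeric relative expression ratio(s).
#' @examples
#' pfafflRatio(2, 1, 2, 0)  # 2
#' @export
pfafflRatio <- function(eTarget, dCtTarget, eRef, dCtRef) {
    stopifnot(is.numeric(eTarget), is.numeric(eRef),
              is.numeric(dCtTarget), is.numeric(dCtRef))
    if (any(eTarget <= 1 | eTarget > 2) || any(eRef <= 1 | eRef > 2))
        stop("amplification efficiencies must lie in (1, 2]")
    if (any(!is.finite(dCtTarget)) || any(!is.finite(dCtRef)))
        stop("delta-Ct values must be finite")
    eTarget^dCtTarget / eRef^dCtRef
}
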