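# Seeded generators for every input the analysis consumes: oligo panels
# with a planted epitope and IC50s simulated from an inverse model of
# competitive inhibition, MFI tables and bimodal cell-level intensities,
# and expression matrices with planted lineage groups. Defaults mirror
# the scale of the study's panels (12 oligos of 4-10 disaccharides, 8 HS
# scFvs plus one negative control, n = 3 replicates). Each function
# seeds R's RNG, so identical arguments give identical outputs.

#' Simulate an oligo panel with a planted epitope
#'
#' Draws a pool of `nTypes` distinct disaccharide types from the
#' 48-state space, plants a consensus epitope of `epitopeLength` units
#' into a random window of each carrier oligo (each oligo carries the
#' epitope with probability `carrierProb`; each planted site is replaced
#' by a random pool type with probability `corruptionProb`), and fills
#' the remaining positions uniformly from the pool. The defaults emulate
#' a panel of oligosaccharides of defined sequence, so sequence-level
#' corruption is off and noise enters downstream through the IC50 model.
#'
#' @param nOligos panel size (default 12).
#' @param lengthRange integer range of oligo lengths in disaccharides.
#' @param epitopeLength planted consensus length; must not exceed
#'   `min(lengthRange)`.
#' @param nTypes disaccharide type pool size (at most 20).
#' @param carrierProb probability an oligo carries the epitope.
#' @param corruptionProb per-site corruption probability in carriers.
#' @param seed integer RNG seed.
#' @return A list with `oligos` (list of [HSOligo-class]), `map`
#'   ([AlphabetMap-class] over the full pool), `consensusCodes`,
#'   `consensusLetters`, `truthPWM` (one-hot
#'   [PositionWeightMatrix-class] of the planted epitope) and `carriers`
#'   (logical).
#' @export
simulateOligoPanel <- function(nOligos = 12, lengthRange = c(4, 10),
                               epitopeLength = 4, nTypes = 12,
                               carrierProb = 1, corruptionProb = 0,
                               seed = 1) {
    stopifnot(nOligos >= 1, nTypes >= 2, nTypes <= 20,
              length(lengthRange) == 2L, lengthRange[1] >= 1,
              lengthRange[1] <= lengthRange[2])
    if (epitopeLength > lengthRange[1])
        stop("epitopeLength (", epitopeLength,
             ") exceeds the minimum oligo length (", lengthRange[1], ")")
    set.seed(seed)
    all48 <- vapply(allDisaccharides(), encodeDisaccharide, character(1))
    poolCodes <- sample(all48, nTypes)
    map <- alphabetFromCodes(poolCodes)
    letters <- alphabetLetters(map)
    consensus <- sample(letters, epitopeLength, replace = TRUE)
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nOligos,
                   replace = TRUE)
    carriers <- stats::runif(nOligos) < carrierProb
    oligos <- vector("list", nOligos)
    for (i in seq_len(nOligos)) {
        s <- sample(letters, lens[i], replace = TRUE)
        if (carriers[i]) {
            start <- sample.int(lens[i] - epitopeLength + 1L, 1L)
            ep <- consensus
            corrupt <- stats::runif(epitopeLength) < corruptionProb
            if (any(corrupt))
                ep[corrupt] <- sample(letters, sum(corrupt), replace = TRUE)
            s[start:(start + epitopeLength - 1L)] <- ep
        }
        code <- paste(.code_for_letter(map, s), collapse = "")
        oligos[[i]] <- decodeOligo(code, sprintf("oligo%02d", i))
    }
    K <- length(letters)
    freq <- matrix(0, K, epitopeLength,
                   dimnames = list(letters, NULL))
    freq[cbind(match(consensus, letters), seq_len(epitopeLength))] <- 1
    truthPWM <- new("PositionWeightMatrix", freq = freq,
                    info = rep(log2(K), epitopeLength),
                    gapFraction = numeric(epitopeLength),
                    allGap = logical(epitopeLength), alphabet = map)
    list(oligos = oligos, map = map,
         consensusCodes = .code_for_letter(map, consensus),
         consensusLetters = consensus, truthPWM = truthPWM,
         carriers = carriers)
}

#' Simulate IC50 values from a ground-truth epitope
#'
#' The inverse model of competitive inhibition used for testing: each
#' oligo is scored against the ground-truth position weight matrix with
#' [scoreOligo()], the score is mapped through a decreasing
#' affine-logistic link onto `icRange` (best possible match ~ 1 ug/ml,
#' no match ~ 100 ug/ml), multiplied by lognormal noise `exp(sigma * Z)`
#' and clamped to `clampRange`. With `sigma = 0` the mapping is strictly
#' decreasing in the match score, so equal scores give equal IC50s.
#'
#' @param oligos list of [HSOligo-class].
#' @param truthPWM the planted [PositionWeightMatrix-class].
#' @param map alphabet map covering the oligos; defaults to the truth
#'   matrix's map.
#' @param sigma lognormal noise on the log scale (default 0.25).
#' @param icRange noiseless IC50 range, low to high (default `c(1, 100)`).
#' @param clampRange post-noise clamp (default `c(0.5, 200)`).
#' @param steepness logistic steepness of the score-to-IC50 link.
#' @param pseudocount passed to [scoreOligo()].
#' @param seed integer RNG seed.
#' @return A data.frame with columns `oligo_id` and `ic50` (ug/ml).
#' @export
simulateIC50 <- function(oligos, truthPWM, map = truthPWM@alphabet,
                         sigma = 0.25, icRange = c(1, 100),
                         clampRange = c(0.5, 200), steepness = 12,
                         pseudocount = 1e-3, seed = 1) {
    stopifnot(is(truthPWM, "PositionWeightMatrix"), length(oligos) >= 1L)
    set.seed(seed)
    scores <- vapply(oligos, function(o)
        scoreOligo(truthPWM, o, map, pseudocount), numeric(1))
    K <- nrow(truthPWM@freq)
    L <- ncol(truthPWM@freq)
    sMax <- L * log2(K)
    sMin <- L * log2(pseudocount * K)
    u <- pmin(1, pmax(0, (scores - sMin) / (sMax - sMin)))
    ic <- icRange[1] + diff(icRange) / (1 + exp(steepness * (u - 0.5)))
    if (sigma > 0)
        ic <- ic * exp(sigma * stats::rnorm(length(ic)))
    ic <- pmin(clampRange[2], pmax(clampRange[1], ic))
    data.frame(oligo_id = vapply(oligos, oligoId, character(1)),
               ic50 = ic, row.names = NULL)
}

#' Simulate an scFv x population MFI table with replicates
#'
#' Population-by-scFv mean intensities are drawn lognormally, replicate
#' values multiply the mean by `exp(replicateSigma * Z)`, and the
#' negative-control scFv is generated at a separate (background) level.
#' With `replicateSigma = 0` replicates equal their population means.
#'
#' @param nPopulations number of cell populations (default 6).
#' @param nScfvs number of HS-specific scFvs (default 8).
#' @param nReplicates replicates per population and scFv (default 3).
#' @param meanlog,sdlogBetween lognormal parameters of the HS scFv
#'   population means.
#' @param replicateSigma lognormal replicate noise (log scale).
#' @param controlMeanlog,controlSdlog lognormal parameters of the
#'   control scFv population means.
#' @param control control scFv label.
#' @param seed integer RNG seed.
#' @return An [MFIExperiment-class].
#' @export
simulateMFITable <- function(nPopulations = 6, nScfvs = 8,
                             nReplicates = 3, meanlog = log(1000),
                             sdlogBetween = 0.8, replicateSigma = 0.2,
                             controlMeanlog = log(100),
                             controlSdlog = 0.1, control = "MPB49",
                             seed = 1) {
    stopifnot(nPopulations >= 1, nScfvs >= 1, nReplicates >= 1)
    set.seed(seed)
    pops <- sprintf("pop%02d", seq_len(nPopulations))
    scfvs <- c(sprintf("scFv%02d", seq_len(nScfvs)), control)
    rows <- list()
    for (p in pops) {
        for (s in scfvs) {
            mu <- if (s == control)
                stats::rlnorm(1, controlMeanlog, controlSdlog)
            else stats::rlnorm(1, meanlog, sdlogBetween)
            vals <- mu * exp(replicateSigma * stats::rnorm(nReplicates))
            rows[[length(rows) + 1L]] <- data.frame(
                population = p, scfv = s,
                replicate = seq_len(nReplicates), mfi = vals)
        }
    }
    MFIExperiment(do.call(rbind, rows), control = control)
}

#' Simulate per-cell MFI values from a two-component mixture
#'
#' Cell-level intensities from a two-component lognormal mixture -- the
#' bimodal single-channel signal that high/low fractionation gates sort
#' on. Component membership is returned for recovery tests.
#'
#' @param nCells number of cells (default 1000).
#' @param weights mixture weights (sum to 1).
#' @param meanlog,sdlog per-component lognormal parameters.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `mfi` and `component` (1 = low,
#'   2 = high).
#' @export
simulateCellMFI <- function(nCells = 1000, weights = c(0.5, 0.5),
                            meanlog = c(log(100), log(1000)),
                            sdlog = c(0.4, 0.4), seed = 1) {
    stopifnot(nCells >= 1, length(weights) == 2L,
              abs(sum(weights) - 1) < 1e-8,
              length(meanlog) == 2L, length(sdlog) == 2L)
    set.seed(seed)
    component <- sample(1:2, nCells, replace = TRUE, prob = weights)
    mfi <- stats::rlnorm(nCells, meanlog[component], sdlog[component])
    data.frame(mfi = mfi, component = component)
}

#' Simulate a DE table and expression matrix with planted lineage groups
#'
#' Generates a genes x cells lognormal expression matrix with two cell
#' groups (erythroid-progenitor-like and megakaryocyte-progenitor-like),
#' `nUp` genes shifted up and `nDown` genes shifted down in the first
#' group by `effectLog2fc` log2 units, background genes with no shift,
#' and flat housekeeping genes. The differential-expression table is then
#' computed from the simulated matrix itself (per-gene Welch t-test on
#' log2 values, Benjamini-Hochberg adjustment, observed log2
#' fold-change), so its p-values and fold-changes are consistent with the
#' planted directions by construction.
#'
#' @param nCellsPerGroup cells per group (default 100).
#' @param nUp,nDown planted signature sizes (default 20 each).
#' @param nBackground unshifted genes (default 160).
#' @param nHousekeeping flat normalization genes (default 5).
#' @param effectLog2fc planted group shift in log2 units (default 2;
#'   0 gives a null dataset).
#' @param baseMeanlog baseline lognormal mean (log scale).
#' @param cellSdlog per-cell lognormal noise (log scale).
#' @param housekeepingMeanlog housekeeping expression level (log scale).
#' @param seed integer RNG seed.
#' @return A list with `expr` (genes x cells matrix), `groups` (factor
#'   `"ERP"`/`"MkP"` per cell), `deTable` (data.frame `gene`, `log2fc`,
#'   `padj`) and `truth` (the planted [SignatureSet-class]).
#' @export
simulateDEAndExpression <- function(nCellsPerGroup = 100, nUp = 20,
                                    nDown = 20, nBackground = 160,
                                    nHousekeeping = 5, effectLog2fc = 2,
                                    baseMeanlog = log(10),
                                    cellSdlog = 0.5,
                                    housekeepingMeanlog = log(50),
                                    seed = 1) {
    stopifnot(nCellsPerGroup >= 2, nUp >= 1, nDown >= 1,
              nHousekeeping >= 1)
    set.seed(seed)
    genes <- c(sprintf("up%03d", seq_len(nUp)),
               sprintf("dn%03d", seq_len(nDown)),
               sprintf("bg%03d", seq_len(nBackground)),
               sprintf("hk%03d", seq_len(nHousekeeping)))
    shift <- c(rep(1, nUp), rep(-1, nDown), rep(0, nBackground),
               rep(0, nHousekeeping)) * effectLog2fc * log(2) / 2
    base <- c(rep(baseMeanlog, nUp + nDown + nBackground),
              rep(housekeepingMeanlog, nHousekeeping))
    nCells <- 2L * nCellsPerGroup
    groups <- factor(rep(c("ERP", "MkP"), each = nCellsPerGroup),
                     levels = c("ERP", "MkP"))
    groupSign <- ifelse(groups == "ERP", 1, -1)
    expr <- matrix(NA_real_, length(genes), nCells,
                   dimnames = list(genes,
                                   sprintf("cell%03d", seq_len(nCells))))
    for (g in seq_along(genes)) {
        mu <- base[g] + shift[g] * groupSign
        expr[g, ] <- stats::rlnorm(nCells, mu, cellSdlog)
    }
    lg <- log2(expr)
    a <- groups == "ERP"
    pvals <- vapply(seq_along(genes), function(g)
        stats::t.test(lg[g, a], lg[g, !a])$p.value, numeric(1))
    deTable <- data.frame(
        gene = genes,
        log2fc = rowMeans(lg[, a, drop = FALSE]) -
                 rowMeans(lg[, !a, drop = FALSE]),
        padj = stats::p.adjust(pvals, method = "BH"),
        row.names = NULL)
    truth <- SignatureSet(up = genes[seq_len(nUp)],
                          down = genes[nUp + seq_len(nDown)],
                          housekeeping = genes[nUp + nDown + nBackground +
                                               seq_len(nHousekeeping)])
    list(expr = expr, groups = groups, deTable = deTable, truth = truth)
}
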