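# Glycotype analytics: summarizing scFv x population MFI tables into
# cellular glycotypes, percentile heatmaps, control-relative values,
# high/low fractionation gates, binding distributions and glycotype
# dissimilarity.

#' Construct an MFIExperiment from a long-format table
#'
#' @param data data.frame with columns `population`, `scfv`, `replicate`
#'   (optional, defaults to 1) and `mfi` (non-negative).
#' @param control label of the negative-control scFv (an antibody with no
#'   known HS epitope); `NA` when none is present. The default follows
#'   the conventional control clone name `"MPB49"` and is only enforced
#'   when control-relative operations are requested.
#' @return An [MFIExperiment-class] with scFvs as rows and
#'   population-replicate samples as columns.
#' @export
MFIExperiment <- function(data, control = "MPB49") {
    stopifnot(is.data.frame(data),
              all(c("population", "scfv", "mfi") %in% colnames(data)))
    if (!"replicate" %in% colnames(data)) data$replicate <- 1L
    if (any(!is.finite(data$mfi)) || any(data$mfi < 0))
        stop("MFI values must be finite and non-negative")
    scfvs <- unique(as.character(data$scfv))
    sample <- paste(data$population, data$replicate, sep = ".")
    samples <- unique(sample)
    m <- matrix(NA_real_, length(scfvs), length(samples),
                dimnames = list(scfvs, samples))
    m[cbind(match(as.character(data$scfv), scfvs),
            match(sample, samples))] <- data$mfi
    first <- !duplicated(sample)
    cd <- S4Vectors::DataFrame(
        population = as.character(data$population)[first],
        replicate = data$replicate[first], row.names = samples)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(mfi = m), colData = cd)
    new("MFIExperiment", se, controlScfv = as.character(control),
        normalization = "raw")
}

#' @describeIn MFIExperiment-class scFv labels (row names).
#' @param x an `MFIExperiment`.
#' @export
scfvNames <- function(x) { stopifnot(is(x, "MFIExperiment")); rownames(x) }

#' @describeIn MFIExperiment-class distinct population labels, in first
#'   appearance order.
#' @export
populationNames <- function(x) {
    stopifnot(is(x, "MFIExperiment"))
    unique(SummarizedExperiment::colData(x)$population)
}

#' @describeIn MFIExperiment-class the designated negative-control scFv.
#' @export
controlScfv <- function(x) {
    stopifnot(is(x, "MFIExperiment")); x@controlScfv
}

.mfi_matrix <- function(x) SummarizedExperiment::assay(x, "mfi")

# replicate-mean MFI matrix, scFvs x populations (population order =
# first appearance)
.replicate_means <- function(x, geometric = FALSE) {
    pops <- populationNames(x)
    cd <- SummarizedExperiment::colData(x)
    m <- .mfi_matrix(x)
    out <- vapply(pops, function(p) {
        sub <- m[, cd$population == p, drop = FALSE]
        if (geometric) exp(rowMeans(log(sub), na.rm = TRUE))
        else rowMeans(sub, na.rm = TRUE)
    }, numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), pops))
    out
}

setMethod("show", "MFIExperiment", function(object) {
    cat(sprintf(
        "MFIExperiment: %d scFvs x %d populations (%d samples), %s\n",
        nrow(object), length(populationNames(object)), ncol(object),
        if (is.na(object@controlScfv)) "no control"
        else paste0("control ", object@controlScfv)))
    cat("  normalization:", object@normalization, "\n")
})

#' Mean and SD of MFI per population and scFv
#'
#' Replicates are summarized by the arithmetic mean and the sample
#' standard deviation (n - 1 denominator). Single-replicate cells get
#' `sd = 0` and are flagged.
#'
#' @param x an [MFIExperiment-class].
#' @return A data.frame with columns `population`, `scfv`, `n`, `mean`,
#'   `sd` and `singleReplicate`.
#' @export
summarizeMFI <- function(x) {
    stopifnot(is(x, "MFIExperiment"))
    cd <- SummarizedExperiment::colData(x)
    m <- .mfi_matrix(x)
    pops <- populationNames(x)
    rows <- list()
    for (p in pops) {
        sub <- m[, cd$population == p, drop = FALSE]
        for (s in rownames(m)) {
            v <- sub[s, ]
            v <- v[!is.na(v)]
            n <- length(v)
            rows[[length(rows) + 1L]] <- data.frame(
                population = p, scfv = s, n = n,
                mean = if (n) mean(v) else NA_real_,
                sd = if (n > 1L) stats::sd(v) else 0,
                singleReplicate = n == 1L)
        }
    }
    do.call(rbind, rows)
}

.percentile_ranks <- function(v) {
    # average-rank percentiles with 0/100 endpoints
    n <- length(v)
    (rank(v, ties.method = "average") - 1) / (n - 1) * 100
}

#' Per-scFv MFI percentiles across populations
#'
#' Within each scFv, MFIs are converted to percentile ranks across
#' populations (average ranks for ties, endpoints 0 and 100), making the
#' heatmap invariant to any strictly increasing transform of the
#' intensities. With `perReplicate = TRUE` (default) percentiles are
#' computed per replicate and then averaged; otherwise they are computed
#' on replicate means.
#'
#' @param x an [MFIExperiment-class] with at least two populations.
#' @param perReplicate compute per replicate, then average.
#' @return A populations x scFvs matrix of percentiles in `[0, 100]`.
#' @export
mfiPercentile <- function(x, perReplicate = TRUE) {
    stopifnot(is(x, "MFIExperiment"))
    pops <- populationNames(x)
    if (length(pops) < 2L)
        stop("percentiles need at least two populations")
    cd <- SummarizedExperiment::colData(x)
    m <- .mfi_matrix(x)
    out <- matrix(NA_real_, length(pops), nrow(m),
                  dimnames = list(pops, rownames(m)))
    for (s in rownames(m)) {
        if (perReplicate) {
            reps <- unique(cd$replicate)
            acc <- matrix(NA_real_, length(pops), length(reps))
            for (k in seq_along(reps)) {
                sel <- cd$replicate == reps[k]
                v <- vapply(pops, function(p) {
                    vv <- m[s, sel & cd$population == p]
                    if (length(vv)) mean(vv, na.rm = TRUE) else NA_real_
                }, numeric(1))
                if (!anyNA(v)) acc[, k] <- .percentile_ranks(v)
            }
            out[, s] <- rowMeans(acc, na.rm = TRUE)
        } else {
            means <- .replicate_means(x)[s, pops]
            out[, s] <- .percentile_ranks(means)
        }
    }
    out
}

#' Control-relative MFI normalization
#'
#' Adjusts every HS scFv value by the matched population's
#' negative-control value (the control's replicate mean in that
#' population). `subtract` clamps at zero (clamped cells are flagged in
#' the metadata); `ratio` divides and requires strictly positive control
#' values. The control row is removed from the result.
#'
#' @param x an [MFIExperiment-class] whose control scFv is present.
#' @param mode `"subtract"` or `"ratio"`.
#' @return A new [MFIExperiment-class] without the control row, with the
#'   normalization recorded; `metadata(x)$clamped` counts clamped values
#'   in subtract mode.
#' @export
controlRelative <- function(x, mode = c("subtract", "ratio")) {
    mode <- match.arg(mode)
    stopifnot(is(x, "MFIExperiment"))
    ctrl <- x@controlScfv
    if (is.na(ctrl) || !ctrl %in% rownames(x))
        stop("control scFv '", ctrl, "' not present in the table")
    cd <- SummarizedExperiment::colData(x)
    m <- .mfi_matrix(x)
    cm <- .replicate_means(x)
    perSample <- cm[ctrl, cd$population]
    keep <- setdiff(rownames(m), ctrl)
    adj <- m[keep, , drop = FALSE]
    nClamped <- 0L
    if (mode == "subtract") {
        adj <- sweep(adj, 2L, perSample, "-")
        nClamped <- sum(adj < 0, na.rm = TRUE)
        adj[adj < 0] <- 0
    } else {
        if (any(perSample <= 0))
            stop("ratio mode requires strictly positive control values")
        adj <- sweep(adj, 2L, perSample, "/")
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(mfi = adj), colData = cd)
    out <- new("MFIExperiment", se, controlScfv = NA_character_,
               normalization = mode)
    S4Vectors::metadata(out)$clamped <- nClamped
    out
}

#' High/low fractionation gate on per-cell intensities
#'
#' Sorts cells by intensity (descending, ties kept in stable input
#' order), labels the top `round(fHigh * n)` cells `high` and the bottom
#' `round(fLow * n)` cells `low` (rounding half away from zero), and
#' leaves the remainder `ungated` -- the in-silico analogue of sorting a
#' binding-high and binding-low fraction on one scFv channel.
#'
#' @param values numeric per-cell intensities, `length >= 2`.
#' @param fHigh,fLow fractions in `(0, 1]` with `fHigh + fLow <= 1`.
#' @return A [GateResult-class] with labels in input order.
#' @examples
#' g <- gateHighLow(stats::rlnorm(1000), 0.5, 0.5)
#' table(gateLabels(g))
#' @export
gateHighLow <- function(values, fHigh = 0.5, fLow = 0.5) {
    stopifnot(is.numeric(values), all(is.finite(values)))
    n <- length(values)
    if (n < 2L) stop("at least two cells are required")
    if (fHigh <= 0 || fLow <= 0) stop("fractions must be positive")
    if (fHigh + fLow > 1 + 1e-12)
        stop("fHigh + fLow must not exceed 1")
    nHigh <- as.integer(floor(fHigh * n + 0.5))
    nLow <- min(as.integer(floor(fLow * n + 0.5)), n - nHigh)
    ord <- order(-values)  # stable: ties keep input order
    labels <- rep("ungated", n)
    labels[ord[seq_len(nHigh)]] <- "high"
    if (nLow > 0L)
        labels[rev(ord)[seq_len(nLow)]] <- "low"
    thresholds <- c(
        highMin = if (nHigh) min(values[labels == "high"]) else NA_real_,
        lowMax = if (nLow) max(values[labels == "low"]) else NA_real_)
    new("GateResult",
        labels = factor(labels, levels = c("high", "low", "ungated")),
        thresholds = thresholds, fractions = c(high = fHigh, low = fLow))
}

#' @describeIn GateResult-class per-cell labels in input order.
#' @param x a `GateResult`.
#' @export
gateLabels <- function(x) { stopifnot(is(x, "GateResult")); x@labels }

#' @describeIn GateResult-class the realized gate thresholds.
#' @export
gateThresholds <- function(x) { stopifnot(is(x, "GateResult")); x@thresholds }

setMethod("show", "GateResult", function(object) {
    tab <- table(object@labels)
    cat(sprintf(
        "GateResult: %d high / %d low / %d ungated (fHigh=%.2f, fLow=%.2f)\n",
        tab[["high"]], tab[["low"]], tab[["ungated"]],
        object@fractions[["high"]], object@fractions[["low"]]))
})

#' Fractional binding distribution across ordered populations
#'
#' For each scFv, the replicate-mean MFI in each listed population is
#' divided by the sum over the listed populations, giving a profile that
#' sums to one -- how an scFv's binding distributes across, e.g., the
#' R1-R4 erythroid maturation fractions. scFvs with zero total signal are
#' returned as `NA` rows with a warning.
#'
#' @param x an [MFIExperiment-class].
#' @param populations character vector of population labels, in display
#'   order; all must exist in `x`.
#' @return An scFvs x populations matrix of fractions.
#' @export
bindingDistribution <- function(x, populations = populationNames(x)) {
    stopifnot(is(x, "MFIExperiment"))
    missing <- setdiff(populations, populationNames(x))
    if (length(missing))
        stop("unknown population(s): ", paste(missing, collapse = ", "))
    means <- .replicate_means(x)[, populations, drop = FALSE]
    tot <- rowSums(means)
    zero <- tot == 0
    if (any(zero))
        warning("all-zero profile for scFv(s): ",
                paste(rownames(means)[zero], collapse = ", "))
    out <- means / tot
    out[zero, ] <- NA_real_
    out
}

#' Summarized glycotype profiles
#'
#' One glycotype per population: the summarized (replicate-mean, or
#' percentile) binding of each scFv in the panel.
#'
#' @param x an [MFIExperiment-class].
#' @param normalization `"raw"` (replicate means; inherits `"subtract"`
#'   or `"ratio"` tags from [controlRelative()]) or `"percentile"`
#'   ([mfiPercentile()] on replicate means).
#' @param geometric use geometric replicate means (raw mode only).
#' @return A [GlycotypeProfiles-class].
#' @export
glycotypeProfiles <- function(x, normalization = c("raw", "percentile"),
                              geometric = FALSE) {
    normalization <- match.arg(normalization)
    stopifnot(is(x, "MFIExperiment"))
    values <- if (normalization == "percentile")
        mfiPercentile(x, perReplicate = FALSE)
    else t(.replicate_means(x, geometric = geometric))
    tag <- if (normalization == "raw") x@normalization else normalization
    new("GlycotypeProfiles", values = values, normalization = tag)
}

#' @describeIn GlycotypeProfiles-class the populations x scFvs value
#'   matrix.
#' @param x a `GlycotypeProfiles`.
#' @export
profileValues <- function(x) {
    stopifnot(is(x, "GlycotypeProfiles")); x@values
}

setMethod("show", "GlycotypeProfiles", function(object) {
    cat(sprintf(
        "GlycotypeProfiles: %d populations x %d scFvs (%s)\n",
        nrow(object@values), ncol(object@values), object@normalization))
})

.profile_dist <- function(m, metric) {
    if (metric == "euclidean") {
        as.matrix(stats::dist(m, method = "euclidean"))
    } else {
        1 - stats::cor(t(m))
    }
}

#' Dissimilarity between glycotype profiles
#'
#' Euclidean or correlation (`1 - Pearson r`) distance between per-scFv
#' binding profiles over the same panel and normalization. Given two
#' profiles, returns one number; given a [GlycotypeProfiles-class],
#' returns the full symmetric matrix.
#'
#' @param a a [GlycotypeProfiles-class], or a named numeric profile.
#' @param b optional second named numeric profile over the same panel.
#' @param metric `"euclidean"` or `"correlation"`.
#' @return A dissimilarity (scalar) or symmetric matrix; zero on the
#'   diagonal.
#' @export
glycotypeDistance <- function(a, b = NULL,
                              metric = c("euclidean", "correlation")) {
    metric <- match.arg(metric)
    if (is(a, "GlycotypeProfiles")) {
        return(.profile_dist(a@values, metric))
    }
    stopifnot(is.numeric(a), is.numeric(b))
    if (is.null(names(a)) || is.null(names(b)) ||
        !identical(sort(names(a)), sort(names(b))))
        stop("profiles must be named over the same scFv panel")
    b <- b[names(a)]
    if (metric == "euclidean") sqrt(sum((a - b)^2))
    else 1 - stats::cor(a, b)
}

#' Average-linkage clustering of glycotype profiles
#'
#' @param x a [GlycotypeProfiles-class].
#' @param metric distance metric, see [glycotypeDistance()].
#' @return An [stats::hclust] tree over populations (deterministic).
#' @export
clusterGlycotypes <- function(x, metric = c("euclidean", "correlation")) {
    metric <- match.arg(metric)
    stopifnot(is(x, "GlycotypeProfiles"))
    if (nrow(x@values) < 2L)
        stop("clustering needs at least two populations")
    d <- stats::as.dist(.profile_dist(x@values, metric))
    stats::hclust(d, method = "average")
}
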