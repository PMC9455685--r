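# Shared readers and writers (CSV/TSV tables, FASTA, GCG MSF, PWM
# JSON/TSV, GSEA .rnk) and the end-to-end epitope pipeline runner.
# Numeric output is formatted to 6 significant digits so reruns of the
# same configuration are byte-identical.

.fmt_num <- function(x)
    vapply(x, function(v) format(v, digits = 6, trim = TRUE), character(1))

# read everything as character so digit codes survive verbatim; callers
# convert numeric columns explicitly
.read_delim_auto <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "", quote = "\"",
                      colClasses = "character")
}

.as_num <- function(x) suppressWarnings(as.numeric(x))

.require_columns <- function(df, cols, path) {
    missing <- setdiff(cols, colnames(df))
    if (length(missing))
        stop("file '", path, "' lacks required column(s): ",
             paste(missing, collapse = ", "))
}

#' Read an oligo panel table
#'
#' CSV or TSV (auto-detected) with a column `id` and either `structure`
#' (the human-readable dialect of [parseHSStructure()]) or `code`
#' (concatenated 11-digit codes).
#'
#' @param path file path.
#' @return A list of [HSOligo-class] objects, in file order.
#' @export
readOligoPanel <- function(path) {
    df <- .read_delim_auto(path)
    .require_columns(df, "id", path)
    if (!any(c("structure", "code") %in% colnames(df)))
        stop("file '", path, "' needs a 'structure' or 'code' column")
    if (anyDuplicated(df$id))
        stop("duplicate oligo id(s) in '", path, "'")
    lapply(seq_len(nrow(df)), function(i) {
        tryCatch({
            if ("structure" %in% colnames(df) &&
                !is.na(df$structure[i]) && nzchar(df$structure[i]))
                parseHSStructure(df$structure[i], id = df$id[i])
            else decodeOligo(as.character(df$code[i]), id = df$id[i])
        }, error = function(e)
            stop("row ", i, " (id '", df$id[i], "') of '", path, "': ",
                 conditionMessage(e), call. = FALSE))
    })
}

#' Read an IC50 table
#'
#' CSV or TSV with columns `oligo_id` and `ic50` (alias
#' `ic50_ug_per_ml`), all values finite and strictly positive.
#'
#' @param path file path.
#' @return A data.frame with columns `oligo_id` and `ic50`.
#' @export
readIC50Table <- function(path) {
    df <- .read_delim_auto(path)
    if ("ic50_ug_per_ml" %in% colnames(df) && !"ic50" %in% colnames(df))
        colnames(df)[colnames(df) == "ic50_ug_per_ml"] <- "ic50"
    .require_columns(df, c("oligo_id", "ic50"), path)
    df$ic50 <- .as_num(df$ic50)
    bad <- which(!is.finite(df$ic50) | df$ic50 <= 0)
    if (length(bad))
        stop("non-positive or missing IC50 in '", path, "', row ",
             bad[1], ", column 'ic50'")
    df[, c("oligo_id", "ic50")]
}

#' Read a long- or wide-format MFI table
#'
#' Long format has columns `population`, `scfv`, `mfi` (and optionally
#' `replicate`); anything else is treated as wide format with a
#' `population` column, an optional `replicate` column, and one column
#' per scFv.
#'
#' @param path file path.
#' @param control negative-control scFv label, see [MFIExperiment()].
#' @return An [MFIExperiment-class].
#' @export
readMFITable <- function(path, control = "MPB49") {
    df <- .read_delim_auto(path)
    if (all(c("population", "scfv", "mfi") %in% colnames(df))) {
        df$mfi <- .as_num(df$mfi)
        return(MFIExperiment(df, control = control))
    }
    .require_columns(df, "population", path)
    idcols <- intersect(c("population", "replicate"), colnames(df))
    scfvs <- setdiff(colnames(df), idcols)
    if (!length(scfvs))
        stop("file '", path, "' has no scFv columns")
    long <- do.call(rbind, lapply(scfvs, function(s) data.frame(
        population = df$population,
        replicate = if ("replicate" %in% idcols) df$replicate
                    else stats::ave(seq_len(nrow(df)), df$population,
                                    FUN = seq_along),
        scfv = s, mfi = .as_num(df[[s]]))))
    MFIExperiment(long, control = control)
}

#' Read a single-column per-cell intensity file
#'
#' One numeric intensity per line (a header naming the column, e.g.
#' `mfi`, is allowed), as exported from cytometry software for one
#' channel.
#'
#' @param path file path.
#' @return Numeric vector of non-negative intensities.
#' @export
readCellMFI <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- trimws(readLines(path))
    lineno <- which(nzchar(lines))
    lines <- lines[lineno]
    if (length(lines) && is.na(.as_num(lines[1]))) {
        lines <- lines[-1]  # header
        lineno <- lineno[-1]
    }
    v <- .as_num(lines)
    bad <- which(is.na(v))
    if (length(bad))
        stop("non-numeric intensity at line ", lineno[bad[1]], " of '",
             path, "'")
    if (any(v < 0))
        stop("negative intensity in '", path, "'")
    v
}

#' Read a differential-expression table
#'
#' CSV or TSV with columns `gene`, `log2fc` and `padj`; adjusted
#' p-values must lie in `(0, 1]`.
#'
#' @param path file path.
#' @return A validated data.frame.
#' @export
readDETable <- function(path) {
    df <- .read_delim_auto(path)
    .require_columns(df, c("gene", "log2fc", "padj"), path)
    df$log2fc <- .as_num(df$log2fc)
    df$padj <- .as_num(df$padj)
    bad <- which(!is.finite(df$padj) | df$padj <= 0 | df$padj > 1)
    if (length(bad))
        stop("adjusted p-value outside (0, 1] in '", path, "', row ",
             bad[1], ", column 'padj'")
    df
}

#' Write a preranked GSEA .rnk file
#'
#' Two tab-separated columns (gene, score), no header, genes in
#' decreasing score order -- the input format of preranked GSEA.
#'
#' @param table data.frame with columns `gene` and `score`, or `gene`,
#'   `padj` and `log2fc` (scores computed via [signedLogPScore()]).
#' @param path output path.
#' @return Invisibly, the written data.frame.
#' @export
writeRnk <- function(table, path) {
    stopifnot(is.data.frame(table), "gene" %in% colnames(table))
    if (!"score" %in% colnames(table)) {
        stopifnot(all(c("padj", "log2fc") %in% colnames(table)))
        table$score <- as.numeric(signedLogPScore(table$padj, table$log2fc))
    }
    out <- table[order(-table$score, table$gene),
                 c("gene", "score"), drop = FALSE]
    writeLines(paste(out$gene, .fmt_num(out$score), sep = "\t"), path)
    invisible(out)
}

# GCG checksum: sum over positions of ((i - 1) mod 57 + 1) * ascii,
# modulo 10000; gaps written as '.'
.gcg_checksum <- function(seq) {
    chars <- utf8ToInt(seq)
    idx <- (seq_along(chars) - 1L) %% 57L + 1L
    sum(idx * chars) %% 10000L
}

#' Write a weighted MSF in GCG format
#'
#' Writes the aligned pseudo-sequences in the GCG multiple-sequence-file
#' dialect. With `expand = FALSE` (default) each oligo appears once and
#' its copy count is carried in the `Weight:` field; with
#' `expand = TRUE` each oligo is physically repeated copy-count times
#' with unit weight. Gaps are written as `.` per GCG convention. Output
#' ordering follows the MSF's sequence order and is byte-stable.
#'
#' @param msf a [WeightedMSF-class].
#' @param path output path.
#' @param expand materialize copies as repeated records.
#' @return Invisibly, `path`.
#' @export
writeMSF <- function(msf, path, expand = FALSE) {
    stopifnot(is(msf, "WeightedMSF"))
    seqs <- gsub("-", ".", msf@aligned, fixed = TRUE)
    ids <- msf@ids
    weights <- as.numeric(msf@copies)
    if (expand) {
        rep_idx <- rep(seq_along(ids), msf@copies)
        copy_no <- unlist(lapply(msf@copies, seq_len))
        seqs <- seqs[rep_idx]
        ids <- sprintf("%s_%d", ids[rep_idx], copy_no)
        weights <- rep(1, length(ids))
    }
    len <- nchar(seqs[1])
    checks <- vapply(seqs, .gcg_checksum, numeric(1), USE.NAMES = FALSE)
    total <- sum(checks) %% 10000
    lines <- c(
        "PileUp", "",
        sprintf(" MSF: %d  Type: P  Check: %d ..", len, total), "",
        sprintf(" Name: %s  Len: %d  Check: %d  Weight: %s",
                ids, len, checks, .fmt_num(weights)),
        "", "//", "")
    wrap <- function(s) {
        starts <- seq(1L, len, by = 50L)
        vapply(starts, function(b) {
            chunk <- substring(s, seq(b, min(b + 49L, len), by = 10L),
                               pmin(seq(b + 9L, b + 49L, by = 10L), len))
            paste(chunk[nzchar(chunk)], collapse = " ")
        }, character(1))
    }
    namew <- max(nchar(ids))
    blocks <- unlist(lapply(seq_len(length(wrap(seqs[1]))), function(b)
        c(sprintf("%-*s  %s", namew, ids,
                  vapply(seqs, function(s) wrap(s)[b], character(1))), "")))
    writeLines(c(lines, blocks), path)
    invisible(path)
}

#' Write pseudo-sequences as FASTA
#'
#' With a [WeightedMSF-class], `expand = TRUE` repeats each aligned
#' record copy-count times; otherwise each oligo appears once and the
#' copy counts can be written to a sidecar two-column TSV.
#'
#' @param x a [WeightedMSF-class] or a named character vector /
#'   [Biostrings::AAStringSet] of sequences.
#' @param path output FASTA path.
#' @param expand repeat records by copy count (WeightedMSF only).
#' @param weightsPath optional sidecar TSV (`id`, `copies`).
#' @return Invisibly, `path`.
#' @export
writePseudoFasta <- function(x, path, expand = FALSE, weightsPath = NULL) {
    if (is(x, "WeightedMSF")) {
        seqs <- x@aligned
        ids <- x@ids
        if (expand) {
            rep_idx <- rep(seq_along(ids), x@copies)
            copy_no <- unlist(lapply(x@copies, seq_len))
            seqs <- seqs[rep_idx]
            ids <- sprintf("%s_%d", ids[rep_idx], copy_no)
        }
        if (!is.null(weightsPath))
            writeLines(c("id\tcopies",
                         paste(x@ids, x@copies, sep = "\t")), weightsPath)
        ss <- Biostrings::AAStringSet(structure(seqs, names = ids))
    } else {
        ss <- if (is(x, "XStringSet")) x else Biostrings::AAStringSet(x)
    }
    Biostrings::writeXStringSet(ss, path)
    invisible(path)
}

#' Write a position weight matrix (and its HS-code logo) as JSON
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePWMJson <- function(pwm, path) {
    stopifnot(is(pwm, "PositionWeightMatrix"))
    logo <- pwmToHSLogo(pwm)
    obj <- list(
        alphabet = list(letters = pwm@alphabet@letters,
                        codes = pwm@alphabet@codes),
        n_columns = ncol(pwm@freq),
        frequencies = unname(apply(pwm@freq, 2L, function(col)
            as.list(structure(as.list(signif(col, 6)),
                              names = rownames(pwm@freq))))),
        information_bits = signif(pwm@info, 6),
        gap_fraction = signif(pwm@gapFraction, 6),
        all_gap = pwm@allGap,
        consensus_letters = consensusLetters(pwm),
        consensus_codes = ifelse(is.na(consensusLetters(pwm)),
                                 NA_character_,
                                 pwm@alphabet@codes[match(
                                     consensusLetters(pwm),
                                     pwm@alphabet@letters)]),
        logo = logoTable(logo))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(path)
}

#' Write a position weight matrix as a TSV matrix
#'
#' One row per alignment column: `position`, one frequency column per
#' letter, then `information_bits` and `gap_fraction`.
#'
#' @param pwm a [PositionWeightMatrix-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePWMTsv <- function(pwm, path) {
    stopifnot(is(pwm, "PositionWeightMatrix"))
    header <- c("position", rownames(pwm@freq), "information_bits",
                "gap_fraction")
    rows <- vapply(seq_len(ncol(pwm@freq)), function(j)
        paste(c(j, .fmt_num(pwm@freq[, j]), .fmt_num(pwm@info[j]),
                .fmt_num(pwm@gapFraction[j])), collapse = "\t"),
        character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
    invisible(path)
}

#' Run the epitope-inference pipeline end to end
#'
#' Reads an oligo panel and its IC50 table, builds the pseudo-amino-acid
#' alphabet, the IC50-weighted aligned MSF and the position weight
#' matrix, back-translates to the HS-code logo, and writes `pwm.json`,
#' `pwm.tsv`, `logo.tsv`, `msf.msf` and `provenance.json` into `outDir`.
#' Outputs are written atomically (staged under temporary names, renamed
#' on success, removed on failure), contain no timestamps, and are
#' byte-identical across reruns of the same inputs and configuration.
#'
#' @param oligoPath oligo panel table, see [readOligoPanel()].
#' @param ic50Path IC50 table, see [readIC50Table()].
#' @param outDir output directory (created if needed).
#' @param reference IC50 weighting reference, see [ic50ToCopies()].
#' @param smallSampleCorrection passed to [computePWM()].
#' @param mode alignment mode, see [alignPseudoSequences()].
#' @return Invisibly, a named character vector of the written paths.
#' @export
runEpitopePipeline <- function(oligoPath, ic50Path, outDir,
                               reference = 100,
                               smallSampleCorrection = FALSE,
                               mode = "auto") {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    final <- file.path(outDir, c(pwm_json = "pwm.json", pwm_tsv = "pwm.tsv",
                                 logo_tsv = "logo.tsv", msf = "msf.msf",
                                 provenance = "provenance.json"))
    names(final) <- c("pwm_json", "pwm_tsv", "logo_tsv", "msf",
                      "provenance")
    staged <- paste0(final, ".tmp")
    on.exit(unlink(staged), add = TRUE)
    oligos <- readOligoPanel(oligoPath)
    records <- readIC50Table(ic50Path)
    map <- buildAlphabet(oligos)
    msf <- buildWeightedMSF(oligos, records, map, reference = reference,
                            mode = mode)
    pwm <- computePWM(msf, smallSampleCorrection = smallSampleCorrection)
    logo <- pwmToHSLogo(pwm)
    writePWMJson(pwm, staged[1])
    writePWMTsv(pwm, staged[2])
    lt <- logoTable(logo)
    writeLines(c(paste(colnames(lt), collapse = "\t"),
                 vapply(seq_len(nrow(lt)), function(i)
                     paste(c(lt$position[i], lt$code[i],
                             .fmt_num(lt$frequency[i]),
                             .fmt_num(lt$height[i])), collapse = "\t"),
                     character(1))), staged[3])
    writeMSF(msf, staged[4])
    prov <- list(
        package = "HSglycotyper",
        version = as.character(utils::packageVersion("HSglycotyper")),
        config = list(oligoPath = oligoPath, ic50Path = ic50Path,
                      reference = reference,
                      smallSampleCorrection = smallSampleCorrection,
                      mode = mode),
        n_oligos = length(oligos),
        total_copies = sum(copyCounts(msf)))
    jsonlite::write_json(prov, staged[5], auto_unbox = TRUE, pretty = TRUE)
    ok <- file.rename(staged, final)
    if (!all(ok)) stop("failed to finalize pipeline outputs")
    invisible(final)
}
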