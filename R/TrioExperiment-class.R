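#' TrioExperiment: counts for a parent/parent/hybrid trio
#'
#' A \code{TrioExperiment} is a
#' \linkS4class{SummarizedExperiment} holding a gene-by-sample matrix of
#' non-negative integer counts (assay \code{"counts"}) for the three lines of
#' a heterosis trio: the two parents (\code{P1}, \code{P2}) and their F1
#' hybrid (\code{F1}), each with at least two replicates.  \code{colData}
#' carries the \code{line} and \code{replicate} assignment of every sample;
#' \code{rowData} may carry a \code{length} column (gene length in bp, used
#' for FPKM) and, for simulated data, the ground-truth effect columns.
#'
#' @param counts integer-like matrix, genes in rows, samples in columns.
#'   Row names are gene identifiers; column names are sample identifiers.
#' @param line character or factor of length \code{ncol(counts)} with values
#'   in \code{c("P1", "P2", "F1")}.
#' @param replicate replicate (block) index per sample; defaults to a
#'   within-line running index.
#' @param geneLengths optional numeric vector of gene lengths in bp, one per
#'   row of \code{counts}.
#' @param rowData,metadata passed on to
#'   \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#'
#' @return A \code{TrioExperiment} object.
#'
#' @examples
#' te <- exampleTrio(n_genes = 50, seed = 1)
#' te
#' table(trioLine(te))
#'
#' @export
#' @import SummarizedExperiment
#' @importFrom S4Vectors SimpleList
setClass("TrioExperiment", contains = "SummarizedExperiment")

TRIO_LINES <- c("P1", "P2", "F1")

setValidity("TrioExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(!is.finite(cts))) msg <- c(msg, "counts must be finite")
    }
    cd <- colData(object)
    if (!all(c("line", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'line' and 'replicate'")
    else {
        ln <- as.character(cd$line)
        if (!all(ln %in% TRIO_LINES))
            msg <- c(msg, sprintf("line values must be in {%s}",
                                  paste(TRIO_LINES, collapse = ", ")))
        else if (ncol(object) > 0L) {
            tab <- table(factor(ln, levels = TRIO_LINES))
            if (any(tab < 2L))
                msg <- c(msg, "each line needs at least 2 replicates")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname TrioExperiment-class
#' @export
TrioExperiment <- function(counts, line, replicate = NULL,
                           geneLengths = NULL, rowData = NULL,
                           metadata = list()) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    line <- factor(as.character(line), levels = TRIO_LINES)
    if (anyNA(line))
        stop("'line' must only contain P1, P2, F1")
    if (is.null(replicate)) {
        replicate <- integer(length(line))
        for (l in TRIO_LINES) replicate[line == l] <- seq_len(sum(line == l))
    }
    cd <- S4Vectors::DataFrame(line = line, replicate = as.integer(replicate),
                               row.names = colnames(counts))
    rd <- if (is.null(rowData))
        S4Vectors::DataFrame(row.names = rownames(counts))
    else S4Vectors::DataFrame(rowData, row.names = rownames(counts))
    if (!is.null(geneLengths)) {
        stopifnot(length(geneLengths) == nrow(counts))
        rd$length <- as.numeric(geneLengths)
    }
    se <- SummarizedExperiment(assays = S4Vectors::SimpleList(counts = counts),
                               colData = cd, rowData = rd,
                               metadata = metadata)
    new("TrioExperiment", se)
}

#' Line and replicate assignment of trio samples
#'
#' @param object a \code{TrioExperiment}.
#' @return \code{trioLine}: factor of line labels (\code{P1}, \code{P2},
#'   \code{F1}) per sample.  \code{trioReplicate}: integer replicate (block)
#'   index per sample.
#' @examples
#' te <- exampleTrio(n_genes = 10, seed = 1)
#' trioLine(te)
#' @rdname trioLine
#' @export
setMethod("trioLine", "TrioExperiment", function(object)
    factor(as.character(colData(object)$line), levels = TRIO_LINES))

#' @rdname trioLine
#' @export
setMethod("trioReplicate", "TrioExperiment", function(object)
    as.integer(colData(object)$replicate))

#' Gene lengths stored in a TrioExperiment
#'
#' @param object a \code{TrioExperiment}.
#' @param value numeric vector of lengths (bp), one per gene.
#' @return numeric vector of gene lengths, or \code{NULL} when none stored.
#' @rdname geneLengths
#' @export
setMethod("geneLengths", "TrioExperiment", function(object) {
    len <- rowData(object)$length
    if (is.null(len)) return(NULL)
    stats::setNames(as.numeric(len), rownames(object))
})

#' @rdname geneLengths
#' @export
setMethod("geneLengths<-", "TrioExperiment", function(object, value) {
    rowData(object)$length <- as.numeric(value)
    validObject(object)
    object
})

#' @describeIn TrioExperiment-class compact display.
#' @param object a \code{TrioExperiment}.
#' @export
setMethod("show", "TrioExperiment", function(object) {
    callNextMethod()
    tab <- table(trioLine(object))
    cat("trio design:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
})

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of a sample's count to the geometric mean count of the gene,
#' restricted to genes nonzero in every sample, then rescaled so the factors
#' have geometric mean exactly 1.
#'
#' @param object a \code{TrioExperiment} or a count matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' sizeFactors(m)   # ratio 1:2, geometric mean 1
#' @rdname sizeFactors
#' @aliases sizeFactors
#' @export
setMethod("sizeFactors", "TrioExperiment", function(object)
    sizeFactors(assay(object, "counts")))

#' @rdname sizeFactors
#' @export
setMethod("sizeFactors", "matrix", function(object)
    .sizeFactorsMatrix(object))

.sizeFactorsMatrix <- function(counts) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    colsums <- colSums(counts)
    if (any(colsums == 0))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(counts)[colsums == 0], collapse = ", "))
    keep <- rowSums(counts == 0) == 0L
    if (!any(keep))
        stop("no gene is nonzero in all samples; cannot compute size factors")
    kept <- counts[keep, , drop = FALSE]
    geo <- exp(rowMeans(log(kept)))     # per-gene geometric mean reference
    sf <- apply(kept / geo, 2L, stats::median)
    sf <- sf / exp(mean(log(sf)))       # force geometric mean 1
    stats::setNames(sf, colnames(counts))
}

#' Count matrix of a TrioExperiment
#'
#' Extracts the (optionally size-factor normalized) count matrix.
#'
#' @param object a \code{TrioExperiment}.
#' @param normalized logical; divide each sample by its size factor?
#' @return numeric matrix of (normalized) counts.
#' @aliases counts
#' @rdname counts
#' @export
setMethod("counts", "TrioExperiment", function(object, normalized = FALSE) {
    cts <- assay(object, "counts")
    if (normalized) {
        sf <- sizeFactors(object)
        cts <- sweep(cts, 2L, sf, "/")
    }
    cts
})
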