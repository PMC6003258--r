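#' FPKM expression values
#'
#' Fragments per kilobase of gene model per million mapped fragments:
#' \eqn{FPKM_{gs} = 10^9 c_{gs} / (L_g N_s)} where \eqn{L_g} is the gene
#' length in bp and \eqn{N_s} the column total of the count matrix.
#'
#' @param object a \code{\link{TrioExperiment}} (gene lengths taken from
#'   \code{rowData(object)$length}) or a count matrix.
#' @param lengths gene lengths in bp (required for the matrix method).
#' @param ... unused.
#' @return matrix of FPKM values with the dimensions of the input counts.
#'   For the \code{TrioExperiment} method the result is also stored as
#'   assay \code{"fpkm"} of the returned object.
#' @examples
#' m <- matrix(c(1000, 999000), 2, 1,
#'             dimnames = list(c("g1", "g2"), "s1"))
#' fpkm(m, lengths = c(1000, 99900))["g1", ]   # 1000 FPKM
#' @rdname fpkm
#' @export
setMethod("fpkm", "matrix", function(object, lengths, ...) {
    if (length(lengths) != nrow(object))
        stop("'lengths' must have one entry per gene")
    if (any(lengths <= 0)) stop("gene lengths must be positive")
    total <- colSums(object)
    if (any(total == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(object)[total == 0], collapse = ", "))
    out <- object * 1e9 / outer(as.numeric(lengths), as.numeric(total))
    dimnames(out) <- dimnames(object)
    out
})

#' @rdname fpkm
#' @export
setMethod("fpkm", "TrioExperiment", function(object, lengths = NULL, ...) {
    if (is.null(lengths)) lengths <- geneLengths(object)
    if (is.null(lengths))
        stop("no gene lengths: supply 'lengths' or set geneLengths()")
    assay(object, "fpkm") <- fpkm(assay(object, "counts"), lengths)
    object
})

#' Expressed-gene filter
#'
#' A gene counts as expressed when its FPKM reaches \code{minFpkm} in at
#' least \code{minSamples} sample(s).  The expressed set is the default
#' enrichment universe.
#'
#' @param fpkmMat FPKM matrix (genes x samples).
#' @param minFpkm expression threshold, default 1 FPKM.
#' @param minSamples minimum number of samples reaching it.
#' @return character vector of expressed gene ids.
#' @export
expressedGenes <- function(fpkmMat, minFpkm = 1, minSamples = 1L) {
    rownames(fpkmMat)[rowSums(fpkmMat >= minFpkm) >= minSamples]
}

#' Within-line replicate agreement
#'
#' Squared Pearson correlation of \code{log2(FPKM + 1)} for every pair of
#' samples from the same line — the usual replicate-quality diagnostic for
#' a trio RNA-seq experiment.
#'
#' @param object FPKM matrix or a \code{\link{TrioExperiment}} carrying an
#'   \code{"fpkm"} assay (computed on the fly from counts and gene lengths
#'   when absent).
#' @param line factor of line labels per sample (matrix method).
#' @param ... unused.
#' @return data.frame with columns \code{line}, \code{sample1},
#'   \code{sample2}, \code{r2}.  Pairs involving a constant column get
#'   \code{NA} with a warning.
#' @examples
#' te <- exampleTrio(n_genes = 300, seed = 5)
#' rr <- replicateR2(te)
#' aggregate(r2 ~ line, rr, mean)
#' @rdname replicateR2
#' @export
setMethod("replicateR2", "matrix", function(object, line, ...) {
    line <- as.factor(line)
    lx <- log2(object + 1)
    rows <- list()
    for (l in levels(line)) {
        idx <- which(line == l)
        if (length(idx) < 2L) next
        for (i in seq_along(idx)[-length(idx)]) for (j in seq(i + 1,
                                                              length(idx))) {
            a <- lx[, idx[i]]; b <- lx[, idx[j]]
            r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
                warning("constant column in pair (", colnames(object)[idx[i]],
                        ", ", colnames(object)[idx[j]], "); R2 undefined")
                NA_real_
            } else stats::cor(a, b)^2
            rows[[length(rows) + 1L]] <- data.frame(
                line = l,
                sample1 = colnames(object)[idx[i]],
                sample2 = colnames(object)[idx[j]],
                r2 = r2, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(line = character(0), sample1 = character(0),
                          sample2 = character(0), r2 = numeric(0))
    rownames(out) <- NULL
    out
})

#' @rdname replicateR2
#' @export
setMethod("replicateR2", "TrioExperiment", function(object, ...) {
    mat <- if ("fpkm" %in% assayNames(object)) assay(object, "fpkm")
           else assay(fpkm(object), "fpkm")
    replicateR2(mat, trioLine(object))
})
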