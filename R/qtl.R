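#' Gene-QTL interval colocalization
#'
#' Reports every (gene, QTL) pair whose 1-based inclusive intervals share
#' at least one base on the same chromosome; touching endpoints therefore
#' count (overlap length 1).  A gene may hit several QTLs and a QTL may
#' contain several genes.  Genes on chromosomes absent from the QTL panel
#' (and vice versa) are skipped with a message, not an error.
#'
#' @param genes \code{GRanges} of gene models with a \code{gene_id}
#'   metadata column (e.g. from \code{\link{readGeneModels}} or
#'   \code{\link{simulateGenomeFeatures}}).
#' @param qtls \code{GRanges} of QTL intervals with \code{qtl_id} and
#'   optionally \code{trait} and \code{markers} metadata columns (e.g. from
#'   \code{\link{readQTLPanel}}).
#' @return data.frame sorted by chromosome and gene start: \code{qtl_id},
#'   \code{trait}, \code{gene}, \code{chrom}, \code{gene_start},
#'   \code{gene_end}, \code{qtl_start}, \code{qtl_end}, \code{overlap_bp}.
#' @examples
#' genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200),
#'                                 gene_id = "g1")
#' qtls <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300),
#'                                qtl_id = "q1", trait = "GPP")
#' qtlColocalization(genes, qtls)   # touching endpoints: overlap 1 bp
#' @export
#' @importFrom GenomicRanges findOverlaps seqnames start end pintersect
#' @importFrom S4Vectors queryHits subjectHits
qtlColocalization <- function(genes, qtls) {
    if (!length(genes) || !length(qtls))
        return(.emptyColoc())
    gChrom <- as.character(seqnames(genes))
    qChrom <- as.character(seqnames(qtls))
    orphan <- setdiff(union(gChrom, qChrom), intersect(gChrom, qChrom))
    if (length(orphan))
        message("chromosome label(s) present on one side only, skipped: ",
                paste(orphan, collapse = ", "))
    ov <- suppressWarnings(findOverlaps(genes, qtls))
    if (!length(ov)) return(.emptyColoc())
    g <- genes[queryHits(ov)]
    q <- qtls[subjectHits(ov)]
    out <- data.frame(
        qtl_id = as.character(q$qtl_id),
        trait = if (!is.null(q$trait)) as.character(q$trait)
                else NA_character_,
        gene = as.character(g$gene_id),
        chrom = as.character(seqnames(g)),
        gene_start = start(g), gene_end = end(g),
        qtl_start = start(q), qtl_end = end(q),
        overlap_bp = pmin(end(g), end(q)) - pmax(start(g), start(q)) + 1L,
        stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$gene_start, out$qtl_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.emptyColoc <- function()
    data.frame(qtl_id = character(0), trait = character(0),
               gene = character(0), chrom = character(0),
               gene_start = integer(0), gene_end = integer(0),
               qtl_start = integer(0), qtl_end = integer(0),
               overlap_bp = integer(0))

#' QTL-wise colocalization report
#'
#' Groups colocalization records by QTL and lists the overlapping candidate
#' genes per QTL, restricted to a supplied gene set (e.g. the DG_HP DEGs)
#' when given — the classic trait / QTL / chromosome / interval / genes
#' report shape.
#'
#' @param colocs a \code{\link{qtlColocalization}} result.
#' @param candidateGenes optional character vector; keep only these genes.
#' @return data.frame with one row per QTL that retains at least one gene:
#'   \code{trait}, \code{qtl_id}, \code{chrom}, \code{interval},
#'   \code{n_genes}, \code{genes} (comma-separated ids), grouped by trait.
#' @export
colocalizationReport <- function(colocs, candidateGenes = NULL) {
    if (!is.null(candidateGenes))
        colocs <- colocs[colocs$gene %in% candidateGenes, , drop = FALSE]
    if (!nrow(colocs))
        return(data.frame(trait = character(0), qtl_id = character(0),
                          chrom = character(0), interval = character(0),
                          n_genes = integer(0), genes = character(0)))
    key <- paste(colocs$trait, colocs$qtl_id, sep = "\r")
    rows <- lapply(split(colocs, key), function(cc) {
        data.frame(trait = cc$trait[1], qtl_id = cc$qtl_id[1],
                   chrom = cc$chrom[1],
                   interval = sprintf("%d-%d", cc$qtl_start[1],
                                      cc$qtl_end[1]),
                   n_genes = length(unique(cc$gene)),
                   genes = paste(sort(unique(cc$gene)), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$trait, out$qtl_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
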