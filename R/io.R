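#' Read a gene-by-sample count matrix from TSV
#'
#' First column = gene id, header = sample ids.
#'
#' @param path TSV file.
#' @return integer matrix with gene row names.
#' @export
readCountMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "numeric"
    if (any(m < 0)) stop("negative counts in ", path)
    m
}

#' Read a sample sheet (sample, line, replicate)
#'
#' @param path TSV file with columns \code{sample}, \code{line},
#'   \code{replicate}.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("sample", "line", "replicate") %in% colnames(df)))
    df
}

#' Assemble a TrioExperiment from TSV inputs
#'
#' @param countsPath counts TSV (see \code{\link{readCountMatrix}}).
#' @param sampleSheetPath sample sheet TSV.
#' @param geneModelsPath optional GFF3/BED gene-model file; supplies gene
#'   lengths.
#' @return a \code{\link{TrioExperiment}}.
#' @export
readTrioExperiment <- function(countsPath, sampleSheetPath,
                               geneModelsPath = NULL) {
    cts <- readCountMatrix(countsPath)
    sheet <- readSampleSheet(sampleSheetPath)
    missing <- setdiff(colnames(cts), sheet$sample)
    if (length(missing))
        stop("samples absent from sample sheet: ",
             paste(missing, collapse = ", "))
    sheet <- sheet[match(colnames(cts), sheet$sample), ]
    lengths <- NULL
    if (!is.null(geneModelsPath)) {
        gm <- readGeneModels(geneModelsPath)
        idx <- match(rownames(cts), gm$gene_id)
        if (anyNA(idx))
            stop("gene id(s) missing from gene models: ",
                 paste(utils::head(rownames(cts)[is.na(idx)], 5L),
                       collapse = ", "))
        lengths <- GenomicRanges::width(gm)[idx]
    }
    TrioExperiment(cts, sheet$line, sheet$replicate, geneLengths = lengths)
}

#' Read a replicated trait table
#'
#' @param path TSV with columns \code{trait}, \code{line},
#'   \code{replicate}, \code{value}.
#' @return data.frame.
#' @export
readTraitTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("trait", "line", "replicate", "value") %in%
                  colnames(df)))
    df
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 coordinates are used as stored (1-based inclusive); BED intervals
#' are 0-based half-open on disk and arrive converted to 1-based inclusive
#' by the importer.  For GFF3, features of type \code{gene} are kept when
#' present and the identifier is taken from \code{ID}/\code{Name}; for BED
#' the \code{name} column is the identifier.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format \code{"gff3"} or \code{"bed"}.
#' @return \code{GRanges} with a \code{gene_id} metadata column.
#' @export
#' @importFrom rtracklayer import
readGeneModels <- function(path, format = c("auto", "gff3", "bed")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else "gff3"
    gr <- rtracklayer::import(path, format = format)
    if (format == "gff3") {
        if (!is.null(gr$type) && any(gr$type == "gene"))
            gr <- gr[gr$type == "gene"]
        id <- if (!is.null(gr$ID)) gr$ID else gr$Name
    } else {
        id <- gr$name
    }
    if (is.null(id) || anyNA(id))
        stop("gene models need an ID/name attribute in ", path)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(id))
    gr
}

#' Write gene models as GFF3
#'
#' @param genes \code{GRanges} with \code{gene_id}.
#' @param path output file.
#' @export
#' @importFrom rtracklayer export
writeGeneModels <- function(genes, path) {
    out <- genes
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        source = "heterex", type = "gene", ID = genes$gene_id)
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' Read a QTL interval panel from TSV
#'
#' Columns \code{qtl_id}, \code{trait}, \code{chrom}, \code{start},
#' \code{end} (1-based inclusive) and optionally \code{markers} (flanking
#' markers, annotation only).
#'
#' @param path TSV file.
#' @return \code{GRanges} with \code{qtl_id}, \code{trait}, \code{markers}.
#' @export
readQTLPanel <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("qtl_id", "trait", "chrom", "start", "end") %in%
                  colnames(df)))
    if (any(df$start > df$end)) stop("QTL intervals need start <= end")
    GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start, df$end),
        qtl_id = df$qtl_id, trait = df$trait,
        markers = if ("markers" %in% colnames(df)) df$markers
                  else NA_character_)
}

#' Write a QTL panel to TSV
#'
#' @param qtls \code{GRanges} as produced by \code{\link{readQTLPanel}} or
#'   \code{\link{simulateGenomeFeatures}}.
#' @param path output file.
#' @export
writeQTLPanel <- function(qtls, path) {
    df <- data.frame(qtl_id = qtls$qtl_id, trait = qtls$trait,
                     chrom = as.character(GenomicRanges::seqnames(qtls)),
                     start = GenomicRanges::start(qtls),
                     end = GenomicRanges::end(qtls),
                     markers = qtls$markers, stringsAsFactors = FALSE)
    writeTSV(df, path)
}

#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of gene-id vectors; each element carries a
#'   \code{description} attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3L)
            stop("malformed GMT line (need term, description, >=1 gene): ",
                 substr(ln, 1, 60))
        ids <- parts[-(1:2)]
        attr(ids, "description") <- parts[2]
        out[[parts[1]]] <- ids
    }
    out
}

#' Write a term map as GMT
#'
#' @param termMap named list of gene-id vectors (optional
#'   \code{description} attributes).
#' @param path output file.
#' @export
writeGMT <- function(termMap, path) {
    lines <- vapply(names(termMap), function(term) {
        desc <- attr(termMap[[term]], "description")
        if (is.null(desc)) desc <- term
        paste(c(term, desc, as.character(termMap[[term]])), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a data.frame (or DataFrame) as TSV
#'
#' @param df table to write.
#' @param path output file.
#' @export
writeTSV <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a count matrix as TSV (gene id first column)
#'
#' @param counts matrix with gene row names.
#' @param path output file.
#' @export
writeCountMatrix <- function(counts, path) {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    writeTSV(df, path)
}
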