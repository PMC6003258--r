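#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim} Hypergeometric(\eqn{N} universe genes, \eqn{K} of them in
#' the term, \eqn{n} drawn).
#'
#' @param k term members in the gene set.
#' @param K term members in the universe.
#' @param n gene-set size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @examples
#' hypergeomTest(5, 5, 5, 10)   # 1/choose(10, 5)
#' @export
hypergeomTest <- function(k, K, n, N) {
    if (n > N) stop("gene-set size n exceeds universe size N")
    if (K > N) stop("term size K exceeds universe size N")
    if (k > min(K, n)) stop("k cannot exceed min(K, n)")
    if (k < 0) stop("k must be non-negative")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation analysis of a gene set
#'
#' Hypergeometric test of every sufficiently large term in a term map
#' against a gene set drawn from a stated universe, with BH-FDR across the
#' tested terms.  Stands in for GO / KEGG over-representation when the term
#' map is a GO or pathway gene-set collection (e.g. read from GMT with
#' \code{\link{readGMT}}).
#'
#' @param geneSet character vector of gene ids (deduplicated with a warning
#'   if needed); must be contained in \code{universe}.
#' @param universe character vector of background gene ids (typically the
#'   expressed genes, \code{\link{expressedGenes}}).
#' @param termMap named list of gene-id vectors; an optional
#'   \code{description} attribute per term is carried through.
#' @param minSize terms with fewer than this many universe members are not
#'   tested (default 3).
#' @param topN optionally keep only the \code{topN} smallest-p rows.
#' @return data.frame sorted by p: \code{term}, \code{description},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{fdr}.
#' @examples
#' tm <- list(T1 = c("g1", "g2", "g3"), T2 = c("g4", "g5", "g6"))
#' enrich(c("g1", "g2", "g3"), paste0("g", 1:6), tm)
#' @export
enrich <- function(geneSet, universe, termMap, minSize = 3L, topN = NULL) {
    geneSet <- as.character(geneSet)
    if (!length(geneSet)) stop("empty gene set: nothing to test")
    if (anyDuplicated(geneSet)) {
        warning("duplicate ids in gene set removed")
        geneSet <- unique(geneSet)
    }
    universe <- unique(as.character(universe))
    outside <- setdiff(geneSet, universe)
    if (length(outside))
        stop("gene set not contained in universe: ",
             paste(utils::head(outside, 5L), collapse = ", "),
             if (length(outside) > 5L) ", ...")
    N <- length(universe)
    n <- length(geneSet)
    rows <- lapply(names(termMap), function(term) {
        members <- intersect(unique(as.character(termMap[[term]])), universe)
        K <- length(members)
        if (K < minSize) return(NULL)
        k <- length(intersect(members, geneSet))
        desc <- attr(termMap[[term]], "description")
        data.frame(term = term,
                   description = if (is.null(desc)) NA_character_ else desc,
                   k = k, K = K, n = n, N = N,
                   p = hypergeomTest(k, K, n, N),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term = character(0), description = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), p = numeric(0), fdr = numeric(0)))
    out$fdr <- bhAdjust(out$p)
    out <- out[order(out$p, out$term), , drop = FALSE]
    if (!is.null(topN)) out <- utils::head(out, topN)
    rownames(out) <- NULL
    out
}
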