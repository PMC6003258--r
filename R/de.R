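#' Method-of-moments negative-binomial dispersion estimates
#'
#' Per-gene dispersion \eqn{\phi} estimated on normalized counts from the
#' within-group excess of variance over the mean
#' (\eqn{Var = \mu + \phi \mu^2}), floored at 0, and shrunk toward the
#' common dispersion (a trimmed mean over genes) with weight \code{shrink}.
#' Three replicates give very noisy per-gene moments; the shrinkage is what
#' makes the estimates usable in the exact test.
#'
#' @param counts normalized count matrix (genes x samples).
#' @param groups factor of group labels per sample, each with >= 2 samples.
#' @param shrink weight of the common dispersion in the shrunk estimate.
#' @param trim trim fraction of the common-dispersion trimmed mean.
#' @return list with \code{phi} (shrunk per-gene estimates), \code{raw}
#'   (unshrunk), and \code{common}.
#' @examples
#' te <- exampleTrio(n_genes = 500, seed = 1, dispersion = 0.1)
#' d <- estimateTrioDispersions(counts(te), trioLine(te))
#' d$common
#' @export
estimateTrioDispersions <- function(counts, groups, shrink = 0.5,
                                    trim = 0.2) {
    counts <- as.matrix(counts)
    groups <- as.factor(groups)
    tab <- table(groups)
    if (any(tab < 2L))
        stop("each group needs >= 2 replicates to estimate dispersions; ",
             "supply a fixed phi instead")
    num <- den <- numeric(nrow(counts))
    for (g in levels(groups)) {
        idx <- which(groups == g)
        mu <- rowMeans(counts[, idx, drop = FALSE])
        v <- apply(counts[, idx, drop = FALSE], 1L, stats::var)
        w <- length(idx) - 1L
        num <- num + w * (v - mu)
        den <- den + w * mu^2
    }
    raw <- ifelse(den > 0, pmax(0, num / den), 0)
    expressed <- rowMeans(counts) >= 1
    common <- if (any(expressed)) mean(raw[expressed], trim = trim) else 0
    list(phi = shrink * common + (1 - shrink) * raw, raw = raw,
         common = common)
}

#' Exact conditional negative-binomial test for two groups
#'
#' Tests equality of means between two groups of counts that have been
#' scaled to a common library size.  Conditional on the grand total
#' \eqn{T = S_1 + S_2}, the group-1 sum under the null (equal means,
#' dispersion \eqn{\phi}) follows the distribution obtained from two
#' independent NB sums with sizes \eqn{n_1/\phi} and \eqn{n_2/\phi}; the
#' two-sided p-value is the total probability of all outcomes no more
#' likely than the observed split.  With \eqn{\phi = 0} the conditional
#' law is Binomial\eqn{(T, n_1/(n_1+n_2))}.
#'
#' @param y1,y2 count vectors of the two groups (library-size adjusted,
#'   rounded to integers).
#' @param phi NB dispersion, \eqn{\phi \ge 0}.
#' @return two-sided p-value in (0, 1].
#' @examples
#' nbExactTest(c(10, 10, 10), c(10, 10, 10), phi = 0.1)   # 1
#' nbExactTest(c(30, 28, 35), c(10, 8, 12), phi = 0)
#' @export
nbExactTest <- function(y1, y2, phi) {
    if (phi < 0) stop("phi must be non-negative")
    s1 <- round(sum(y1))
    total <- s1 + round(sum(y2))
    .nbExactP(s1, total, length(y1), length(y2), phi)
}

## p-value for an observed group-1 sum s1 out of total, group sizes n1/n2.
.nbExactP <- function(s1, total, n1, n2, phi) {
    if (total == 0) return(1)
    s <- 0:total
    if (phi <= 0) {
        lp <- stats::dbinom(s, total, n1 / (n1 + n2), log = TRUE)
    } else {
        lp <- stats::dnbinom(s, size = n1 / phi, prob = 0.5, log = TRUE) +
            stats::dnbinom(total - s, size = n2 / phi, prob = 0.5,
                           log = TRUE)
        lp <- lp - .logSumExp(lp)
    }
    lobs <- lp[s1 + 1L]
    min(1, sum(exp(lp[lp <= lobs + 1e-8])))
}

.logSumExp <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), with input
#' validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of BH-adjusted values (FDR).
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the significance criteria FDR <= \code{alpha} and
#' |log2FC| >= \code{minL2fc} (both boundaries inclusive) to a DE result
#' table and labels each gene \code{up}, \code{down} or
#' \code{not_significant}.
#'
#' @param results data.frame/DataFrame with columns \code{logFC} and
#'   \code{fdr}.
#' @param alpha FDR threshold (default 0.05).
#' @param minL2fc minimum |log2 fold change| (default 1, i.e. 2-fold).
#' @return the input with a \code{call} column added.
#' @export
callDEGs <- function(results, alpha = 0.05, minL2fc = 1) {
    call <- rep("not_significant", nrow(results))
    sig <- results$fdr <= alpha
    call[sig & results$logFC >= minL2fc] <- "up"
    call[sig & results$logFC <= -minL2fc] <- "down"
    results$call <- call
    results
}

#' Differential expression between two trio lines
#'
#' Runs the full exact-test workflow for one contrast: scales each sample's
#' counts to the geometric-mean library size (rounded), estimates per-gene
#' dispersions (unless a fixed \eqn{\phi} is supplied), applies the exact
#' conditional NB test, adjusts with Benjamini-Hochberg, and calls DEGs.
#' \code{logFC} is log2 of the first contrast line over the second,
#' computed from normalized group means with a pseudocount added to both.
#'
#' @param object a \code{\link{TrioExperiment}}.
#' @param contrast two line labels, numerator first (default
#'   \code{c("F1", "P1")}).
#' @param alpha,minL2fc DEG thresholds, see \code{\link{callDEGs}}.
#' @param dispersion optional fixed \eqn{\phi} (single value or per-gene
#'   vector); when \code{NULL} it is estimated.
#' @param shrink,trim dispersion-shrinkage parameters, see
#'   \code{\link{estimateTrioDispersions}}.
#' @param pseudocount added to both group means for the fold change.
#' @param ... unused.
#' @return \code{DataFrame} with columns \code{gene}, \code{contrast},
#'   \code{baseMean}, \code{logFC}, \code{phi}, \code{p}, \code{fdr},
#'   \code{call}; thresholds in \code{metadata()}.
#' @examples
#' te <- exampleTrio(n_genes = 200, seed = 2)
#' de <- nbDifferentialExpression(te, c("F1", "P1"))
#' table(de$call)
#' @rdname nbDifferentialExpression
#' @export
setMethod("nbDifferentialExpression", "TrioExperiment",
          function(object, contrast = c("F1", "P1"), alpha = 0.05,
                   minL2fc = 1, dispersion = NULL, shrink = 0.5,
                   trim = 0.2, pseudocount = 0.5, ...) {
    stopifnot(length(contrast) == 2L, all(contrast %in% TRIO_LINES),
              contrast[1] != contrast[2])
    line <- trioLine(object)
    keep <- line %in% contrast
    cts <- assay(object, "counts")[, keep, drop = FALSE]
    grp <- factor(as.character(line[keep]), levels = contrast)
    lib <- colSums(cts)
    if (any(lib == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(cts)[lib == 0], collapse = ", "))
    common <- exp(mean(log(lib)))
    pseudo <- round(sweep(cts, 2L, common / lib, "*"))
    phi <- if (is.null(dispersion))
        estimateTrioDispersions(pseudo, grp, shrink = shrink, trim = trim)$phi
    else rep_len(dispersion, nrow(pseudo))
    idx1 <- grp == contrast[1]
    n1 <- sum(idx1); n2 <- sum(!idx1)
    s1 <- round(rowSums(pseudo[, idx1, drop = FALSE]))
    total <- s1 + round(rowSums(pseudo[, !idx1, drop = FALSE]))
    p <- vapply(seq_len(nrow(pseudo)), function(i)
        .nbExactP(s1[i], total[i], n1, n2, phi[i]), numeric(1))
    m1 <- s1 / n1
    m2 <- (total - s1) / n2
    res <- S4Vectors::DataFrame(
        gene = rownames(pseudo),
        contrast = paste0(contrast[1], "_vs_", contrast[2]),
        baseMean = (m1 + m2) / 2,
        logFC = log2((m1 + pseudocount) / (m2 + pseudocount)),
        phi = phi, p = p, fdr = bhAdjust(p),
        row.names = rownames(pseudo))
    res <- callDEGs(res, alpha = alpha, minL2fc = minL2fc)
    metadata(res) <- list(contrast = contrast, alpha = alpha,
                          minL2fc = minL2fc, pseudocount = pseudocount)
    res
})

#' Venn partition of DEG sets and the DG_HP / DG_PP summary
#'
#' Partitions the three DEG sets of a trio — F1 vs P1 (A), F1 vs P2 (B) and
#' P1 vs P2 (C) — into the seven Venn regions, and reports
#' \eqn{DG_{HP} = A \cup B} (hybrid-parent DEGs) and \eqn{DG_{PP} = C}
#' (parent-parent DEGs) together with their overlap.
#'
#' @param degF1P1,degF1P2,degP1P2 character vectors of gene ids.
#' @return list with \code{regions} (named 7-vector of exclusive region
#'   counts), \code{nDgHP}, \code{nDgPP}, \code{nOverlap}
#'   (\eqn{|DG_{HP} \cap DG_{PP}|}), \code{nUnion}, and the id sets
#'   \code{dgHP}, \code{dgPP}.
#' @examples
#' partitionDEGs(c("g1", "g2"), c("g2", "g3"), "g3")
#' @export
partitionDEGs <- function(degF1P1, degF1P2, degP1P2) {
    a <- unique(as.character(degF1P1))
    b <- unique(as.character(degF1P2))
    c_ <- unique(as.character(degP1P2))
    all <- union(union(a, b), c_)
    inA <- all %in% a; inB <- all %in% b; inC <- all %in% c_
    regions <- c(
        A_only = sum(inA & !inB & !inC),
        B_only = sum(!inA & inB & !inC),
        C_only = sum(!inA & !inB & inC),
        AB_only = sum(inA & inB & !inC),
        AC_only = sum(inA & !inB & inC),
        BC_only = sum(!inA & inB & inC),
        ABC = sum(inA & inB & inC))
    dgHP <- union(a, b)
    list(regions = regions,
         nDgHP = length(dgHP), nDgPP = length(c_),
         nOverlap = length(intersect(dgHP, c_)),
         nUnion = length(all),
         dgHP = dgHP, dgPP = c_)
}
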