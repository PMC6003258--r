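#' Additive/dominance effect decomposition for one gene
#'
#' Least-squares fit of the randomized-block model
#' \eqn{y = u + line + block + e} to a balanced trio (3 lines x r
#' replicates) and extraction of the composite genetic effects: the signed
#' additive effect \eqn{a = (\bar y_{P1} - \bar y_{P2})/2} and the
#' dominance effect \eqn{d = \bar y_{F1} - (\bar y_{P1} + \bar y_{P2})/2}.
#' The residual variance comes from the additive two-way fit with
#' \eqn{(3-1)(r-1)} degrees of freedom.
#'
#' @param y expression values for one gene, one per sample.
#' @param line line labels (\code{P1}/\code{P2}/\code{F1}) per sample.
#' @param replicate block index per sample; the design must be balanced
#'   (every line observed once in every block).
#' @return list with \code{u} (grand mean), \code{lineMeans},
#'   \code{aSigned}, \code{d}, \code{blockEffects}, \code{sigma2},
#'   \code{df}, \code{r}.
#' @examples
#' y <- c(10, 10, 20, 20, 25, 25)
#' estimateEffects(y, rep(c("P1", "P2", "F1"), each = 2), rep(1:2, 3))
#' @export
estimateEffects <- function(y, line, replicate) {
    line <- factor(as.character(line), levels = TRIO_LINES)
    block <- as.factor(replicate)
    if (anyNA(line)) stop("line labels must be P1, P2, F1")
    tab <- table(line, block)
    if (any(tab != 1L))
        stop("design must be balanced: each line once per replicate block")
    r <- nlevels(block)
    if (r < 2L) stop("at least 2 replicate blocks required")
    u <- mean(y)
    lineMeans <- vapply(split(y, line), mean, numeric(1))
    blockMeans <- vapply(split(y, block), mean, numeric(1))
    fitted <- lineMeans[as.character(line)] +
        blockMeans[as.character(block)] - u
    df <- (3L - 1L) * (r - 1L)
    sigma2 <- sum((y - fitted)^2) / df
    list(u = u, lineMeans = lineMeans,
         aSigned = unname((lineMeans["P1"] - lineMeans["P2"]) / 2),
         d = unname(lineMeans["F1"] -
                        (lineMeans["P1"] + lineMeans["P2"]) / 2),
         blockEffects = blockMeans - u,
         sigma2 = sigma2, df = df, r = r)
}

#' Dominance ratio Hp = [d] / [a]
#'
#' The potency ratio: the dominance effect over the magnitude of the
#' additive effect, so its sign carries the direction of dominance and is
#' invariant to which parent is labelled P1.  Degenerate parents
#' (\eqn{|a| \le eps}) yield signed infinity when a dominance effect is
#' present (over-dominance by definition: the hybrid leaves a parental
#' range of width zero) and 0 (additive) when both effects vanish.
#'
#' @param aSigned signed additive effect \eqn{(\bar P_1 - \bar P_2)/2}.
#' @param d dominance effect \eqn{\bar F_1 - MP}.
#' @param eps magnitude below which an effect counts as zero.
#' @return numeric Hp (possibly \code{Inf}/\code{-Inf}); vectorized.
#' @examples
#' dominanceRatio(-5, 5)    # 1
#' dominanceRatio(0, 3)     # Inf
#' @export
dominanceRatio <- function(aSigned, d, eps = 1e-8) {
    aMag <- abs(aSigned)
    ifelse(aMag > eps, d / aMag,
           ifelse(abs(d) > eps, sign(d) * Inf, 0))
}

#' Classify the mode of inheritance from Hp
#'
#' Band classification of the dominance ratio:
#' additive \eqn{(-0.2 < H_p \le 0.2)};
#' partial dominance \eqn{(-0.8 < H_p \le -0.2} or \eqn{0.2 < H_p \le 0.8)};
#' dominance \eqn{(-1.2 < H_p \le -0.8} or \eqn{0.8 < H_p \le 1.2)};
#' over-dominance \eqn{(H_p \le -1.2} or \eqn{H_p > 1.2)}.
#' The four bands partition the extended real line; infinite Hp is
#' over-dominance.
#'
#' @param hp numeric vector of dominance ratios.
#' @return factor with levels \code{additive}, \code{partial_dominance},
#'   \code{dominance}, \code{over_dominance}.
#' @examples
#' classifyMode(c(0, 0.2, -0.2, 1.2, 1.2000001, Inf))
#' @export
classifyMode <- function(hp) {
    mode <- character(length(hp))
    mode[hp > -0.2 & hp <= 0.2] <- "additive"
    mode[(hp > 0.2 & hp <= 0.8) | (hp > -0.8 & hp <= -0.2)] <-
        "partial_dominance"
    mode[(hp > 0.8 & hp <= 1.2) | (hp > -1.2 & hp <= -0.8)] <- "dominance"
    mode[hp > 1.2 | hp <= -1.2] <- "over_dominance"
    factor(mode, levels = INHERITANCE_MODES)
}

#' Confidence interval for the dominance-vs-additive contrast
#'
#' The classification is backed by a t-based confidence interval (default
#' level 99.8\%) for \eqn{[d] - [a]} when \eqn{d > 0} and \eqn{[d] + [a]}
#' when \eqn{d < 0} (at \eqn{d = 0} the \eqn{[d] - [a]} form is used).
#' In a balanced trio these contrasts equal \eqn{\bar y_{F1}} minus the
#' higher (resp. lower) parent mean, so their standard error is
#' \eqn{\sqrt{2\sigma^2 / r}}.
#'
#' @param estimate an \code{\link{estimateEffects}} result.
#' @param level confidence level, default 0.998.
#' @return list with \code{contrast} (\code{"d-a"} or \code{"d+a"}),
#'   \code{estimate}, \code{ciLow}, \code{ciHigh}, \code{confident}
#'   (does the CI exclude 0?).
#' @examples
#' eff <- estimateEffects(c(10, 11, 20, 21, 31, 30),
#'                        rep(c("P1", "P2", "F1"), each = 2), rep(1:2, 3))
#' effectCI(eff)
#' @export
effectCI <- function(estimate, level = 0.998) {
    if (estimate$df < 1L) stop("residual df must be >= 1")
    if (estimate$sigma2 < 0) stop("sigma2 must be >= 0")
    aMag <- abs(estimate$aSigned)
    d <- estimate$d
    est <- if (d >= 0) d - aMag else d + aMag
    se <- sqrt(2 * estimate$sigma2 / estimate$r)
    tcrit <- stats::qt(1 - (1 - level) / 2, df = estimate$df)
    ciLow <- est - tcrit * se
    ciHigh <- est + tcrit * se
    list(contrast = if (d >= 0) "d-a" else "d+a",
         estimate = est, ciLow = ciLow, ciHigh = ciHigh,
         confident = (ciLow > 0) || (ciHigh < 0))
}

#' Per-gene inheritance-mode calls for a trio
#'
#' For every gene: the additive/dominance decomposition
#' (\code{\link{estimateEffects}}), the dominance ratio
#' (\code{\link{dominanceRatio}}), the band classification
#' (\code{\link{classifyMode}}) and the contrast confidence interval
#' (\code{\link{effectCI}}).  By default the expression scale is linear —
#' size-factor-normalized counts for a \code{TrioExperiment}, or any
#' matrix you pass (e.g. FPKM); \code{log2 = TRUE} analyses
#' \code{log2(x + 1)}.
#'
#' @param object a \code{\link{TrioExperiment}} or an expression matrix.
#' @param genes optional gene ids to classify (e.g. the DG_HP set);
#'   default all genes.
#' @param line,replicate design vectors (matrix method).
#' @param level CI level, default 0.998.
#' @param eps zero-effect tolerance of \code{\link{dominanceRatio}}.
#' @param log2 analyse on the log2(x+1) scale?
#' @param ... unused.
#' @return \code{DataFrame}: \code{gene}, \code{a} (signed), \code{d},
#'   \code{Hp}, \code{mode}, \code{ciLow}, \code{ciHigh}, \code{confident}.
#' @examples
#' te <- exampleTrio(n_genes = 100, seed = 4)
#' calls <- inheritanceModes(te)
#' modeSummary(calls)
#' @rdname inheritanceModes
#' @export
setMethod("inheritanceModes", "matrix",
          function(object, line, replicate, genes = NULL, level = 0.998,
                   eps = 1e-8, log2 = FALSE, ...) {
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(object))
        if (length(missing))
            stop("gene(s) not in matrix: ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        object <- object[genes, , drop = FALSE]
    }
    if (log2) object <- base::log2(object + 1)
    n <- nrow(object)
    a <- d <- hp <- ciLow <- ciHigh <- numeric(n)
    confident <- logical(n)
    for (i in seq_len(n)) {
        eff <- estimateEffects(object[i, ], line, replicate)
        ci <- effectCI(eff, level = level)
        a[i] <- eff$aSigned; d[i] <- eff$d
        hp[i] <- dominanceRatio(eff$aSigned, eff$d, eps = eps)
        ciLow[i] <- ci$ciLow; ciHigh[i] <- ci$ciHigh
        confident[i] <- ci$confident
    }
    res <- S4Vectors::DataFrame(
        gene = rownames(object), a = a, d = d, Hp = hp,
        mode = classifyMode(hp), ciLow = ciLow, ciHigh = ciHigh,
        confident = confident, row.names = rownames(object))
    metadata(res) <- list(level = level, eps = eps, log2 = log2)
    res
})

#' @describeIn inheritanceModes analyses FPKM when gene lengths are stored
#'   (counts per million otherwise); per-gene length factors cancel in
#'   \eqn{H_p}, and total-count scaling is robust to genome-wide
#'   differential expression, unlike median-of-ratios factors.
#' @export
setMethod("inheritanceModes", "TrioExperiment",
          function(object, genes = NULL, level = 0.998, eps = 1e-8,
                   log2 = FALSE, ...) {
    expr <- if (!is.null(geneLengths(object)))
        assay(fpkm(object), "fpkm")
    else sweep(assay(object, "counts"), 2L,
               colSums(assay(object, "counts")) / 1e6, "/")
    inheritanceModes(expr,
                     line = trioLine(object),
                     replicate = trioReplicate(object),
                     genes = genes, level = level, eps = eps, log2 = log2)
})

#' Mode-of-inheritance composition
#'
#' Fraction of genes in each of the four inheritance modes.
#'
#' @param calls an \code{\link{inheritanceModes}} result, or a factor /
#'   character vector of modes.
#' @return named numeric vector over the four modes, summing to 1.
#' @examples
#' modeSummary(rep(c("over_dominance", "additive"), c(6, 4)))
#' @export
modeSummary <- function(calls) {
    mode <- if (is.data.frame(calls) || methods::is(calls, "DataFrame"))
        calls$mode else calls
    mode <- factor(as.character(mode), levels = INHERITANCE_MODES)
    if (!length(mode)) stop("no calls supplied")
    tab <- prop.table(table(mode))
    stats::setNames(as.numeric(tab[INHERITANCE_MODES]), INHERITANCE_MODES)
}
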