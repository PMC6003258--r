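#' Mid-parent heterosis
#'
#' Percent deviation of the F1 hybrid from the mid-parent value,
#' \eqn{100 (F_1 - MP) / MP} with \eqn{MP = (\bar P_1 + \bar P_2)/2}.
#'
#' @param f1Mean,p1Mean,p2Mean line means of the trait.
#' @return MPH in percent.
#' @examples
#' midParentHeterosis(42.8, 29.89, 34.8)   # yield per plant: 32.32%
#' @export
midParentHeterosis <- function(f1Mean, p1Mean, p2Mean) {
    mp <- (p1Mean + p2Mean) / 2
    if (any(mp == 0)) stop("mid-parent value is zero; MPH undefined")
    100 * (f1Mean - mp) / mp
}

#' High-parent (better-parent) heterosis
#'
#' Percent deviation of the F1 hybrid from the better parent,
#' \eqn{100 (F_1 - BP) / BP}.  The better parent is the higher-mean parent
#' by default; set \code{higherIsBetter = FALSE} for traits where lower
#' values are favourable.
#'
#' @param f1Mean,p1Mean,p2Mean line means of the trait.
#' @param higherIsBetter is a larger trait value better?
#' @return HPH in percent.
#' @examples
#' highParentHeterosis(42.8, 29.89, 34.8)  # yield per plant: 22.99%
#' @export
highParentHeterosis <- function(f1Mean, p1Mean, p2Mean,
                                higherIsBetter = TRUE) {
    bp <- if (higherIsBetter) pmax(p1Mean, p2Mean) else pmin(p1Mean, p2Mean)
    if (any(bp == 0)) stop("better-parent value is zero; HPH undefined")
    100 * (f1Mean - bp) / bp
}

#' Heterosis table from replicated trait measurements
#'
#' Computes, for every trait in a replicated trait table, the line means,
#' mid-parent and better-parent values, MPH and HPH percentages, and
#' two-sided Welch t-test p-values.  \code{p_mph} tests the F1 replicate
#' values against per-replicate mid-parent values \eqn{(P_{1k}+P_{2k})/2}
#' paired by replicate index; \code{p_hph} tests them against the better
#' parent's replicates.
#'
#' @param traits data.frame with columns \code{trait}, \code{line}
#'   (\code{P1}/\code{P2}/\code{F1}), \code{replicate}, \code{value}.
#' @param higherIsBetter single flag or named logical vector per trait.
#' @return data.frame with one row per trait: line means, \code{MP},
#'   \code{BP}, \code{MPH}, \code{HPH} (percent, full precision),
#'   \code{p_mph}, \code{p_hph} and significance stars
#'   (\code{*} p<0.05, \code{**} p<0.01).
#' @examples
#' tt <- simulateTraits(nReplicates = 5, seed = 2)
#' head(heterosisTable(tt))
#' @export
heterosisTable <- function(traits, higherIsBetter = TRUE) {
    stopifnot(all(c("trait", "line", "replicate", "value") %in%
                  colnames(traits)))
    if (any(!is.finite(traits$value)))
        stop("trait values must be finite")
    traitNames <- unique(traits$trait)
    hib <- if (length(higherIsBetter) == 1L)
        stats::setNames(rep(higherIsBetter, length(traitNames)), traitNames)
    else higherIsBetter
    rows <- lapply(traitNames, function(tr) {
        sub <- traits[traits$trait == tr, , drop = FALSE]
        present <- TRIO_LINES %in% sub$line
        if (!all(present)) {
            warning(sprintf("trait '%s' skipped: missing line(s) %s", tr,
                            paste(TRIO_LINES[!present], collapse = ", ")))
            return(NULL)
        }
        vals <- lapply(TRIO_LINES, function(l) {
            v <- sub[sub$line == l, , drop = FALSE]
            v <- v[order(v$replicate), ]
            v$value
        })
        names(vals) <- TRIO_LINES
        means <- vapply(vals, mean, numeric(1))
        mp <- (means["P1"] + means["P2"]) / 2
        better <- if (hib[[tr]]) {
            if (means["P1"] >= means["P2"]) "P1" else "P2"
        } else {
            if (means["P1"] <= means["P2"]) "P1" else "P2"
        }
        bp <- means[[better]]
        r <- min(lengths(vals))
        mpReps <- (vals$P1[seq_len(r)] + vals$P2[seq_len(r)]) / 2
        pMph <- .welchP(vals$F1, mpReps)
        pHph <- .welchP(vals$F1, vals[[better]])
        data.frame(trait = tr,
                   mean_P1 = means[["P1"]], mean_P2 = means[["P2"]],
                   mean_F1 = means[["F1"]], MP = unname(mp), BP = bp,
                   MPH = midParentHeterosis(means[["F1"]], means[["P1"]],
                                            means[["P2"]]),
                   HPH = 100 * (means[["F1"]] - bp) / bp,
                   p_mph = pMph, p_hph = pHph,
                   sig_mph = .stars(pMph), sig_hph = .stars(pHph),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(trait = character(0))
    rownames(out) <- NULL
    out
}

## Welch two-sided t-test p, with the zero-variance/zero-difference
## boundary mapped to p = 1 (statistic 0).
.welchP <- function(x, y) {
    if (stats::var(x) + stats::var(y) == 0)
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
}

.stars <- function(p) {
    if (is.na(p)) return("")
    if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
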