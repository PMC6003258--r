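#' Simulation configuration for a heterosis trio
#'
#' Holds every knob of the negative-binomial trio simulator.  Per-gene line
#' means are placed on the linear count scale as
#' \eqn{\mu_{P1} = m + a}, \eqn{\mu_{P2} = m - a},
#' \eqn{\mu_{F1} = m + H_p |a|}, where the true dominance ratio \eqn{H_p} is
#' drawn uniformly inside the band of the gene's assigned inheritance mode,
#' so the truth is exact by construction.  Counts are drawn
#' NB(mean, \eqn{\phi}) with variance \eqn{\mu + \phi \mu^2}
#' (Poisson when \eqn{\phi = 0}).
#'
#' @param nGenes number of genes (rows).
#' @param nReplicates replicates per line; at least 2 (the trio design the
#'   simulator emulates uses 3).
#' @param modeFractions named proportions over the four inheritance modes
#'   (\code{additive}, \code{partial_dominance}, \code{dominance},
#'   \code{over_dominance}); must sum to 1.  The default reproduces the
#'   over-dominance-heavy composition typical of hybrid-rice panicle
#'   transcriptomes.
#' @param baseMean expected mid-parent count \eqn{m}; per-gene means are
#'   drawn uniformly in \code{[0.5, 1.5] * baseMean}.
#' @param effectScale half-parent-difference \eqn{|a|} in count units;
#'   per-gene magnitudes are drawn uniformly in
#'   \code{[0.5, 1.5] * effectScale} and capped at \eqn{0.8 m / \max(1,|H_p|)}
#'   so that all three line means stay strictly positive and the planted
#'   \eqn{H_p} remains exact.  The default (twice \code{baseMean}) makes the
#'   cap bind, i.e. parents diverge strongly at every gene — the regime in
#'   which mode recovery is informative; lower it for weaker parental
#'   divergence.
#' @param dispersion NB dispersion \eqn{\phi \ge 0}; 0 gives Poisson counts.
#' @param blockEffectSd SD of the log-normal multiplicative replicate (block)
#'   effect shared by all genes of a sample; 0 disables block effects.
#' @param libSizeRange two positive integers; each sample's library size is
#'   drawn uniformly between them and enters the mean as
#'   \code{libSize / mean(libSizeRange)}.
#' @param bandMargin distance kept between sampled \eqn{H_p} values and the
#'   classification band edges, clamped per band to 45\% of the band width
#'   (the additive and dominance bands are only 0.4 wide, so a large
#'   requested margin concentrates them near the band centre).
#' @param hpMax upper bound for sampled over-dominant \eqn{|H_p|}.
#' @param seed integer RNG seed; identical configs reproduce identical
#'   output.
#'
#' @return A \code{SimConfig} object.
#' @examples
#' cfg <- simConfig(nGenes = 100, seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L, nReplicates = 3L,
                      modeFractions = c(additive = 0.040,
                                        partial_dominance = 0.156,
                                        dominance = 0.173,
                                        over_dominance = 0.631),
                      baseMean = 500, effectScale = 2 * baseMean,
                      dispersion = 0.05, blockEffectSd = 0.05,
                      libSizeRange = c(900000L, 1100000L),
                      bandMargin = 0.05, hpMax = 2.5, seed = 1L) {
    new("SimConfig", nGenes = as.integer(nGenes),
        nReplicates = as.integer(nReplicates),
        modeFractions = modeFractions, baseMean = as.numeric(baseMean),
        effectScale = as.numeric(effectScale),
        dispersion = as.numeric(dispersion),
        blockEffectSd = as.numeric(blockEffectSd),
        libSizeRange = as.numeric(libSizeRange),
        bandMargin = as.numeric(bandMargin), hpMax = as.numeric(hpMax),
        seed = as.integer(seed))
}

#' @rdname simConfig
#' @export
setClass("SimConfig", representation(
    nGenes = "integer", nReplicates = "integer", modeFractions = "numeric",
    baseMean = "numeric", effectScale = "numeric", dispersion = "numeric",
    blockEffectSd = "numeric", libSizeRange = "numeric",
    bandMargin = "numeric", hpMax = "numeric", seed = "integer"))

INHERITANCE_MODES <- c("additive", "partial_dominance", "dominance",
                       "over_dominance")

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
    if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
    mf <- object@modeFractions
    if (!setequal(names(mf), INHERITANCE_MODES))
        msg <- c(msg, sprintf("modeFractions must be named by {%s}",
                              paste(INHERITANCE_MODES, collapse = ", ")))
    else if (abs(sum(mf) - 1) > 1e-9)
        msg <- c(msg, "modeFractions must sum to 1 (tolerance 1e-9)")
    if (any(mf < 0)) msg <- c(msg, "modeFractions must be non-negative")
    if (object@baseMean <= 0) msg <- c(msg, "baseMean must be positive")
    if (object@effectScale <= 0) msg <- c(msg, "effectScale must be positive")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (object@blockEffectSd < 0) msg <- c(msg, "blockEffectSd must be >= 0")
    if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0) ||
        diff(object@libSizeRange) < 0)
        msg <- c(msg, "libSizeRange must be two positive increasing numbers")
    if (object@bandMargin < 0) msg <- c(msg, "bandMargin must be >= 0")
    if (object@hpMax <= 1.2) msg <- c(msg, "hpMax must exceed 1.2")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x 3 lines x",
        object@nReplicates, "replicates\n")
    cat("  baseMean", object@baseMean, " effectScale", object@effectScale,
        " dispersion", object@dispersion, " blockEffectSd",
        object@blockEffectSd, "\n")
    cat("  modeFractions:",
        paste(sprintf("%s=%.3f", names(object@modeFractions),
                      object@modeFractions), collapse = " "), "\n")
    cat("  seed", object@seed, "\n")
})

## Hp sampling intervals per mode: (lo, hi) on the positive side; the sign
## is drawn separately except for the (symmetric) additive band.
.hpBandInterval <- function(mode, margin, hpMax) {
    band <- switch(mode,
        additive = c(-0.2, 0.2),
        partial_dominance = c(0.2, 0.8),
        dominance = c(0.8, 1.2),
        over_dominance = c(1.2, hpMax))
    m <- min(margin, 0.45 * diff(band))
    c(band[1] + m, band[2] - if (mode == "over_dominance") 0 else m)
}

.sampleHp <- function(modes, margin, hpMax) {
    hp <- numeric(length(modes))
    sign <- ifelse(stats::runif(length(modes)) < 0.5, -1, 1)
    for (mode in INHERITANCE_MODES) {
        idx <- which(modes == mode)
        if (!length(idx)) next
        iv <- .hpBandInterval(mode, margin, hpMax)
        if (mode == "additive") {
            hp[idx] <- stats::runif(length(idx), -iv[2], iv[2])
        } else {
            hp[idx] <- sign[idx] * stats::runif(length(idx), iv[1], iv[2])
        }
    }
    hp
}

#' Simulate a trio count matrix with known inheritance-mode truth
#'
#' Draws negative-binomial counts for P1, P2 and F1 replicates with per-gene
#' additive and dominance effects planted on the linear count scale so that
#' the true dominance ratio of every gene lies inside the band of its
#' assigned mode.  Ground truth (\code{true_a}, \code{true_d},
#' \code{true_Hp}, \code{true_mode}) and simulated gene lengths are stored
#' in \code{rowData}; library sizes and block factors in \code{colData}.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return a \code{\link{TrioExperiment}}.
#' @examples
#' te <- simulateTrioCounts(simConfig(nGenes = 200, seed = 3))
#' head(rowData(te))
#' @export
simulateTrioCounts <- function(config) {
    validObject(config)
    set.seed(config@seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    G <- config@nGenes
    r <- config@nReplicates
    nS <- 3L * r
    line <- factor(rep(TRIO_LINES, each = r), levels = TRIO_LINES)
    repl <- rep(seq_len(r), times = 3L)
    sampleIds <- paste0(line, "_rep", repl)

    if (G == 0L) {
        cts <- matrix(integer(0), nrow = 0L, ncol = nS,
                      dimnames = list(NULL, sampleIds))
        return(TrioExperiment(cts, line, repl,
                              metadata = list(simConfig = config)))
    }

    mode <- sample(INHERITANCE_MODES, G, replace = TRUE,
                   prob = config@modeFractions[INHERITANCE_MODES])
    hp <- .sampleHp(mode, config@bandMargin, config@hpMax)
    m <- stats::runif(G, 0.5, 1.5) * config@baseMean
    aMag <- pmin(stats::runif(G, 0.5, 1.5) * config@effectScale,
                 0.8 * m / pmax(1, abs(hp)))
    aSign <- ifelse(stats::runif(G) < 0.5, -1, 1)
    a <- aSign * aMag
    d <- hp * aMag
    floorMean <- 0.1
    muLine <- cbind(P1 = pmax(m + a, floorMean),
                    P2 = pmax(m - a, floorMean),
                    F1 = pmax(m + d, floorMean))

    libSize <- round(stats::runif(nS, config@libSizeRange[1],
                                  config@libSizeRange[2]))
    libFactor <- libSize / mean(config@libSizeRange)
    blockFactor <- if (config@blockEffectSd > 0)
        exp(stats::rnorm(nS, 0, config@blockEffectSd)) else rep(1, nS)

    mu <- muLine[, as.character(line), drop = FALSE] *
        rep(libFactor * blockFactor, each = G)
    cts <- if (config@dispersion > 0)
        matrix(stats::rnbinom(G * nS, mu = mu, size = 1 / config@dispersion),
               nrow = G)
    else matrix(stats::rpois(G * nS, lambda = mu), nrow = G)
    dimnames(cts) <- list(sprintf("gene%05d", seq_len(G)), sampleIds)

    rowData <- S4Vectors::DataFrame(
        length = round(stats::runif(G, 500, 5000)),
        true_m = m, true_a = a, true_d = d, true_Hp = hp,
        true_mode = mode)
    te <- TrioExperiment(cts, line, repl, rowData = rowData,
                         metadata = list(simConfig = config))
    colData(te)$libSize <- libSize
    colData(te)$blockFactor <- blockFactor
    te
}

#' Small simulated trio for examples
#'
#' @param n_genes,seed forwarded to \code{\link{simConfig}}.
#' @param ... further \code{simConfig} arguments.
#' @return a \code{\link{TrioExperiment}}.
#' @export
exampleTrio <- function(n_genes = 100, seed = 1L, ...)
    simulateTrioCounts(simConfig(nGenes = n_genes, seed = seed, ...))

#' Replicated panicle trait measurements of the WFYT025 trio
#'
#' Line means and standard deviations of ten yield-related panicle traits
#' for the super-hybrid rice combination WFYT025 (F1) and its parents
#' CHT025 (P1) and WFB (P2), used as the default specification of
#' \code{\link{simulateTraits}}.
#'
#' @return data.frame with columns \code{trait}, \code{line}, \code{mean},
#'   \code{sd}.
#' @examples
#' head(panicleTraitSpecs())
#' @export
panicleTraitSpecs <- function() {
    traits <- c("spike_length_cm", "primary_branch_number",
                "secondary_branch_number", "solid_grain_number",
                "total_grain_number", "empty_grain_number",
                "seed_setting_ratio_pct", "thousand_grain_weight_g",
                "tiller", "yield_per_plant_g")
    means <- rbind(
        P1 = c(23.24, 12.89, 49.26, 227.40, 251.36, 23.95, 89.65, 18.64,
               6.8, 29.89),
        F1 = c(24.34, 11.45, 45.67, 221.43, 247.08, 25.65, 89.04, 22.44,
               8.7, 42.8),
        P2 = c(19.61, 8.46, 26.51, 141.42, 151.21, 9.78, 93.05, 23.60,
               10.4, 34.8))
    sds <- rbind(
        P1 = c(1.75, 1.45, 9.66, 42.72, 40.39, 6.52, 0.04, 0.92, 0.92, 7.02),
        F1 = c(0.67, 1.00, 5.44, 18.30, 21.20, 10.68, 4.29, 0.63, 1.25, 2.80),
        P2 = c(1.71, 1.26, 5.21, 17.60, 17.89, 2.49, 1.62, 0.34, 2.50, 6.89))
    data.frame(
        trait = rep(traits, each = 3L),
        line = rep(c("P1", "F1", "P2"), times = length(traits)),
        mean = as.vector(means[c("P1", "F1", "P2"), ]),
        sd = as.vector(sds[c("P1", "F1", "P2"), ]),
        stringsAsFactors = FALSE)
}

#' Simulate a replicated trait table
#'
#' Normal draws per trait, line and replicate around the specified line
#' means.
#'
#' @param specs data.frame with columns \code{trait}, \code{line},
#'   \code{mean}, \code{sd} (one row per trait/line); defaults to
#'   \code{\link{panicleTraitSpecs}}.
#' @param nReplicates replicates per line, at least 2.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{trait}, \code{line},
#'   \code{replicate}, \code{value}.
#' @examples
#' tt <- simulateTraits(nReplicates = 3, seed = 1)
#' head(tt)
#' @export
simulateTraits <- function(specs = panicleTraitSpecs(), nReplicates = 3L,
                           seed = 1L) {
    stopifnot(all(c("trait", "line", "mean", "sd") %in% colnames(specs)))
    if (any(specs$sd < 0)) stop("trait SDs must be non-negative")
    if (nReplicates < 2L) stop("nReplicates must be >= 2")
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    n <- nrow(specs)
    out <- data.frame(
        trait = rep(specs$trait, each = nReplicates),
        line = rep(specs$line, each = nReplicates),
        replicate = rep(seq_len(nReplicates), times = n),
        value = stats::rnorm(n * nReplicates,
                             mean = rep(specs$mean, each = nReplicates),
                             sd = rep(specs$sd, each = nReplicates)),
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Simulate gene models, a QTL panel and a term map with planted truth
#'
#' Genes are laid out round-robin over \code{nChromosomes} chromosomes as
#' non-overlapping 1-based inclusive intervals.  Each QTL interval is placed
#' over a contiguous run of genes on one chromosome, so the set of genes
#' falling inside each QTL is known exactly and returned as truth.  Terms
#' are random gene subsets of the requested sizes.
#'
#' @param nGenes number of gene models.
#' @param nChromosomes number of chromosomes (default 12, the rice karyotype).
#' @param nQtl number of QTL intervals.
#' @param termSizes integer vector of term sizes for the simulated term map.
#' @param genesPerQtl range of genes covered per QTL.
#' @param seed integer RNG seed.
#' @return list with \code{genes} (GRanges, \code{gene_id} metadata),
#'   \code{qtls} (GRanges with \code{qtl_id}, \code{trait}, \code{markers}),
#'   \code{termMap} (named list of gene-id vectors with a \code{description}
#'   attribute per term), and \code{truth} (named list: QTL id to the gene
#'   ids planted inside it).
#' @examples
#' gf <- simulateGenomeFeatures(nGenes = 100, nQtl = 5, seed = 2)
#' gf$qtls
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
simulateGenomeFeatures <- function(nGenes, nChromosomes = 12L, nQtl = 10L,
                                   termSizes = rep(10L, 20L),
                                   genesPerQtl = c(1L, 4L), seed = 1L) {
    if (nChromosomes < 1L) stop("nChromosomes must be >= 1")
    if (nQtl < 0L) stop("nQtl must be >= 0")
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    geneIds <- sprintf("gene%05d", seq_len(nGenes))
    chrom <- paste0("chr", rep_len(seq_len(nChromosomes), nGenes))
    width <- round(stats::runif(nGenes, 500, 5000))
    gap <- round(stats::runif(nGenes, 1000, 20000))
    start <- integer(nGenes)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        start[idx] <- cumsum(gap[idx]) +
            c(0, cumsum(width[idx])[-length(idx)]) + 1L
    }
    genes <- GRanges(chrom, IRanges(start, width = width),
                     gene_id = geneIds)

    qtls <- GRanges()
    truth <- list()
    if (nQtl > 0L && nGenes > 0L) {
        traitCodes <- c("GPP", "GW", "SNP", "YD")
        qStart <- qEnd <- integer(nQtl)
        qChrom <- character(nQtl)
        truth <- vector("list", nQtl)
        for (q in seq_len(nQtl)) {
            ch <- sample(unique(chrom), 1L)
            idx <- which(chrom == ch)
            k <- min(sample(seq(genesPerQtl[1], genesPerQtl[2]), 1L),
                     length(idx))
            first <- sample(seq_len(length(idx) - k + 1L), 1L)
            run <- idx[first:(first + k - 1L)]
            qChrom[q] <- ch
            qStart[q] <- max(1L, min(start[run]) - 500L)
            qEnd[q] <- max(start[run] + width[run] - 1L) + 500L
            truth[[q]] <- geneIds[run]
        }
        qtlIds <- sprintf("qSIM-%02d", seq_len(nQtl))
        qtls <- GRanges(qChrom, IRanges(qStart, qEnd),
                        qtl_id = qtlIds,
                        trait = sample(traitCodes, nQtl, replace = TRUE),
                        markers = sprintf("RM%03d-RM%03d",
                                          sample(999, nQtl, replace = TRUE),
                                          sample(999, nQtl, replace = TRUE)))
        names(truth) <- qtlIds
        ## QTL placement can incidentally cover extra genes beyond the
        ## planted run; record the full contained set as truth.
        ov <- GenomicRanges::findOverlaps(genes, qtls)
        truth <- split(geneIds[S4Vectors::queryHits(ov)],
                       qtlIds[S4Vectors::subjectHits(ov)])
        truth <- truth[qtlIds[qtlIds %in% names(truth)]]
    }

    termMap <- list()
    if (length(termSizes) && nGenes > 0L) {
        termMap <- lapply(seq_along(termSizes), function(i) {
            ids <- sample(geneIds, min(termSizes[i], nGenes))
            attr(ids, "description") <- sprintf("simulated term %d", i)
            ids
        })
        names(termMap) <- sprintf("TERM:%04d", seq_along(termSizes))
    }
    list(genes = genes, qtls = qtls, termMap = termMap, truth = truth)
}
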