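suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(GenomicRanges)
})

## a tiny balanced trio count matrix with explicit line means
makeTrioMatrix <- function(means = c(P1 = 100, P2 = 200, F1 = 150),
                           r = 3, nGenes = 1, noise = 0, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    line <- rep(c("P1", "P2", "F1"), each = r)
    mu <- matrix(rep(means[line], each = nGenes), nrow = nGenes)
    cts <- if (noise > 0) matrix(rpois(length(mu), mu), nrow = nGenes)
           else round(mu)
    rownames(cts) <- sprintf("g%03d", seq_len(nGenes))
    colnames(cts) <- paste0(line, "_", rep(seq_len(r), 3))
    list(counts = cts, line = line, replicate = rep(seq_len(r), 3))
}

## null trio: every line at the same mean
nullTrio <- function(nGenes = 2000, mu = 100, phi = 0.1, r = 3) {
    cts <- matrix(rnbinom(nGenes * 3 * r, mu = mu, size = 1 / phi),
                  nGenes, 3 * r)
    TrioExperiment(cts, rep(c("P1", "P2", "F1"), each = r))
}

## Table-1-style line means/SDs for the yield-per-plant trait
yieldSpecs <- function() data.frame(
    trait = "yield_per_plant_g", line = c("P1", "F1", "P2"),
    mean = c(29.89, 42.8, 34.8), sd = c(7.02, 2.80, 6.89))

figModeFractions <- c(additive = 0.040, partial_dominance = 0.156,
                      dominance = 0.173, over_dominance = 0.631)
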