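test_that("identical config and seed reproduce identical output", {
    cfg <- simConfig(nGenes = 150, seed = 11)
    te1 <- simulateTrioCounts(cfg)
    te2 <- simulateTrioCounts(cfg)
    expect_identical(assay(te1, "counts"), assay(te2, "counts"))
    expect_identical(as.data.frame(rowData(te1)), as.data.frame(rowData(te2)))
    tt1 <- simulateTraits(nReplicates = 4, seed = 5)
    tt2 <- simulateTraits(nReplicates = 4, seed = 5)
    expect_identical(tt1, tt2)
    gf1 <- simulateGenomeFeatures(nGenes = 80, nQtl = 6, seed = 9)
    gf2 <- simulateGenomeFeatures(nGenes = 80, nQtl = 6, seed = 9)
    expect_identical(as.data.frame(gf1$genes), as.data.frame(gf2$genes))
    expect_identical(as.data.frame(gf1$qtls), as.data.frame(gf2$qtls))
    expect_identical(gf1$termMap, gf2$termMap)
})

test_that("degenerate and invalid simulator configs are handled", {
    te <- simulateTrioCounts(simConfig(nGenes = 0, seed = 1))
    expect_equal(nrow(te), 0L)
    expect_equal(ncol(te), 9L)
    bad <- figModeFractions
    bad["additive"] <- bad["additive"] + 0.1
    expect_error(simConfig(modeFractions = bad), "sum to 1")
    expect_error(simConfig(nReplicates = 1), "nReplicates")
    expect_error(simConfig(dispersion = -0.1), "dispersion")
    expect_error(simConfig(baseMean = 0), "baseMean")
    expect_error(simulateTraits(nReplicates = 1), "nReplicates")
    sp <- yieldSpecs(); sp$sd[1] <- -1
    expect_error(simulateTraits(sp), "non-negative")
    expect_error(simulateGenomeFeatures(10, nChromosomes = 0), "nChromosomes")
})

test_that("planted truth is self-consistent with the Hp bands", {
    for (margin in c(0, 0.05, 0.3)) {
        te <- simulateTrioCounts(simConfig(nGenes = 400, bandMargin = margin,
                                           seed = 21))
        rd <- rowData(te)
        expect_identical(as.character(classifyMode(rd$true_Hp)),
                         as.character(rd$true_mode))
        ## Hp is exact by construction: d / |a| on the planted means
        expect_equal(rd$true_Hp, rd$true_d / abs(rd$true_a), tolerance = 1e-12)
    }
})

test_that("per-line sample means converge to the planted line means", {
    cfg <- simConfig(nGenes = 300, nReplicates = 200, baseMean = 1000,
                     dispersion = 0, blockEffectSd = 0,
                     libSizeRange = c(1e6, 1e6), seed = 33)
    te <- simulateTrioCounts(cfg)
    rd <- rowData(te)
    mu <- cbind(P1 = rd$true_m + rd$true_a, P2 = rd$true_m - rd$true_a,
                F1 = rd$true_m + rd$true_d)
    line <- trioLine(te)
    ok <- TRUE
    for (l in levels(line)) {
        emp <- rowMeans(assay(te, "counts")[, line == l, drop = FALSE])
        ok <- ok & (abs(emp - mu[, l]) / mu[, l] < 0.05)
    }
    expect_gte(mean(ok), 0.99)
})

test_that("trait simulation honours zero-SD and matches specified means", {
    sp <- yieldSpecs(); sp$sd[] <- 0
    tt <- simulateTraits(sp, nReplicates = 5, seed = 2)
    expect_equal(tt$value, rep(sp$mean, each = 5))
    big <- simulateTraits(yieldSpecs(), nReplicates = 10000, seed = 3)
    m <- tapply(big$value, big$line, mean)
    sp <- yieldSpecs()
    expect_true(all(abs(m[sp$line] - sp$mean) / sp$mean < 0.02))
})

test_that("simulated gene models are non-overlapping and QTL truth is exact", {
    gf <- simulateGenomeFeatures(nGenes = 120, nQtl = 8, seed = 4)
    byChrom <- split(gf$genes, as.character(seqnames(gf$genes)))
    for (gr in byChrom) {
        gr <- sort(gr)
        if (length(gr) > 1)
            expect_true(all(start(gr)[-1] > end(gr)[-length(gr)]))
    }
    expect_true(all(start(gf$genes) >= 1))
    ## planted gene sets are exactly what interval overlap recovers
    co <- qtlColocalization(gf$genes, gf$qtls)
    rec <- split(co$gene, co$qtl_id)
    expect_identical(lapply(rec, sort),
                     lapply(gf$truth[names(rec)], sort))
    expect_setequal(names(rec), names(gf$truth))
    empty <- simulateGenomeFeatures(nGenes = 50, nQtl = 0, seed = 1)
    expect_length(empty$qtls, 0)
    expect_identical(nrow(qtlColocalization(empty$genes, empty$qtls)), 0L)
})
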