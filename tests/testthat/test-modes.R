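test_that("effect decomposition is exact on noiseless line means", {
    tm <- makeTrioMatrix(c(P1 = 10, P2 = 20, F1 = 15), r = 2)
    eff <- estimateEffects(tm$counts[1, ], tm$line, tm$replicate)
    expect_equal(eff$aSigned, -5)
    expect_equal(eff$d, 0)
    expect_equal(eff$sigma2, 0)
    tm2 <- makeTrioMatrix(c(P1 = 10, P2 = 20, F1 = 25), r = 3)
    eff2 <- estimateEffects(tm2$counts[1, ], tm2$line, tm2$replicate)
    expect_equal(eff2$d, 10)
    expect_equal(abs(eff2$aSigned), 5)
    expect_equal(eff2$df, 4L)
})

test_that("effect estimates equal a brute-force least-squares fit", {
    set.seed(25)
    line <- rep(c("P1", "P2", "F1"), each = 3)
    block <- factor(rep(1:3, 3))
    for (i in 1:50) {
        y <- rnorm(9, 100, 20)
        eff <- estimateEffects(y, line, block)
        fit <- lm(y ~ factor(line, levels = c("P1", "P2", "F1")) + block)
        pred <- predict(fit)
        lineMeans <- tapply(pred, line, mean)
        expect_equal(eff$aSigned,
                     unname((lineMeans["P1"] - lineMeans["P2"]) / 2))
        expect_equal(eff$d,
                     unname(lineMeans["F1"] -
                            (lineMeans["P1"] + lineMeans["P2"]) / 2))
        expect_equal(eff$sigma2, summary(fit)$sigma^2)
        expect_equal(eff$df, fit$df.residual)
    }
    expect_error(estimateEffects(rnorm(8), line[-1], block[-1]), "balanced")
})

test_that("the dominance ratio handles degenerate effects totally", {
    expect_equal(dominanceRatio(5, 0), 0)
    expect_equal(dominanceRatio(-5, 5), 1)          # |a| convention
    expect_equal(dominanceRatio(0, 3), Inf)
    expect_equal(dominanceRatio(0, -3), -Inf)
    expect_equal(dominanceRatio(0, 0), 0)
    expect_identical(as.character(classifyMode(dominanceRatio(0, 3))),
                     "over_dominance")
    expect_identical(as.character(classifyMode(dominanceRatio(1e-12, 0))),
                     "additive")
})

test_that("Hp band classification matches the published band edges", {
    expect_identical(as.character(classifyMode(0)), "additive")
    expect_identical(as.character(classifyMode(0.2)), "additive")
    expect_identical(as.character(classifyMode(-0.2)), "partial_dominance")
    expect_identical(as.character(classifyMode(0.8)), "partial_dominance")
    expect_identical(as.character(classifyMode(1.2)), "dominance")
    expect_identical(as.character(classifyMode(1.2000001)), "over_dominance")
    expect_identical(as.character(classifyMode(-1.2)), "over_dominance")
    expect_identical(as.character(classifyMode(c(Inf, -Inf))),
                     rep("over_dominance", 2))
})

test_that("the four bands partition the extended reals", {
    grid <- c(seq(-3, 3, by = 0.001), Inf, -Inf,
              -1.2, -0.8, -0.2, 0.2, 0.8, 1.2)
    set.seed(2)
    grid <- c(grid, rnorm(5000, 0, 2))
    modes <- classifyMode(grid)
    expect_false(anyNA(modes))       # every value lands in exactly one band
    expect_setequal(as.character(unique(modes)),
                    c("additive", "partial_dominance", "dominance",
                      "over_dominance"))
})

test_that("mode calls are invariant under swapping the parent labels", {
    te <- simulateTrioCounts(simConfig(nGenes = 80, seed = 19))
    calls <- inheritanceModes(te)
    line <- as.character(trioLine(te))
    swapped <- ifelse(line == "P1", "P2", ifelse(line == "P2", "P1", "F1"))
    te2 <- TrioExperiment(assay(te, "counts"), swapped, trioReplicate(te),
                          rowData = rowData(te))
    calls2 <- inheritanceModes(te2)
    expect_equal(calls$Hp, calls2$Hp)
    expect_identical(as.character(calls$mode), as.character(calls2$mode))
    expect_equal(calls$a, -calls2$a)
    expect_equal(calls$d, calls2$d)
})

test_that("the effect CI follows its conventions and degenerate forms", {
    eff <- list(aSigned = 5, d = 10, sigma2 = 0, df = 4L, r = 3L)
    ci <- effectCI(eff)
    expect_equal(ci$contrast, "d-a")
    expect_equal(ci$ciLow, 5)
    expect_equal(ci$ciHigh, 5)
    expect_true(ci$confident)
    ## d < 0 uses d + a; d = 0 defaults to d - a
    expect_equal(effectCI(list(aSigned = 5, d = -10, sigma2 = 0, df = 4L,
                               r = 3L))$contrast, "d+a")
    expect_equal(effectCI(list(aSigned = 5, d = 0, sigma2 = 1, df = 4L,
                               r = 3L))$contrast, "d-a")
    expect_error(effectCI(list(aSigned = 1, d = 1, sigma2 = 1, df = 0L,
                               r = 2L)), "df")
})

test_that("99.8% CIs reach nominal coverage on simulated effects", {
    set.seed(55)
    nSim <- 4000
    r <- 3
    line <- rep(c("P1", "P2", "F1"), each = r)
    block <- rep(1:r, 3)
    mu <- c(P1 = 110, P2 = 100, F1 = 120)     # true d - |a| = 15 - 5 = 10
    trueContrast <- 10
    sigma <- 2
    covered <- logical(nSim)
    for (i in seq_len(nSim)) {
        y <- mu[line] + rnorm(9, 0, sigma)
        ci <- effectCI(estimateEffects(y, line, block))
        covered[i] <- ci$ciLow <= trueContrast && trueContrast <= ci$ciHigh
    }
    expect_gte(mean(covered), 0.99)
    expect_lte(mean(covered), 1.0)
})

test_that("mode proportions summarize calls and sum to one", {
    s <- modeSummary(rep(c("over_dominance", "additive"), c(6, 4)))
    expect_equal(s[["over_dominance"]], 0.6)
    expect_equal(sum(s), 1)
    s2 <- modeSummary(rep("additive", 5))
    expect_equal(unname(s2), c(1, 0, 0, 0))
    expect_error(modeSummary(character(0)), "no calls")
})

test_that("modes are recovered on a clean synthetic trio", {
    te <- simulateTrioCounts(simConfig(nGenes = 800, dispersion = 0.02,
                                       bandMargin = 0.3, seed = 77))
    calls <- inheritanceModes(te)
    expect_gte(mean(as.character(calls$mode) == rowData(te)$true_mode), 0.85)
    ## restricting to a gene subset subsets the calls
    sub <- inheritanceModes(te, genes = rownames(te)[1:10])
    expect_identical(sub$gene, rownames(te)[1:10])
    expect_error(inheritanceModes(te, genes = "nope"), "not in matrix")
})
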