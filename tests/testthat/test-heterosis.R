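test_that("heterosis formulas reproduce the published worked examples", {
    expect_equal(round(midParentHeterosis(42.8, 29.89, 34.8), 2), 32.32)
    expect_equal(round(highParentHeterosis(42.8, 29.89, 34.8), 2), 22.99)
    expect_equal(round(midParentHeterosis(22.44, 18.64, 23.60), 2), 6.25)
    expect_equal(round(midParentHeterosis(8.7, 6.8, 10.4), 2), 1.16)
    ## direct arithmetic for the tiller HPH: (8.7 - 10.4) / 10.4
    expect_equal(round(highParentHeterosis(8.7, 6.8, 10.4), 2),
                 round(100 * (8.7 - 10.4) / 10.4, 2))
    expect_equal(round(highParentHeterosis(8.7, 6.8, 10.4), 2), -16.35)
})

test_that("heterosis boundary cases and errors behave as defined", {
    expect_equal(midParentHeterosis(15, 10, 20), 0)
    expect_equal(highParentHeterosis(20, 10, 20), 0)
    expect_error(midParentHeterosis(5, 1, -1), "undefined")
    expect_error(highParentHeterosis(5, 0, 0), "undefined")
    ## lower-is-better flag flips the better parent
    expect_equal(highParentHeterosis(8, 10, 16, higherIsBetter = FALSE),
                 100 * (8 - 10) / 10)
})

test_that("MPH and HPH are scale invariant and sign-coherent", {
    set.seed(14)
    for (i in 1:20) {
        m <- runif(3, 5, 50)
        c_ <- runif(1, 0.1, 10)
        expect_equal(midParentHeterosis(m[1], m[2], m[3]),
                     midParentHeterosis(c_ * m[1], c_ * m[2], c_ * m[3]))
        expect_equal(highParentHeterosis(m[1], m[2], m[3]),
                     highParentHeterosis(c_ * m[1], c_ * m[2], c_ * m[3]))
        mp <- mean(m[2:3])
        expect_identical(midParentHeterosis(m[1], m[2], m[3]) > 0, m[1] > mp)
        expect_identical(highParentHeterosis(m[1], m[2], m[3]) > 0,
                         m[1] > max(m[2:3]))
    }
})

test_that("heterosisTable reduces to the closed forms at zero variance", {
    sp <- panicleTraitSpecs()
    sp$sd[] <- 0
    tt <- simulateTraits(sp, nReplicates = 3, seed = 1)
    ht <- heterosisTable(tt)
    for (i in seq_len(nrow(ht))) {
        m <- sp[sp$trait == ht$trait[i], ]
        means <- setNames(m$mean, m$line)
        expect_equal(ht$MPH[i], midParentHeterosis(means["F1"], means["P1"],
                                                   means["P2"]),
                     ignore_attr = TRUE)
        expect_equal(ht$HPH[i], highParentHeterosis(means["F1"], means["P1"],
                                                    means["P2"]),
                     ignore_attr = TRUE)
    }
})

test_that("heterosisTable handles identical-F1 and missing-line inputs", {
    ## F1 replicates identical to per-replicate midparent values: p_mph = 1
    tt <- data.frame(trait = "t",
                     line = rep(c("P1", "P2", "F1"), each = 3),
                     replicate = rep(1:3, 3),
                     value = c(10, 12, 14, 20, 22, 24, 15, 17, 19))
    ht <- heterosisTable(tt)
    expect_equal(ht$p_mph, 1)
    expect_equal(ht$MPH, 0)
    ## missing line: skipped with a warning
    tt2 <- tt[tt$line != "P2", ]
    expect_warning(ht2 <- heterosisTable(tt2), "missing line")
    expect_equal(nrow(ht2), 0)
})

test_that("a Table-1-sized yield effect is detected in most replicated trials", {
    hits <- 0L
    nRuns <- 200L
    for (s in seq_len(nRuns)) {
        tt <- simulateTraits(yieldSpecs(), nReplicates = 10, seed = 1000 + s)
        ht <- heterosisTable(tt)
        hits <- hits + (ht$p_mph < 0.05)
    }
    expect_gt(hits / nRuns, 0.5)
})
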