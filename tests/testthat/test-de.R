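test_that("dispersion estimation recovers known dispersion regimes", {
    set.seed(3)
    grp <- rep(c("A", "B"), each = 3)
    pois <- matrix(rpois(1000 * 6, 150), 1000, 6)
    d0 <- estimateTrioDispersions(pois, grp)
    expect_lte(median(d0$phi), 0.05)
    nb <- matrix(rnbinom(1000 * 6, mu = 150, size = 1 / 0.4), 1000, 6)
    d4 <- estimateTrioDispersions(nb, grp)
    expect_gte(d4$common, 0.2)
    expect_lte(d4$common, 0.6)
    same <- matrix(rep(rpois(50, 100), 6), 50, 6)
    expect_equal(estimateTrioDispersions(same, grp)$raw, rep(0, 50))
    expect_error(estimateTrioDispersions(pois[, 1:4],
                                         c("A", "A", "A", "B")),
                 "fixed phi")
})

test_that("the exact NB test honours its boundary contracts", {
    expect_equal(nbExactTest(c(10, 10, 10), c(10, 10, 10), phi = 0.2), 1)
    expect_equal(nbExactTest(c(0, 0, 0), c(0, 0, 0), phi = 0.1), 1)
    expect_error(nbExactTest(c(1, 2), c(3, 4), phi = -1), "non-negative")
    set.seed(5)
    for (i in 1:20) {
        y1 <- rpois(3, 50); y2 <- rpois(3, 50)
        p12 <- nbExactTest(y1, y2, phi = 0.1)
        expect_equal(nbExactTest(y2, y1, phi = 0.1), p12)  # label symmetry
        expect_gt(p12, 0)
        expect_lte(p12, 1)
    }
})

test_that("at phi = 0 the exact test equals binomial enumeration", {
    binomOracle <- function(s1, total, n1, n2) {
        probs <- dbinom(0:total, total, n1 / (n1 + n2))
        sum(probs[probs <= probs[s1 + 1] * (1 + 1e-10)])
    }
    expect_equal(nbExactTest(c(5, 5, 5), c(2, 2, 1), phi = 0),
                 binomOracle(15, 20, 3, 3))
    set.seed(9)
    for (i in 1:50) {
        n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
        y1 <- rpois(n1, 20); y2 <- rpois(n2, 20)
        expect_equal(nbExactTest(y1, y2, phi = 0),
                     binomOracle(sum(y1), sum(y1) + sum(y2), n1, n2))
    }
})

test_that("exact-test p-values agree in rank with an independent DE engine", {
    set.seed(17)
    mu <- matrix(100, 200, 6)
    mu[1:40, 4:6] <- mu[1:40, 4:6] * runif(40, 1.5, 4)
    cts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.15), nrow(mu))
    rownames(cts) <- sprintf("g%03d", seq_len(nrow(cts)))
    te <- TrioExperiment(cbind(cts, matrix(rpois(200 * 3, 100), 200, 3)),
                         rep(c("P1", "P2", "F1"), each = 3))
    mine <- nbDifferentialExpression(te, c("P2", "P1"), dispersion = 0.15)
    dge <- edgeR::DGEList(counts = cts,
                          group = rep(c("P1", "P2"), each = 3))
    ref <- edgeR::exactTest(dge, dispersion = 0.15)$table
    expect_gt(cor(mine$p, ref$PValue, method = "spearman"), 0.98)
})

test_that("BH adjustment matches the brute-force step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
    stepUp <- function(p) {
        m <- length(p)
        o <- order(p)
        adj <- numeric(m)
        for (i in seq_len(m))
            adj[o[i]] <- min(1, min(m * p[o[i:m]] / (i:m)))
        adj
    }
    set.seed(20)
    for (i in 1:1000) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), stepUp(p))
    }
})

test_that("DEG calls apply inclusive FDR and fold-change thresholds", {
    res <- S4Vectors::DataFrame(
        gene = paste0("g", 1:4),
        logFC = c(1, 0.9, -1, -2),
        fdr = c(0.05, 0.04, 0.05, 0.6))
    out <- callDEGs(res, alpha = 0.05, minL2fc = 1)
    expect_identical(out$call,
                     c("up", "not_significant", "down", "not_significant"))
})

test_that("swapping contrast lines negates logFC and keeps p", {
    te <- simulateTrioCounts(simConfig(nGenes = 100, seed = 13))
    ab <- nbDifferentialExpression(te, c("F1", "P1"), dispersion = 0.05)
    ba <- nbDifferentialExpression(te, c("P1", "F1"), dispersion = 0.05)
    expect_equal(ab$p, ba$p)
    expect_equal(ab$logFC, -ba$logFC)
})

test_that("null trios are controlled and planted effects are detected", {
    set.seed(31)
    fracs <- vapply(1:5, function(i) {
        de <- nbDifferentialExpression(nullTrio(1000), c("F1", "P1"))
        mean(de$fdr <= 0.05)
    }, numeric(1))
    expect_lte(mean(fracs), 0.05)
    ## planted 4-fold changes at mean 200, phi = 0.1, 3 vs 3
    set.seed(32)
    n <- 600
    sgn <- sample(c(1, -1), n, TRUE)
    muP1 <- ifelse(sgn > 0, 200, 800)
    mu <- cbind(matrix(rep(muP1, 3), n), matrix(rep(1000 - muP1, 3), n),
                matrix(200, n, 3))
    cts <- matrix(rnbinom(length(mu), mu = mu, size = 10), n)
    te <- TrioExperiment(cts, rep(c("P1", "P2", "F1"), each = 3))
    de <- nbDifferentialExpression(te, c("P1", "P2"))
    expect_gte(mean(de$call != "not_significant"), 0.8)
})

test_that("the Venn partition conserves counts and matches hand results", {
    pt <- partitionDEGs(c("g1", "g2"), c("g2", "g3"), "g3")
    expect_equal(pt$nDgHP, 3)
    expect_equal(pt$nOverlap, 1)
    expect_setequal(pt$dgHP, c("g1", "g2", "g3"))
    empty <- partitionDEGs(character(0), character(0), character(0))
    expect_true(all(empty$regions == 0))
    expect_equal(empty$nDgHP, 0)
    set.seed(41)
    for (i in 1:20) {
        ids <- paste0("g", 1:100)
        a <- sample(ids, 40); b <- sample(ids, 30); c_ <- sample(ids, 50)
        pt <- partitionDEGs(a, b, c_)
        expect_equal(sum(pt$regions), length(union(union(a, b), c_)))
        expect_equal(pt$nDgHP, length(union(a, b)))
        expect_equal(pt$nOverlap, length(intersect(union(a, b), c_)))
    }
})
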