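#' Run the full trio heterosis pipeline
#'
#' One call that goes from inputs (or a simulation) to every stage result:
#' trait heterosis, FPKM quantification and replicate agreement,
#' differential expression for the three trio contrasts, the DG_HP/DG_PP
#' Venn partition, per-gene inheritance-mode classification, term
#' enrichment and QTL colocalization, plus a machine-readable summary.
#' Identical configuration and seed give an identical summary.
#'
#' The configuration is a nested list (or a YAML file with the same shape):
#' \describe{
#'   \item{\code{simulate}}{arguments for \code{\link{simConfig}}, plus
#'     optional \code{nQtl}, \code{termSizes}, \code{traitReplicates};
#'     when present the pipeline runs on simulated data.}
#'   \item{\code{inputs}}{paths \code{counts}, \code{sampleSheet}, and
#'     optionally \code{geneModels}, \code{qtlPanel}, \code{termMap}
#'     (GMT), \code{traits}; used when \code{simulate} is absent.}
#'   \item{\code{thresholds}}{\code{alpha} (0.05), \code{minL2fc} (1),
#'     \code{ciLevel} (0.998), \code{enrichMinSize} (3), \code{minFpkm}
#'     (1), \code{classifyAll} (FALSE: classify DG_HP only).}
#' }
#'
#' @param config nested list or path to a YAML file.
#' @param outDir output directory; created if needed.  \code{NULL} skips
#'   all file output and returns results only.
#' @param seed overrides \code{config$seed} / simulation seeds.
#' @param quiet suppress progress messages?
#' @return (invisibly) list with per-stage results and \code{summary}, the
#'   content of \code{summary.json}.
#' @examples
#' res <- runHeterosisPipeline(list(simulate = list(nGenes = 150)),
#'                             outDir = NULL, seed = 11, quiet = TRUE)
#' res$summary$modeProportions
#' @export
runHeterosisPipeline <- function(config = list(), outDir = NULL,
                                 seed = NULL, quiet = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    th <- .mergeThresholds(config$thresholds)
    if (is.null(seed)) seed <- config$seed
    if (is.null(seed)) seed <- 1L
    seed <- as.integer(seed)
    logLines <- character()
    log <- function(stage, ...) {
        line <- sprintf("[%s] %s", stage, paste0(...))
        if (!quiet) message(line)
        logLines <<- c(logLines, line)
    }
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    save <- function(obj, name, writer = writeTSV) {
        if (!is.null(outDir)) writer(obj, file.path(outDir, name))
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    results <- list(config = config, seed = seed)

    ## ---- data -------------------------------------------------------
    simulated <- !is.null(config$simulate)
    if (simulated) {
        results$data <- stage("simulate", {
            sim <- config$simulate
            scArgs <- sim[intersect(names(sim), names(formals(simConfig)))]
            scArgs$seed <- seed
            cfg <- do.call(simConfig, scArgs)
            te <- simulateTrioCounts(cfg)
            gf <- simulateGenomeFeatures(
                nGenes = cfg@nGenes,
                nQtl = if (is.null(sim$nQtl)) 10L else sim$nQtl,
                termSizes = if (is.null(sim$termSizes)) rep(10L, 20L)
                            else sim$termSizes,
                seed = seed + 1L)
            geneLengths(te) <- GenomicRanges::width(gf$genes)
            traits <- simulateTraits(
                nReplicates = if (is.null(sim$traitReplicates)) 3L
                              else sim$traitReplicates,
                seed = seed + 2L)
            log("simulate", cfg@nGenes, " genes, ", length(gf$qtls),
                " QTLs, seed ", seed)
            list(te = te, genes = gf$genes, qtls = gf$qtls,
                 termMap = gf$termMap, qtlTruth = gf$truth,
                 traits = traits)
        })
    } else {
        results$data <- stage("ingest", {
            inp <- config$inputs
            if (is.null(inp$counts) || is.null(inp$sampleSheet))
                stop("inputs$counts and inputs$sampleSheet are required")
            te <- readTrioExperiment(inp$counts, inp$sampleSheet,
                                     inp$geneModels)
            genes <- if (!is.null(inp$geneModels))
                readGeneModels(inp$geneModels) else NULL
            qtls <- if (!is.null(inp$qtlPanel)) readQTLPanel(inp$qtlPanel)
                    else NULL
            termMap <- if (!is.null(inp$termMap)) readGMT(inp$termMap)
                       else NULL
            traits <- if (!is.null(inp$traits)) readTraitTable(inp$traits)
                      else NULL
            log("ingest", nrow(te), " genes x ", ncol(te), " samples")
            list(te = te, genes = genes, qtls = qtls, termMap = termMap,
                 traits = traits)
        })
    }
    te <- results$data$te

    ## ---- phenotype heterosis ---------------------------------------
    if (!is.null(results$data$traits)) {
        results$heterosis <- stage("phenotype_heterosis", {
            ht <- heterosisTable(results$data$traits)
            save(ht, "heterosis.tsv")
            log("phenotype_heterosis", nrow(ht), " traits")
            ht
        })
    }

    ## ---- quantification --------------------------------------------
    results$quant <- stage("quantification", {
        sf <- sizeFactors(te)
        fpkmMat <- if (!is.null(geneLengths(te)))
            assay(fpkm(te), "fpkm") else NULL
        universe <- if (!is.null(fpkmMat))
            expressedGenes(fpkmMat, minFpkm = th$minFpkm)
        else rownames(te)
        if (!is.null(fpkmMat))
            save(data.frame(gene = rownames(fpkmMat), fpkmMat,
                            check.names = FALSE), "fpkm.tsv")
        r2 <- if (nrow(te) > 1) replicateR2(
            if (!is.null(fpkmMat)) fpkmMat
            else counts(te, normalized = TRUE), trioLine(te)) else NULL
        log("quantification", length(universe), " expressed genes")
        list(sizeFactors = sf, fpkm = fpkmMat, universe = universe,
             replicateR2 = r2)
    })

    ## ---- differential expression -----------------------------------
    contrasts <- list(c("F1", "P1"), c("F1", "P2"), c("P1", "P2"))
    results$de <- stage("differential_expression", {
        de <- lapply(contrasts, function(ct)
            nbDifferentialExpression(te, ct, alpha = th$alpha,
                                     minL2fc = th$minL2fc))
        names(de) <- vapply(contrasts, paste, character(1),
                            collapse = "_vs_")
        for (nm in names(de))
            save(de[[nm]], paste0("de_", nm, ".tsv"))
        for (nm in names(de))
            log("differential_expression", nm, ": ",
                sum(de[[nm]]$call != "not_significant"), " DEGs")
        de
    })
    degSets <- lapply(results$de, function(d)
        d$gene[d$call != "not_significant"])
    results$partition <- stage("set_partition", {
        pt <- partitionDEGs(degSets$F1_vs_P1, degSets$F1_vs_P2,
                            degSets$P1_vs_P2)
        log("set_partition", "DG_HP=", pt$nDgHP, " DG_PP=", pt$nDgPP,
            " overlap=", pt$nOverlap)
        pt
    })

    ## ---- inheritance modes -----------------------------------------
    results$modes <- stage("inheritance_mode", {
        genes <- if (isTRUE(th$classifyAll)) NULL
                 else results$partition$dgHP
        if (!isTRUE(th$classifyAll) && !length(genes)) {
            log("inheritance_mode", "no DG_HP genes; skipped")
            NULL
        } else {
            calls <- inheritanceModes(te, genes = genes,
                                      level = th$ciLevel)
            save(calls, "inheritance_modes.tsv")
            log("inheritance_mode", nrow(calls), " genes classified")
            calls
        }
    })

    ## ---- enrichment -------------------------------------------------
    if (!is.null(results$data$termMap)) {
        results$enrichment <- stage("enrichment", {
            geneSet <- intersect(results$partition$dgHP,
                                 results$quant$universe)
            if (!length(geneSet)) {
                log("enrichment", "empty DG_HP in universe; skipped")
                NULL
            } else {
                er <- enrich(geneSet, results$quant$universe,
                             results$data$termMap,
                             minSize = th$enrichMinSize)
                save(er, "enrichment.tsv")
                log("enrichment", nrow(er), " terms tested")
                er
            }
        })
    }

    ## ---- QTL colocalization ----------------------------------------
    if (!is.null(results$data$qtls) && !is.null(results$data$genes) &&
        length(results$data$qtls)) {
        results$colocalization <- stage("qtl_colocalization", {
            co <- qtlColocalization(results$data$genes, results$data$qtls)
            rpt <- colocalizationReport(co, results$partition$dgHP)
            save(co, "colocalization.tsv")
            save(rpt, "colocalization_report.tsv")
            log("qtl_colocalization", nrow(co), " gene-QTL pairs, ",
                nrow(rpt), " QTLs with DG_HP genes")
            list(pairs = co, report = rpt)
        })
    }

    ## ---- summary ----------------------------------------------------
    results$summary <- stage("summary", {
        s <- list(
            seed = seed,
            nGenes = nrow(te), nSamples = ncol(te),
            thresholds = th[order(names(th))],
            degCounts = lapply(results$de, function(d)
                list(up = sum(d$call == "up"),
                     down = sum(d$call == "down"),
                     total = sum(d$call != "not_significant"))),
            venn = as.list(results$partition$regions),
            nDgHP = results$partition$nDgHP,
            nDgPP = results$partition$nDgPP,
            nOverlap = results$partition$nOverlap)
        if (!is.null(results$modes))
            s$modeProportions <- as.list(modeSummary(results$modes))
        if (!is.null(results$heterosis))
            s$heterosis <- lapply(seq_len(nrow(results$heterosis)),
                function(i) {
                    h <- results$heterosis[i, ]
                    list(trait = h$trait, MPH = round(h$MPH, 2),
                         HPH = round(h$HPH, 2),
                         p_mph = h$p_mph, p_hph = h$p_hph)
                })
        if (!is.null(results$enrichment) && nrow(results$enrichment))
            s$topTerms <- utils::head(results$enrichment$term, 10L)
        if (!is.null(results$colocalization))
            s$colocalization <- list(
                nPairs = nrow(results$colocalization$pairs),
                nQtlsWithCandidates = nrow(results$colocalization$report))
        if (!is.null(outDir))
            jsonlite::write_json(s, file.path(outDir, "summary.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 pretty = TRUE)
        s
    })
    if (!is.null(outDir))
        writeLines(logLines, file.path(outDir, "run.log"))
    invisible(results)
}

.mergeThresholds <- function(th) {
    defaults <- list(alpha = 0.05, minL2fc = 1, ciLevel = 0.998,
                     enrichMinSize = 3L, minFpkm = 1, classifyAll = FALSE)
    if (is.null(th)) return(defaults)
    stopifnot(is.list(th))
    bad <- setdiff(names(th), names(defaults))
    if (length(bad))
        stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    out <- utils::modifyList(defaults, th)
    stopifnot(out$alpha > 0, out$alpha <= 1, out$minL2fc >= 0,
              out$ciLevel > 0, out$ciLevel < 1, out$enrichMinSize >= 1)
    out
}
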