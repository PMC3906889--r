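# End-to-end orchestration: simulate (or load) -> fit -> reference ->
# score -> classify/QC -> select -> cluster -> enrich, with every table
# written as provenance-stamped TSV and a deterministic run log.

#' Pipeline configuration
#'
#' @param outDir output directory (created if absent).
#' @param screenCfg a [screenConfig] for the primary (misfolded-allele
#'   background) screen. Its seed drives the whole run.
#' @param wtFracEnhancer,wtFracSuppressor planted effect rates of the
#'   simulated companion wild-type-background screen (mostly null by
#'   default: interactions specific to the misfolded allele are the
#'   object of the screen).
#' @param fitCfg a [fitConfig].
#' @param thDeltaF,thWT per-screen classification [Thresholds].
#' @param qcCuts a [qcConfig].
#' @param remcCfg a [remcConfig]; its seed is derived from the screen seed.
#' @param fitSeries when `TRUE`, the generator renders intensity time
#'   series for every culture and the pipeline fits them with
#'   [fitLogistic]; when `FALSE` the generator's L values feed the scoring
#'   directly (fast path).
#' @param enrichAlpha adjusted-p cutoff counting a term as enriched.
#' @param nPerm permutations for the aggregate enrichment z.
#' @param verbose echo progress to the console.
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outDir,
                           screenCfg = screenConfig(nGenes = 120L, seed = 1L),
                           wtFracEnhancer = 0.02, wtFracSuppressor = 0.02,
                           fitCfg = fitConfig(),
                           thDeltaF = Thresholds(10, -16),
                           thWT = Thresholds(10, -12),
                           qcCuts = qcConfig(),
                           remcCfg = NULL,
                           fitSeries = FALSE,
                           enrichAlpha = 0.05,
                           nPerm = 200L,
                           verbose = FALSE) {
  if (is.null(remcCfg)) remcCfg <- remcConfig(seed = screenCfg$seed + 17L)
  structure(
    list(outDir = outDir, screenCfg = screenCfg,
         wtFracEnhancer = wtFracEnhancer,
         wtFracSuppressor = wtFracSuppressor,
         fitCfg = fitCfg, thDeltaF = thDeltaF, thWT = thWT,
         qcCuts = qcCuts, remcCfg = remcCfg, fitSeries = fitSeries,
         enrichAlpha = enrichAlpha, nPerm = as.integer(nPerm),
         verbose = verbose),
    class = "pipelineConfig"
  )
}

# fitted-L dose responses from a generated screen's rendered series
.fitScreenSeries <- function(screen, fitCfg) {
  tbl <- fitScreen(screen$series, fitCfg, meta = screen$seriesMeta)
  mut <- tbl[tbl$type == "mutant", , drop = FALSE]
  ref <- tbl[tbl$type == "reference", , drop = FALSE]
  drs <- lapply(split(mut, mut$strain), function(sub) {
    sub <- sub[order(sub$dose), , drop = FALSE]
    DoseResponse(sub$strain[1L], sub$dose,
                 ifelse(sub$grew, sub$L, NA_real_), sub$grew)
  })
  list(doseResponses = drs,
       reference = data.frame(replicate = ref$strain, dose = ref$dose,
                              L = ifelse(ref$grew, ref$L, NA_real_)),
       fitTable = tbl)
}

#' Run the full analysis pipeline on a simulated screen
#'
#' Simulates the primary and companion screens, optionally fits rendered
#' time series, builds the reference model, scores / classifies / QC-flags
#' every strain in both screens, selects genes for clustering, assembles
#' profiles (screen interactions, control growth, gene-drug columns), runs
#' recursive EM clustering with hierarchical within-cluster ordering and
#' gene-set enrichment, and writes all tables plus a run log to
#' `cfg$outDir`. Repeated runs with an identical configuration produce
#' byte-identical files.
#'
#' @param cfg a [pipelineConfig].
#' @return (invisibly) a list: `summary` (counts), `deltaF` and `wildtype`
#'   interaction tables, `selected`, the cluster `tree`, `clusterSummary`,
#'   and the output file paths.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$screenCfg$seed
  provCfg <- cfg
  provCfg$outDir <- NULL  # provenance hash must not depend on where we write
  logLines <- c(.tsvHeader(seed, provCfg),
                sprintf("# stage log (seed %d)", seed))
  note <- function(...) {
    line <- sprintf(...)
    if (cfg$verbose) message(line)
    logLines <<- c(logLines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()
  out <- function(name) {
    paths[[name]] <<- file.path(cfg$outDir, name)
    paths[[name]]
  }

  note("simulate: primary screen, %d genes, %d doses, %d reference replicates",
       cfg$screenCfg$nGenes, length(cfg$screenCfg$doses),
       cfg$screenCfg$nRefReplicates)
  deltaF <- stage("simulate", generateScreen(cfg$screenCfg,
                                             emitSeries = cfg$fitSeries))
  wtCfg <- cfg$screenCfg
  wtCfg$fracEnhancer <- cfg$wtFracEnhancer
  wtCfg$fracSuppressor <- cfg$wtFracSuppressor
  wtCfg$seed <- cfg$screenCfg$seed + 1L
  wt <- stage("simulate", generateScreen(wtCfg, emitSeries = FALSE))

  if (cfg$fitSeries) {
    note("fit: logistic fits for %d rendered cultures", length(deltaF$series))
    fitted <- stage("fit", .fitScreenSeries(deltaF, cfg$fitCfg))
    drs <- fitted$doseResponses
    refReplicates <- fitted$reference
    screenTab <- fitted$fitTable
    screenTab$oligomycin <- screenTab$dose
    screenTab$orf <- screenTab$strain
    screenTab$gene <- screenTab$strain
    writeScreenTable(screenTab, out("screen_deltaF.tsv"), seed, provCfg)
  } else {
    drs <- screenDoseResponses(deltaF)
    refReplicates <- deltaF$reference
  }

  note("reference: %s of grown replicates per dose", "median")
  ref <- stage("reference", buildReference(refReplicates))

  note("score: wild-type companion screen")
  wtRes <- stage("score", scoreScreen(screenDoseResponses(wt),
                                      buildReference(wt$reference),
                                      th = cfg$thWT, cuts = cfg$qcCuts))
  note("score: primary screen with companion QC context")
  dfRes <- stage("score", scoreScreen(drs, ref, th = cfg$thDeltaF,
                                      companions = wtRes,
                                      companionTh = cfg$thWT,
                                      cuts = cfg$qcCuts))

  dfTbl <- rankInteractions(interactionTable(dfRes))
  wtTbl <- rankInteractions(interactionTable(wtRes))
  intOut <- function(tbl, file) {
    tbl$orf <- tbl$strain
    tbl$gene <- tbl$strain
    tbl$orf_effect <- tbl$K0
    tbl$interaction <- tbl$INT
    tbl$n_no_growth <- tbl$tier
    writeInteractionTable(tbl, out(file), seed, provCfg)
  }
  intOut(dfTbl, "interactions_deltaF.tsv")
  intOut(wtTbl, "interactions_wildtype.tsv")

  note("select: union of per-screen threshold passers")
  selected <- stage("select", selectGenes(dfTbl, wtTbl, cfg$thDeltaF, cfg$thWT))
  writeLines(c(.tsvHeader(seed, provCfg), "gene", selected),
             out("selected_genes.tsv"))

  summaryCounts <- list(
    n_genes = nrow(dfTbl),
    n_enhancers = sum(dfTbl$class == "deletion_enhancer", na.rm = TRUE),
    n_suppressors = sum(dfTbl$class == "deletion_suppressor", na.rm = TRUE),
    n_tiered = sum(dfTbl$tier > 0L),
    n_selected = length(selected)
  )

  tree <- NULL
  clusterSummary <- NULL
  if (length(selected) >= 2L) {
    note("cluster: %d selected genes over the %d-column schema",
         length(selected), nrow(profileSchema()))
    X <- cbind(
      A = dfTbl$INT[match(selected, dfTbl$strain)],
      B = wtTbl$INT[match(selected, wtTbl$strain)],
      C = dfTbl$K0[match(selected, dfTbl$strain)],
      deltaF$geneDrug[selected, , drop = FALSE]
    )
    rownames(X) <- selected
    profiles <- InteractionProfiles(X)
    writeProfilesTable(profiles, out("profiles.tsv"), seed, provCfg)
    tree <- stage("cluster", remc(profiles, cfg$remcCfg))
    ctab <- clusterTable(tree)
    lv <- leaves(tree)
    ordered <- do.call(rbind, lapply(lv, function(l) {
      ord <- hclustOrder(l, profiles)$order
      data.frame(cluster = l@name, gene = ord,
                 position = seq_along(ord), log_lik = l@logLik)
    }))
    .writeTsv(ordered, out("clusters.tsv"), seed, provCfg)

    note("enrich: %d terms against a %d-gene universe",
         length(deltaF$geneSets), nrow(dfTbl))
    universe <- dfTbl$strain
    clusterSummary <- do.call(rbind, lapply(seq_along(lv), function(i) {
      l <- lv[[i]]
      en <- stage("enrich",
                  enrichment(l@members, deltaF$geneSets, universe,
                             nPerm = cfg$nPerm, seed = seed + 100L + i))
      data.frame(cluster = l@name, size = length(l@members),
                 log_lik = l@logLik, goid_z = en$z,
                 n_enriched_terms = sum(en$terms$p_adj < cfg$enrichAlpha))
    }))
    writeClusterSummary(clusterSummary, out("cluster_summary.tsv"), seed, provCfg)
    summaryCounts$n_clusters <- length(lv)
  } else {
    note("cluster: skipped (%d gene(s) selected)", length(selected))
    summaryCounts$n_clusters <- 0L
  }

  note("summary: %d enhancers, %d suppressors, %d tiered, %d selected, %d clusters",
       summaryCounts$n_enhancers, summaryCounts$n_suppressors,
       summaryCounts$n_tiered, summaryCounts$n_selected,
       summaryCounts$n_clusters)
  writeLines(logLines, out("run_log.txt"))

  invisible(list(summary = summaryCounts, deltaF = dfTbl, wildtype = wtTbl,
                 selected = selected, tree = tree,
                 clusterSummary = clusterSummary, paths = paths,
                 reference = ref))
}
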