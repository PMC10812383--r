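#' Assemble and validate a pipeline run configuration
#'
#' Either `cohortPath` (a cohort table for [readCohort()]) or
#' `simulate = TRUE` (generate the cohort with [simulateCohort()] from
#' `seed`) must be chosen.  ddG and neoantigen inputs are optional; the
#' corresponding stages are skipped and the skip is recorded in the run
#' manifest.
#'
#' @param outputDir Directory for the report bundle (created if needed).
#' @param cohortPath Optional path to a cohort TSV/CSV.
#' @param simulate Generate a synthetic cohort instead of reading one.
#' @param seed Integer seed for simulation.
#' @param catalogPath,domainMapPath,signaturePath,transcriptPath Optional
#'   overrides of the bundled defaults.
#' @param ddgPath,neoantigenPath Optional TSVs (`variant`, `model`, `ddg`;
#'   `tumor_id`, `mhc_binding`, `tcell_reactivity`).
#' @param tmbThreshold TMB-high cutoff (mut/Mb), boundary included.
#' @param inclusionThreshold Signature channel inclusion rule.
#' @param exactTestCutoff Largest per-sample n for exact Mann-Whitney.
#' @return A validated list of class `"RunConfig"`.
#' @export
runConfig <- function(outputDir,
                      cohortPath = NULL, simulate = is.null(cohortPath),
                      seed = 1L,
                      catalogPath = NULL, domainMapPath = NULL,
                      signaturePath = NULL, transcriptPath = NULL,
                      ddgPath = NULL, neoantigenPath = NULL,
                      tmbThreshold = 10, inclusionThreshold = 0.01,
                      exactTestCutoff = 20) {
  if (is.null(cohortPath) && !simulate)
    stop("either cohortPath or simulate = TRUE is required")
  if (!is.null(cohortPath) && !file.exists(cohortPath))
    stop("cohort file not found: ", cohortPath)
  for (p in c(catalogPath, domainMapPath, signaturePath, transcriptPath,
              ddgPath, neoantigenPath))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  if (tmbThreshold <= 0) stop("tmbThreshold must be positive")
  if (inclusionThreshold <= 0 || inclusionThreshold >= 1)
    stop("inclusionThreshold must lie in (0, 1)")
  structure(list(outputDir = outputDir, cohortPath = cohortPath,
                 simulate = simulate, seed = as.integer(seed),
                 catalogPath = catalogPath,
                 domainMapPath = domainMapPath,
                 signaturePath = signaturePath,
                 transcriptPath = transcriptPath, ddgPath = ddgPath,
                 neoantigenPath = neoantigenPath,
                 tmbThreshold = tmbThreshold,
                 inclusionThreshold = inclusionThreshold,
                 exactTestCutoff = exactTestCutoff),
            class = "RunConfig")
}

.writeTsv <- function(d, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  name
}

#' Run the end-to-end analysis
#'
#' Stages: cohort acquisition (file or simulation), driver flagging and
#' group assignment, per-(cancer type, group) summary, trinucleotide
#' context calls for the non-driver variants of Group 3 tumors with
#' per-cancer-type in-context fractions, pairwise TMB comparisons with
#' Benjamini-Hochberg adjustment, stability census (when ddG input is
#' present), neoantigen burden and its Spearman correlation with TMB (when
#' scores are present).  Every table is written to `outputDir` along with
#' a JSON manifest recording thresholds, seed, inputs, skipped stages and
#' output checksums; a stage failure aborts with a stage-tagged message.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `assignments`, `summary`, `contextCalls`, `contextFractions`,
#'   `stats`, `stabilityCensus`, `neoantigenBurden`, `manifest`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))

  catalog <- stage("inputs", if (is.null(config$catalogPath))
    defaultDriverCatalog() else readDriverCatalog(config$catalogPath))
  dmap <- stage("inputs", if (is.null(config$domainMapPath))
    defaultDomainMap() else readDomainMap(config$domainMapPath))
  sigm <- stage("inputs", if (is.null(config$signaturePath))
    poleSignatureMatrix() else readSignatureMatrix(config$signaturePath))
  transcript <- stage("inputs", if (is.null(config$transcriptPath))
    poleTranscript() else readTranscript(config$transcriptPath))

  simOut <- NULL
  cohort <- stage("cohort", {
    if (!is.null(config$cohortPath)) readCohort(config$cohortPath, catalog)
    else {
      simOut <- simulateCohort(syntheticCohortConfig(seed = config$seed),
                               catalog, sigm, transcript)
      simOut$cohort
    }
  })

  assignments <- stage("stratify",
    assignGroups(cohort, catalog, config$tmbThreshold))
  summary <- stage("stratify", summarizeGroups(cohort, assignments))

  sets <- stage("context", poleContextSets(sigm, config$inclusionThreshold))
  v <- poleVariants(cohort)
  g3 <- assignments$tumor_id[assignments$group == "G3"]
  g3v <- v[v$tumor_id %in% g3 & !v$is_exod_driver, , drop = FALSE]
  calls <- stage("context", {
    cc <- classifyVariantContext(g3v, sets, transcript)
    cc$tumor_id <- g3v$tumor_id
    cc
  })
  ctypes <- tumorProfiles(cohort)$cancer_type[
    match(calls$tumor_id, tumorProfiles(cohort)$tumor_id)]
  fractions <- stage("context", {
    out <- lapply(split(seq_len(nrow(calls)), ctypes), function(i)
      fractionInContext(calls[i, , drop = FALSE]))
    out$overall <- fractionInContext(calls)
    out
  })

  stats <- stage("stats",
    groupTmbComparisons(cohort, assignments,
                        pairs = list(c("G2", "G3"), c("G1", "G3"),
                                     c("G1", "G2"))))

  skipped <- character()
  censusOut <- NULL
  ddgTab <- if (!is.null(config$ddgPath))
    utils::read.delim(config$ddgPath, stringsAsFactors = FALSE)
  else if (!is.null(simOut)) simOut$ddg
  if (is.null(ddgTab)) skipped <- c(skipped, "stability_census")
  else censusOut <- stage("stability", stabilityCensus(ddgTab, dmap))

  burden <- NULL; tmbNeo <- NULL
  neoTab <- if (!is.null(config$neoantigenPath))
    utils::read.delim(config$neoantigenPath, stringsAsFactors = FALSE)
  else if (!is.null(simOut)) simOut$neoantigens
  if (is.null(neoTab) || !nrow(neoTab)) {
    skipped <- c(skipped, "neoantigen_burden")
  } else {
    burden <- stage("neoantigen", neoantigenBurden(neoTab))
    prof <- as.data.frame(tumorProfiles(cohort))
    m <- merge(prof[, c("tumor_id", "tmb")], burden, by = "tumor_id")
    tmbNeo <- if (nrow(m) >= 3)
      stage("neoantigen", spearmanCor(m$tmb, m$neoantigen_burden))
  }

  outputs <- character()
  outputs <- c(outputs,
    .writeTsv(cbind(as.data.frame(assignments)),
              config$outputDir, "group_assignments.tsv"),
    .writeTsv(summary, config$outputDir, "group_summary.tsv"),
    .writeTsv(as.data.frame(calls), config$outputDir,
              "context_calls.tsv"),
    .writeTsv(fractions$overall$breakdown, config$outputDir,
              "context_aggregate.tsv"),
    .writeTsv(stats, config$outputDir, "stats_report.tsv"))
  if (!is.null(censusOut))
    outputs <- c(outputs, .writeTsv(
      as.data.frame(censusOut$census), config$outputDir,
      "stability_census.tsv"))
  if (!is.null(burden))
    outputs <- c(outputs, .writeTsv(burden, config$outputDir,
                                    "neoantigen_burden.tsv"))

  manifest <- list(
    package = "poleSig",
    version = as.character(utils::packageVersion("poleSig")),
    seed = config$seed,
    simulated = is.null(config$cohortPath),
    tmb_threshold = config$tmbThreshold,
    inclusion_threshold = config$inclusionThreshold,
    signature_source = if (is.null(config$signaturePath))
      "bundled synthetic POLE signature set" else config$signaturePath,
    n_tumors = length(cohort),
    group_counts = as.list(table(assignments$group)),
    fraction_in_context_overall = fractions$overall$fraction,
    skipped_stages = as.list(skipped),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest,
                       file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, assignments = assignments,
                 summary = summary, contextCalls = calls,
                 contextFractions = fractions, stats = stats,
                 stabilityCensus = censusOut, neoantigenBurden = burden,
                 tmbNeoantigenCorrelation = tmbNeo,
                 manifest = manifest))
}
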