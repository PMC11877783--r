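#' Resolve a pipeline run configuration
#'
#' Fills defaults, validates, and (when `outDir` is set) serializes the
#' resolved configuration and package version into the output directory
#' for provenance.
#'
#' @param ... configuration fields: `manifests` (character paths),
#'   `outDir`, `seed`, `tol`, `strictTrunkGene`, `preset`, `scenario`,
#'   `nPatients`, `meanDepth`, `noiseless`, plus any [PresenceParams()]
#'   argument (`minAltReads`, `alpha`, `errorRate`, `vafDetect`,
#'   `powerFloor`).
#' @return list with the resolved fields and a `params`
#'   [PresenceParams-class].
#' @export
runConfig <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  defaults <- list(manifests = character(), outDir = NULL, seed = 1L,
                   tol = 0.05, strictTrunkGene = NULL, preset = NULL,
                   scenario = "balanced", nPatients = 1L,
                   meanDepth = 1063, noiseless = FALSE)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[k] <- list(defaults[[k]])
  pp <- intersect(names(cfg),
                  c("minAltReads", "alpha", "errorRate", "vafDetect",
                    "powerFloor"))
  cfg$params <- do.call(PresenceParams, cfg[pp])
  cfg$seed <- suppressWarnings(as.integer(cfg$seed))
  if (is.na(cfg$seed)) stopf("seed must be an integer")
  cfg
}

writeConfigRecord <- function(cfg, outDir) {
  rec <- cfg[setdiff(names(cfg), "params")]
  rec$presenceParams <- list(
    minAltReads = cfg$params@minAltReads, alpha = cfg$params@alpha,
    errorRate = cfg$params@errorRate, vafDetect = cfg$params@vafDetect,
    powerFloor = cfg$params@powerFloor)
  rec$packageVersion <-
    as.character(utils::packageVersion("clonalProvenance"))
  jsonlite::write_json(rec, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

specForScenario <- function(scenario, i, cfg) {
  if (!is.null(cfg$preset)) {
    if (cfg$preset != "gbm244") stopf("unknown preset '%s'", cfg$preset)
    return(gbm244Preset(noiseless = cfg$noiseless, seed = cfg$seed + i,
                        meanDepth = cfg$meanDepth))
  }
  sc <- if (scenario == "balanced") {
    if (i %% 2L == 0L) "SVZ_ASSOCIATED" else "PRIMARY_ASSOCIATED"
  } else scenario
  randomPatientSpec(cfg$seed + i, scenario = sc,
                    meanDepth = cfg$meanDepth, noiseless = cfg$noiseless)
}

#' Simulate patients and write their files
#'
#' Writes, per patient, the variant table, a manifest pointing at it,
#' and truth sidecars (per-variant category; per-patient pattern in a
#' cohort-level file). The output of this subcommand is valid
#' [runClassify()] input with no manual edits.
#'
#' @param config a [runConfig()] list; uses `outDir`, `seed`, `preset`
#'   or `scenario`, `nPatients`, `meanDepth`, `noiseless`.
#' @return invisible list of [PatientDataset-class] objects.
#' @export
runSimulate <- function(config) {
  cfg <- if (is.null(config$params)) runConfig(config) else config
  if (is.null(cfg$outDir)) stopf("runSimulate needs outDir")
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  writeConfigRecord(cfg, cfg$outDir)
  datasets <- list()
  patterns <- list()
  for (i in seq_len(cfg$nPatients)) {
    pid <- sprintf("SIM-%03d", i)
    spec <- specForScenario(cfg$scenario, i, cfg)
    ds <- simulatePatient(spec, patientId = pid)
    tabFile <- sprintf("%s.variants.tsv", pid)
    writeVariantTable(ds@variants, file.path(cfg$outDir, tabFile))
    writePatientManifest(ds@manifest,
                         file.path(cfg$outDir, sprintf("%s.manifest", pid)),
                         table = tabFile)
    utils::write.table(
      data.frame(variant = names(truthCategories(ds)),
                 category = unname(truthCategories(ds))),
      file.path(cfg$outDir, sprintf("%s.truth_categories.tsv", pid)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    patterns[[pid]] <- truthPattern(ds)
    datasets[[pid]] <- ds
  }
  utils::write.table(
    data.frame(patient = names(patterns),
               pattern = unlist(patterns, use.names = FALSE)),
    file.path(cfg$outDir, "truth_patterns.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(datasets)
}

## run presence -> categorize -> classify -> lineage for one loaded patient
classifyOnePatient <- function(variants, manifest, cfg) {
  calls <- callPatient(variants, manifest, cfg$params)
  categories <- categorizePatient(calls)
  call <- classifyRecurrencePattern(categories, calls,
                                    patientId = manifest@patientId,
                                    strictTrunkGene = cfg$strictTrunkGene)
  tree <- inferLineage(calls, tol = cfg$tol)
  list(calls = calls, categories = categories, pattern = call,
       tree = tree)
}

#' Run the full classification pipeline over patient manifests
#'
#' For each manifest: presence calling, mutation categorization,
#' recurrence-pattern classification and lineage-tree reconstruction,
#' with per-patient outputs (presence matrix TSV, category TSV, pattern
#' report JSON, Newick tree, SVZ-vs-tumor VAF scatter TSVs) and
#' cohort-level outputs (oncoplot matrix, summary TSV) under `outDir`.
#' Per-patient failures are isolated: remaining patients still run and
#' the failure is reported in the `errors` element.
#'
#' @param config a [runConfig()] list; uses `manifests`, `outDir`,
#'   `tol`, `strictTrunkGene` and the presence parameters.
#' @return list with `results` (per patient), `summary` (cohort
#'   summary), `errors` (named character).
#' @export
runClassify <- function(config) {
  cfg <- if (is.null(config$params)) runConfig(config) else config
  if (length(cfg$manifests) == 0L)
    stopf("no manifests given: nothing to classify")
  out <- cfg$outDir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    writeConfigRecord(cfg, out)
  }
  results <- list(); errors <- character()
  for (mf in cfg$manifests) {
    res <- tryCatch({
      manifest <- readPatientManifest(mf)
      tab <- manifest@samples$file[1]
      if (is.na(tab)) stopf("manifest %s names no variant table", mf)
      variants <- readVariantTable(tab)
      r <- classifyOnePatient(variants, manifest, cfg)
      pid <- manifest@patientId
      if (!is.null(out)) {
        writePresenceMatrix(r$calls,
                            file.path(out, paste0(pid, ".presence.tsv")))
        utils::write.table(r$categories,
                           file.path(out, paste0(pid, ".categories.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeRecurrenceReport(r$pattern,
                              file.path(out, paste0(pid, ".pattern.json")))
        if (!is.null(r$tree)) {
          writeNewick(r$tree, file.path(out, paste0(pid, ".tree.nwk")))
          writeTreeEdges(r$tree,
                         file.path(out, paste0(pid, ".tree_edges.tsv")))
        }
        utils::write.table(
          vafScatter(r$calls, "SVZ", "PRIMARY", r$categories),
          file.path(out, paste0(pid, ".vaf_svz_primary.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      r
    }, error = function(e) e)
    if (inherits(res, "error")) errors[mf] <- conditionMessage(res)
    else results[[patientId(res$pattern)]] <- res
  }
  summary <- NULL
  if (length(results)) {
    summary <- summarizeCohort(lapply(results, `[[`, "pattern"))
    if (!is.null(out)) {
      utils::write.table(summary$summary,
                         file.path(out, "cohort_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summary$patients,
                         file.path(out, "cohort_patients.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeOncoplotMatrix(lapply(results, `[[`, "categories"),
                          file.path(out, "oncoplot_matrix.tsv"))
    }
  }
  if (length(errors))
    warning("patient failures: ", paste(names(errors), collapse = ", "),
            call. = FALSE)
  list(results = results, summary = summary, errors = errors)
}

#' Benchmark recovery of simulated ground truth
#'
#' For each scenario, simulates patients, runs the full pipeline in
#' memory, and reports recurrence-label recovery, per-variant category
#' accuracy and mean lineage-tree concordance with binomial Monte-Carlo
#' standard errors.
#'
#' @param scenarios data.frame with columns `name`, `meanDepth`,
#'   `noiseless`, `nPatients` (one row per scenario).
#' @param config a [runConfig()] list supplying `seed`, `tol` and
#'   presence parameters.
#' @return data.frame with one row per scenario.
#' @export
runBenchmark <- function(scenarios, config = runConfig()) {
  cfg <- if (is.null(config$params)) runConfig(config) else config
  rows <- lapply(seq_len(nrow(scenarios)), function(si) {
    sc <- scenarios[si, ]
    labOK <- catOK <- catN <- 0L
    conc <- numeric(0)
    for (i in seq_len(sc$nPatients)) {
      scfg <- cfg
      scfg$meanDepth <- sc$meanDepth; scfg$noiseless <- sc$noiseless
      scfg$seed <- cfg$seed + si * 100000L
      spec <- specForScenario("balanced", i, scfg)
      ds <- simulatePatient(spec, sprintf("B%d-%03d", si, i))
      r <- classifyOnePatient(ds@variants, ds@manifest, scfg)
      labOK <- labOK + (patternLabel(r$pattern) == truthPattern(ds))
      truthCat <- truthCategories(ds)
      predCat <- stats::setNames(r$categories$category,
                                 r$categories$variant)[names(truthCat)]
      ok <- !is.na(truthCat)
      catOK <- catOK + sum(predCat[ok] == truthCat[ok], na.rm = TRUE)
      catN <- catN + sum(ok)
      if (!is.null(r$tree))
        conc <- c(conc, tryCatch(
          treeConcordance(r$tree, ds@tree, keyMap = ds@truth$keyMap),
          error = function(e) NA_real_))
    }
    n <- sc$nPatients
    labAcc <- labOK / n; catAcc <- catOK / catN
    data.frame(scenario = sc$name, nPatients = n, nVariants = catN,
               labelRecovery = labAcc,
               labelSE = sqrt(labAcc * (1 - labAcc) / n),
               categoryAccuracy = catAcc,
               categorySE = sqrt(catAcc * (1 - catAcc) / catN),
               meanTreeConcordance = mean(conc, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
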