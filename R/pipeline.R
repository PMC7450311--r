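#' Default end-to-end run configuration
#'
#' Returns the full configuration list understood by [runEndToEnd()],
#' optionally overridden from a YAML file or a named list. Sections:
#' `input` (either `simulate: true` with a `cohort` block of
#' [syntheticCohortSpec()] arguments, or `manifest`/`atlas`/`lookup` paths
#' for image data), `density` (grid size), `modeling` (classifiers,
#' iterations, train fraction, consensus threshold), `hubs` (threshold)
#' and `seed`. One master seed derives all stage seeds by fixed offsets.
#'
#' @param overrides named list or path to a YAML file.
#' @return configuration list.
#' @export
runConfig <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    input = list(simulate = TRUE, manifest = NULL, atlas = NULL,
                 lookup = NULL, cohort = list()),
    density = list(gridSize = 4096L, minVoxels = 10L),
    modeling = list(classifiers = "svm_linear", iterations = 100L,
                    trainFraction = 0.5, consensusThreshold = 0.5,
                    nFolds = 10L),
    hubs = list(threshold = 1.0),
    outDir = NULL)
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Validate a run configuration
#'
#' Checks paths and numeric ranges before any computation.
#'
#' @param cfg configuration list from [runConfig()].
#' @return the validated configuration, invisibly; errors on problems.
#' @export
validateRunConfig <- function(cfg) {
  if (!isTRUE(cfg$input$simulate)) {
    for (p in c("manifest", "atlas", "lookup")) {
      if (is.null(cfg$input[[p]]) || !file.exists(cfg$input[[p]]))
        stop("input$", p, " missing or not found: ",
             if (is.null(cfg$input[[p]])) "NULL" else cfg$input[[p]])
    }
  }
  with(cfg$modeling, {
    if (trainFraction <= 0 || trainFraction >= 1)
      stop("modeling$trainFraction must be in (0, 1)")
    if (iterations < 1) stop("modeling$iterations must be >= 1")
    if (!all(classifiers %in% c("svm_linear", "logistic_l1",
                                "random_forest")))
      stop("unknown classifier kind")
  })
  if (cfg$density$gridSize < 64) stop("density$gridSize too small")
  if (is.null(cfg$outDir)) stop("outDir must be set")
  invisible(cfg)
}

## Build RoiSampleSets either by simulation or from a manifest of images.
.loadSubjects <- function(cfg) {
  if (isTRUE(cfg$input$simulate)) {
    spec <- do.call(syntheticCohortSpec,
                    c(cfg$input$cohort,
                      list(seed = .iterSeed(cfg$seed, 0L, 10L))))
    coh <- generateCohort(spec)
    list(subjects = coh@subjects, labels = coh@labels, truth = coh@truth,
         lookup = if (spec@nRegions == 90L) aal90Lookup() else
           data.frame(label = seq_len(spec@nRegions),
                      name = paste0("region_", seq_len(spec@nRegions)),
                      x_mni = NA_real_, y_mni = NA_real_, z_mni = NA_real_,
                      lobe = NA_character_))
  } else {
    mf <- readManifest(cfg$input$manifest)
    atlas <- readAtlasVolume(cfg$input$atlas)
    lookup <- readRoiLookup(cfg$input$lookup)
    mask <- brainMask(atlas)
    subjects <- lapply(seq_len(nrow(mf)), function(k) {
      vol <- readBrainVolume(mf$image_path[k])
      vol <- normalizeGlobalMean(vol, mask)
      extractRoiSamples(vol, atlas, minVoxels = cfg$density$minVoxels,
                        subjectId = mf$subject_id[k], lookup = lookup)
    })
    list(subjects = subjects, labels = as.integer(mf$group == "pMCI"),
         truth = NULL, lookup = lookup)
  }
}

#' Run the full workflow: samples -> networks -> classification -> hubs
#'
#' Executes every stage on one configuration: load or simulate per-subject
#' region samples, build each subject's metabolic network, vectorize the
#' lower triangles into the cohort feature table, run the repeated-split
#' predictive pipeline, and derive the hub report. All artifacts (per-
#' subject networks, feature table, per-iteration results JSON,
#' performance/error tables, hub report) are written under `cfg$outDir`.
#'
#' @param cfg configuration list from [runConfig()].
#' @param verbose log stage progress (default TRUE).
#' @return invisibly, a list with the in-memory `dataset`, `results`,
#'   `hubs` and the paths written.
#' @export
runEndToEnd <- function(cfg, verbose = TRUE) {
  validateRunConfig(cfg)
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            ...)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  say("stage 1/4: loading subjects")
  inp <- .loadSubjects(cfg)
  say("  ", length(inp$subjects), " subjects")
  say("stage 2/4: building metabolic networks")
  netDir <- file.path(cfg$outDir, "networks")
  dir.create(netDir, showWarnings = FALSE)
  fvs <- vector("list", length(inp$subjects))
  for (k in seq_along(inp$subjects)) {
    net <- tryCatch(
      buildNetwork(inp$subjects[[k]], gridSize = cfg$density$gridSize,
                   minVoxels = cfg$density$minVoxels),
      error = function(e) stop("network stage failed for subject ",
                               inp$subjects[[k]]@subjectId, ": ",
                               conditionMessage(e)))
    writeNetwork(net, file.path(netDir, paste0(net@subjectId, ".csv")))
    fvs[[k]] <- vectorizeLowerTriangle(net)
  }
  say("stage 3/4: predictive modeling (",
      cfg$modeling$iterations, " iterations)")
  ds <- cohortDataset(fvs, inp$labels,
                      vapply(inp$subjects, slot, character(1), "subjectId"))
  featPath <- file.path(cfg$outDir, "features.csv")
  writeFeatureTable(ds, featPath)
  results <- runPipeline(ds, nIterations = cfg$modeling$iterations,
                         trainFraction = cfg$modeling$trainFraction,
                         kinds = cfg$modeling$classifiers,
                         baseSeed = .iterSeed(cfg$seed, 0L, 20L),
                         consensusThreshold = cfg$modeling$consensusThreshold,
                         nFolds = cfg$modeling$nFolds)
  resPath <- file.path(cfg$outDir, "results.json")
  jsonlite::write_json(
    lapply(results, function(r)
      list(classifier = r@classifier,
           summary = r@summary,
           consensus_features = r@consensusFeatures,
           per_iteration = lapply(r@perIteration, function(x)
             list(iteration = x$iteration, n_selected = length(x$selected),
                  selected = x$selected, lambda = x$lambda,
                  metrics = x$metrics)))),
    resPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tabs <- performanceTables(results)
  write.csv(tabs$performance, file.path(cfg$outDir, "performance.csv"),
            row.names = FALSE)
  write.csv(tabs$error_rates, file.path(cfg$outDir, "error_rates.csv"),
            row.names = FALSE)
  say("stage 4/4: hub identification")
  hubs <- tryCatch(
    hubsFromResult(results[[1L]], ds@featureIndex, lookup = inp$lookup,
                   threshold = cfg$hubs$threshold),
    error = function(e) {
      say("  hub stage skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(hubs))
    writeHubReport(hubs, file.path(cfg$outDir, "hubs.csv"),
                   file.path(cfg$outDir, "hubs.json"))
  say("done in ", format(round(difftime(Sys.time(), t0, units = "mins"), 2)),
      " (seed ", cfg$seed, ")")
  invisible(list(dataset = ds, results = results, hubs = hubs,
                 truth = inp$truth,
                 paths = list(features = featPath, results = resPath,
                              networks = netDir)))
}
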