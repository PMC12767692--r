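#' @include AllClasses.R AllGenerics.R synthetic.R curves.R cross-sections.R
#' @include signature-discovery.R models.R shapley.R evaluation.R
NULL

#' Pipeline configuration
#'
#' Assembles the effective configuration for [runPipeline()], with every
#' stage's parameters explicit. A single global seed deterministically
#' derives per-stage seeds. Serializable to/from YAML with
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param inputDir directory with an ingested cohort in canonical layout, or
#'   NULL to simulate one.
#' @param nRecords,nVars,mSourcesTrue synthetic-cohort size (used when
#'   `inputDir` is NULL).
#' @param densityPerYear cross-section sampling density.
#' @param m number of sources to discover.
#' @param icaTol,icaMaxIter ICA settings.
#' @param bandwidthDays,floorRate,persistenceDays curve-transformation
#'   settings.
#' @param architecture,nSeeds attribution model settings.
#' @param shapPermutations,shapBackground,shapMaxSamples Shapley estimator
#'   settings.
#' @param labelWindow outcome label window (relative days, inclusive).
#' @param testFraction held-out fraction for the attribution model.
#' @param seed global seed.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(inputDir = NULL, nRecords = 2000L, nVars = 60L,
                           mSourcesTrue = 8L, densityPerYear = 1 / 3,
                           m = 8L, icaTol = 1e-4, icaMaxIter = 500L,
                           bandwidthDays = 180, floorRate = 0.01,
                           persistenceDays = 90,
                           architecture = "random_forest", nSeeds = 1L,
                           shapPermutations = 8L, shapBackground = 128L,
                           shapMaxSamples = 500L,
                           labelWindow = c(4, 1095), testFraction = 0.2,
                           seed = 1L) {
  cfg <- list(inputDir = inputDir, nRecords = as.integer(nRecords),
              nVars = as.integer(nVars),
              mSourcesTrue = as.integer(mSourcesTrue),
              densityPerYear = densityPerYear, m = as.integer(m),
              icaTol = icaTol, icaMaxIter = as.integer(icaMaxIter),
              bandwidthDays = bandwidthDays, floorRate = floorRate,
              persistenceDays = persistenceDays,
              architecture = architecture, nSeeds = as.integer(nSeeds),
              shapPermutations = as.integer(shapPermutations),
              shapBackground = as.integer(shapBackground),
              shapMaxSamples = as.integer(shapMaxSamples),
              labelWindow = as.numeric(labelWindow),
              testFraction = testFraction, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' @rdname pipelineConfig
#' @param config a PipelineConfig.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stage definitions: which config fields each stage depends on, and its
# upstream stages (the dependency graph used for selective re-runs)
.stageDefs <- list(
  ingest = list(deps = character(),
                keys = c("inputDir", "nRecords", "nVars", "mSourcesTrue",
                         "seed")),
  curves = list(deps = "ingest",
                keys = c("bandwidthDays", "floorRate", "persistenceDays")),
  xsect = list(deps = "curves", keys = c("densityPerYear", "seed")),
  discover = list(deps = "xsect",
                  keys = c("m", "icaTol", "icaMaxIter", "seed")),
  attribute = list(deps = c("discover", "ingest", "curves"),
                   keys = c("architecture", "nSeeds", "shapPermutations",
                            "shapBackground", "shapMaxSamples",
                            "testFraction", "seed")),
  evaluate = list(deps = c("attribute", "ingest"), keys = character()))

.stageRunners <- function() list(
  ingest = function(cfg, art) {
    if (!is.null(cfg$inputDir)) {
      cohort <- readCohort(cfg$inputDir)
      truth <- NULL
    } else {
      gt <- sampleGroundTruth(cfg$nVars, cfg$mSourcesTrue,
                              seed = deriveSeed(cfg$seed, "truth"))
      sim <- simulateCohort(gt, simConfig(cfg$nRecords,
                                          seed = deriveSeed(cfg$seed,
                                                            "cohort")))
      cohort <- sim$cohort
      truth <- list(gt = gt, expressions = sim$expressions,
                    labels = sim$labels)
    }
    list(cohort = cohort, truth = truth,
         catalog = buildCatalog(cohort))
  },
  curves = function(cfg, art) {
    ing <- art$ingest
    list(curvesets = cohortCurves(ing$cohort, ing$catalog,
                                  bandwidthDays = cfg$bandwidthDays,
                                  floorRate = cfg$floorRate,
                                  persistenceDays = cfg$persistenceDays))
  },
  xsect = function(cfg, art) {
    plan <- samplingPlan(art$curves$curvesets, cfg$densityPerYear,
                         seed = deriveSeed(cfg$seed, "xsect"))
    x <- assembleMatrix(art$curves$curvesets, plan, art$ingest$catalog)
    std <- fitStandardizer(x)
    list(x = applyStandardizer(std, x), standardizer = std)
  },
  discover = function(cfg, art) {
    discoverSignatures(art$xsect$x, cfg$m, art$xsect$standardizer,
                       tol = cfg$icaTol, maxIter = cfg$icaMaxIter,
                       seed = deriveSeed(cfg$seed, "ica"))
  },
  attribute = function(cfg, art) {
    ing <- art$ingest
    cohort <- ing$cohort
    y <- as.integer(recordLabels(cohort)[recordIds(cohort)] == "positive")
    evalX <- assembleMatrix(art$curves$curvesets, indexDayPlan(cohort),
                            ing$catalog)
    evalX <- applyStandardizer(art$xsect$standardizer, evalX)
    S <- t(exprValues(inferExpressions(art$discover$model, evalX)))
    set.seed(deriveSeed(cfg$seed, "split"))
    testIdx <- sort(sample(length(y), round(cfg$testFraction * length(y))))
    trIdx <- setdiff(seq_along(y), testIdx)
    cfgM <- modelConfig(cfg$architecture, "sources",
                        seed = deriveSeed(cfg$seed, "model"))
    fit <- trainModel(cfgM, S[trIdx, , drop = FALSE], y[trIdx])
    aucTest <- aucScore(fit$predict(S[testIdx, , drop = FALSE]), y[testIdx])
    set.seed(deriveSeed(cfg$seed, "shapbg"))
    bg <- S[sample(trIdx, min(cfg$shapBackground, length(trIdx))), ,
            drop = FALSE]
    explIdx <- if (length(testIdx) > cfg$shapMaxSamples)
      sort(sample(testIdx, cfg$shapMaxSamples)) else testIdx
    expl <- shapleyValues(fit, S[explIdx, , drop = FALSE], bg,
                          nPermutations = cfg$shapPermutations,
                          seed = deriveSeed(cfg$seed, "shap"))
    list(model = fit, aucTest = aucTest, testIdx = testIdx,
         explIdx = explIdx, explanation = expl,
         effects = aggregateEffects(expl), expressions = S, labels = y)
  },
  evaluate = function(cfg, art) {
    out <- list(effects = art$attribute$effects,
                aucTest = art$attribute$aucTest)
    truth <- art$ingest$truth
    if (!is.null(truth)) {
      ids <- recordIds(art$ingest$cohort)
      out$recovery <- recoveryScore(truth$expressions,
                                    t(art$attribute$expressions))
      out$causalSources <- truth$gt@causalSources
    }
    out
  })

.stageHash <- function(cfg, stage, hashes) {
  def <- .stageDefs[[stage]]
  objectHash(list(cfg[def$keys], hashes[def$deps],
                  version = as.character(utils::packageVersion("ehrsig"))))
}

#' Run the discovery-and-attribution pipeline
#'
#' Executes ingest (or simulate) -> curves -> cross-sections -> discovery ->
#' attribution -> evaluation in dependency order, persisting each stage
#' artifact under `outDir` and recording config hashes in a manifest. On
#' re-runs, stages whose configuration and upstream inputs are unchanged are
#' skipped; changing one parameter re-runs only the stages downstream of it.
#' A manifest whose stored configuration disagrees with the requested one is
#' refused unless `force = TRUE`.
#'
#' @param config a [pipelineConfig()] or a YAML path.
#' @param outDir run directory for artifacts and the manifest.
#' @param force overwrite a mismatching previous run.
#' @param quiet suppress stage logging.
#' @return list(artifacts, manifest, ran = names of stages executed).
#' @export
runPipeline <- function(config, outDir, force = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(outDir, "manifest.json")
  cfgHash <- objectHash(unclass(config))
  prev <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL
  if (!is.null(prev) && !identical(prev$config_hash, cfgHash) && !force)
    stop("runPipeline: existing run at ", outDir,
         " used a different configuration; use force = TRUE to redo ",
         "(stages unaffected by the change are still reused)")
  log <- function(...) if (!quiet) message("[ehrsig] ", ...)
  runners <- .stageRunners()
  artifacts <- list()
  hashes <- character()
  ran <- character()
  for (stage in names(.stageDefs)) {
    h <- .stageHash(config, stage, hashes)
    f <- file.path(outDir, paste0(stage, ".rds"))
    cached <- !is.null(prev) && identical(prev$stages[[stage]], h) &&
      file.exists(f)
    if (cached) {
      log("stage ", stage, ": cached, skipping")
      artifacts[[stage]] <- readRDS(f)
    } else {
      log("stage ", stage, ": running")
      artifacts[[stage]] <- tryCatch(runners[[stage]](config, artifacts),
        error = function(e)
          stop("pipeline stage '", stage, "' failed (artifact: ", f, "): ",
               conditionMessage(e)))
      saveRDS(artifacts[[stage]], f, version = 3)
      ran <- c(ran, stage)
    }
    hashes[stage] <- h
  }
  # echo the effective config into the run directory
  writePipelineConfig(config, file.path(outDir, "config.yaml"))
  manifest <- list(config_hash = cfgHash, stages = as.list(hashes),
                   config = unclass(config),
                   package_version =
                     as.character(utils::packageVersion("ehrsig")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  effectsPath <- file.path(outDir, "effects.csv")
  data.table::fwrite(artifacts$attribute$effects, effectsPath)
  invisible(list(artifacts = artifacts, manifest = manifest, ran = ran))
}
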