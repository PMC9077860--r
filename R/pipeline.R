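# Configuration-driven end-to-end orchestration: descriptors ->
# pretreatment -> division -> GA/DCV selection -> PLS -> validation ->
# applicability domain -> Y-randomization, with every intermediate
# written to disk and a reproducibility manifest.

#' Build a pipeline configuration
#'
#' Input is either \code{smilesPath} + \code{activityPath} (CSV with
#' header \code{id,value}) or an in-memory molecule list + activity
#' vector. All stage parameters mirror the individual stage functions.
#'
#' @param smilesPath,activityPath input files (ignored when
#'   \code{molecules} is given).
#' @param molecules optional named list of \linkS4class{Molecule}.
#' @param activity optional named numeric pLC50 vector.
#' @param activityKind \code{"pLC50"} or \code{"LC50"} for file input.
#' @param outputDir directory for stage artifacts.
#' @param sdCut,corrCut pretreatment cutoffs.
#' @param k,testFraction division parameters.
#' @param dcv a \code{\link{dcvConfig}}.
#' @param nLv latent variables for the final PLS fit (NULL = pick by Q2).
#' @param confidence named vector with \code{t2} and \code{dmodx} levels.
#' @param nPerm Y-randomization permutation count.
#' @param seed master seed for division and randomization.
#' @return configuration list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(smilesPath = NULL, activityPath = NULL,
                           molecules = NULL, activity = NULL,
                           activityKind = "pLC50",
                           outputDir = tempfile("qsar_run_"),
                           sdCut = 1e-4, corrCut = 0.95,
                           k = 5, testFraction = 0.34,
                           dcv = dcvConfig(), nLv = 3,
                           confidence = c(t2 = 0.95, dmodx = 0.99),
                           nPerm = 100, seed = 1) {
  cfg <- list(smilesPath = smilesPath, activityPath = activityPath,
              molecules = molecules, activity = activity,
              activityKind = activityKind, outputDir = outputDir,
              sdCut = sdCut, corrCut = corrCut, k = k,
              testFraction = testFraction, dcv = dcv, nLv = nLv,
              confidence = confidence, nPerm = nPerm,
              seed = as.integer(seed))
  if (is.null(cfg$molecules) &&
      (is.null(cfg$smilesPath) || is.null(cfg$activityPath)))
    stop("either molecules/activity or smilesPath/activityPath required")
  class(cfg) <- "pipelineConfig"
  cfg
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full QSAR pipeline
#'
#' Executes descriptor computation, pretreatment, k-medoids division,
#' GA/DCV descriptor selection, the final PLS fit, validation,
#' applicability-domain assessment and Y-randomization; every stage
#' writes its artifact under \code{outputDir} and the manifest records
#' the seed and configuration so a rerun reproduces the run byte for
#' byte (timestamps aside). A stage failure aborts with the stage name;
#' artifacts of completed stages are retained.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$outputDir, f)
  artifacts <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mols <- stage("input", {
    if (!is.null(config$molecules)) config$molecules
    else readSmiles(config$smilesPath)
  })
  act <- stage("input", {
    if (!is.null(config$activity)) config$activity
    else readActivity(config$activityPath, config$activityKind)
  })

  desc <- stage("descriptors", etaDescriptors(mols))
  utils::write.csv(data.frame(id = rownames(desc), desc, check.names = FALSE),
                   art("descriptors.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "descriptors.csv")

  table <- stage("descriptors", descriptorTable(desc, act))
  pre <- stage("pretreat", pretreat(table, config$sdCut, config$corrCut))
  utils::write.csv(pre$log, art("pretreatment_log.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "pretreatment_log.csv")

  split <- stage("split", {
    cl <- kMedoids(pre$table, k = config$k, seed = config$seed)
    splitTrainTest(cl, pre$table, config$testFraction)
  })
  .writeJson(list(train = trainIds(split), test = testIds(split),
                  clusters = as.list(clusterAssignments(split)),
                  medoids = medoidIds(split), seed = config$seed),
             art("split.json"))
  artifacts <- c(artifacts, "split.json")

  train <- pre$table[trainIds(split), ]
  test <- pre$table[testIds(split), ]
  candidates <- stage("select", runGA(train, config$dcv))
  selection <- stage("select", dcvReport(candidates, train, test))
  utils::write.csv(selection, art("selection.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "selection.csv")
  subset <- strsplit(selection$subset[1], "+", fixed = TRUE)[[1]]

  fitv <- stage("fit", validateModel(train, test, subset = subset,
                                     nLv = config$nLv,
                                     nPerm = config$nPerm,
                                     seed = config$seed))
  model <- fitv$model
  .writeJson(list(nLv = nLatent(model), descriptors = subset,
                  xMean = as.list(model@xMean), xSd = as.list(model@xSd),
                  yMean = model@yMean,
                  W = apply(model@W, 2, as.numeric, simplify = FALSE),
                  P = apply(model@P, 2, as.numeric, simplify = FALSE),
                  q = model@q, coef = as.list(model@coef)),
             art("model.json"))
  artifacts <- c(artifacts, "model.json")

  rep <- fitv$report
  .writeJson(list(r2 = rep@r2, q2Loo = rep@q2Loo, q2F1 = rep@q2F1,
                  q2F2 = rep@q2F2, rmseTrain = rep@rmseTrain,
                  rmseTest = rep@rmseTest, see = rep@see, f = rep@fStat,
                  yRandomization = rep@yRand[c("r2Intercept",
                                               "q2Intercept", "pass",
                                               "nPerm")]),
             art("validation.json"))
  artifacts <- c(artifacts, "validation.json")

  ad <- stage("ad", {
    Xall <- descriptorValues(pre$table)[, subset, drop = FALSE]
    dmodx(model, Xall, ids = compoundIds(pre$table),
          confidence = config$confidence[["dmodx"]])
  })
  utils::write.csv(data.frame(id = ad@ids, dmodx = ad@dmodx, t2 = ad@t2,
                              inDomain = ad@inDomain),
                   art("applicability_domain.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "applicability_domain.csv")

  cfgPath <- art("config.json")
  cfgOut <- config[setdiff(names(config), c("molecules", "activity"))]
  cfgOut$dcv <- unclass(cfgOut$dcv)
  .writeJson(cfgOut, cfgPath)
  manifest <- list(
    package = "etaqsar",
    version = as.character(utils::packageVersion("etaqsar")),
    seed = config$seed,
    configHash = unname(tools::md5sum(cfgPath)),
    nCompounds = length(mols),
    nDescriptorsRaw = ncol(desc),
    nDescriptorsPretreated = ncol(descriptorValues(pre$table)),
    selectedSubset = subset,
    artifacts = c(artifacts, "config.json"))
  .writeJson(manifest, art("manifest.json"))
  invisible(manifest)
}
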