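#' @import methods
NULL

#' Molecule: a labelled molecular graph
#'
#' A hydrogen-explicit, Kekulized molecular graph. Atoms carry the element
#' symbol, atomic number \code{Z}, valence electron count \code{Zv} and
#' period number \code{PN} needed by the ETA atomic formulas; bonds carry an
#' integer order (1-3) and an aromatic-ring flag assigned after Kekulization.
#' The hydrogen-suppressed view is obtained with \code{\link{heavySkeleton}}.
#'
#' @slot id single compound identifier.
#' @slot name optional free-text name.
#' @slot atoms data.frame with columns \code{element}, \code{Z}, \code{Zv},
#'   \code{PN}, \code{isH} (logical), \code{charge} (integer, expected 0).
#' @slot bonds data.frame with columns \code{from}, \code{to} (1-based atom
#'   indices), \code{order} (1-3) and \code{aromatic} (logical).
#' @export
setClass("Molecule",
  representation(id = "character", name = "character",
                 atoms = "data.frame", bonds = "data.frame"))

setValidity("Molecule", function(object) {
  msg <- character()
  a <- object@atoms; b <- object@bonds
  need_a <- c("element", "Z", "Zv", "PN", "isH", "charge")
  need_b <- c("from", "to", "order", "aromatic")
  if (!all(need_a %in% names(a))) msg <- c(msg, "atoms lacks required columns")
  if (!all(need_b %in% names(b))) msg <- c(msg, "bonds lacks required columns")
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(msg) == 0L && nrow(b) > 0L) {
    if (any(b$from == b$to)) msg <- c(msg, "bond endpoints must be distinct")
    if (any(b$from < 1L | b$to < 1L | b$from > nrow(a) | b$to > nrow(a)))
      msg <- c(msg, "bond endpoint out of range")
    if (!all(b$order %in% 1:3)) msg <- c(msg, "bond order must be 1, 2 or 3")
  }
  if (length(msg) == 0L && nrow(a) > 0L) {
    if (any(a$Z < 1L)) msg <- c(msg, "Z must be >= 1")
    if (any(a$Zv < 1L | a$Zv > 8L)) msg <- c(msg, "Zv must lie in 1..8")
    hrow <- which(a$isH)
    if (length(hrow)) {
      deg <- tabulate(c(b$from, b$to), nbins = nrow(a))
      if (any(deg[hrow] != 1L))
        msg <- c(msg, "every hydrogen must have exactly one bond")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DescriptorTable: compounds x descriptors joined with a response
#'
#' @slot ids ordered compound identifiers (unique).
#' @slot values numeric matrix, one row per compound, named columns.
#' @slot response numeric response (pLC50), aligned with rows; may contain
#'   NA when the table is used response-free.
#' @export
setClass("DescriptorTable",
  representation(ids = "character", values = "matrix", response = "numeric"))

setValidity("DescriptorTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "compound ids must be unique")
  if (nrow(object@values) != length(object@ids))
    msg <- c(msg, "value matrix rows must match ids")
  if (length(object@response) != length(object@ids))
    msg <- c(msg, "response must align with ids")
  if (is.null(colnames(object@values)) && ncol(object@values) > 0L)
    msg <- c(msg, "descriptor columns must be named")
  if (length(msg)) msg else TRUE
})

#' SplitResult: clustering and train/test division of a dataset
#'
#' @slot clusters integer cluster label per compound, named by id.
#' @slot medoids ids of the cluster medoids.
#' @slot trainIds,testIds disjoint id sets whose union is all compounds
#'   (both empty until \code{\link{splitTrainTest}} has run).
#' @export
setClass("SplitResult",
  representation(clusters = "integer", medoids = "character",
                 trainIds = "character", testIds = "character"))

setValidity("SplitResult", function(object) {
  msg <- character()
  ids <- names(object@clusters)
  if (is.null(ids)) msg <- c(msg, "clusters must be named by compound id")
  if (length(object@trainIds) || length(object@testIds)) {
    if (length(intersect(object@trainIds, object@testIds)))
      msg <- c(msg, "train and test sets must be disjoint")
    if (!setequal(c(object@trainIds, object@testIds), ids))
      msg <- c(msg, "train + test must partition the dataset")
  }
  if (length(object@medoids) && !all(object@medoids %in% ids))
    msg <- c(msg, "every medoid must be a dataset member")
  if (length(msg)) msg else TRUE
})

#' PLSModel: a fitted NIPALS PLS1 regression
#'
#' X is autoscaled (zero mean, unit variance) and y mean-centred before the
#' NIPALS iterations; one latent variable is extracted per deflation round
#' under the sign convention that every y-loading \code{q[a]} is
#' non-negative, which makes weights, scores and loadings reproducible.
#'
#' @slot nLv number of latent variables.
#' @slot xMean,xSd,yMean centring/scaling parameters.
#' @slot W,P weight and X-loading matrices (p x a).
#' @slot q y-loadings (length a).
#' @slot scores training score matrix T (n x a).
#' @slot coef regression coefficients on the original variable scale,
#'   first element the intercept.
#' @slot xVar,yVar fraction of (scaled) X and y variance explained per LV.
#' @slot y,fitted training response and fitted values.
#' @slot trainXs autoscaled training X (kept for residual diagnostics).
#' @export
setClass("PLSModel",
  representation(nLv = "integer", xMean = "numeric", xSd = "numeric",
                 yMean = "numeric", W = "matrix", P = "matrix", q = "numeric",
                 scores = "matrix", coef = "numeric", xVar = "numeric",
                 yVar = "numeric", y = "numeric", fitted = "numeric",
                 trainXs = "matrix"))

setValidity("PLSModel", function(object) {
  msg <- character()
  a <- object@nLv
  if (ncol(object@W) != a || ncol(object@P) != a || length(object@q) != a)
    msg <- c(msg, "W, P, q dimensions must match nLv")
  if (a > 0 && any(object@q < -1e-12))
    msg <- c(msg, "sign convention requires q >= 0")
  if (length(msg)) msg else TRUE
})

#' AdReport: applicability-domain diagnostics
#'
#' @slot ids compound ids.
#' @slot dmodx normalized distance-to-model in X-space per compound.
#' @slot dCrit critical DModX value at \code{confidence}.
#' @slot t2 Hotelling T-squared per compound; \code{t2Crit} its limit.
#' @slot inDomain logical flag per compound (dmodx <= dCrit).
#' @slot confidence confidence level used.
#' @export
setClass("AdReport",
  representation(ids = "character", dmodx = "numeric", dCrit = "numeric",
                 t2 = "numeric", t2Crit = "numeric", inDomain = "logical",
                 confidence = "numeric"))

setValidity("AdReport", function(object) {
  ok <- object@inDomain == (object@dmodx <= object@dCrit + 1e-12)
  if (all(ok)) TRUE else "inDomain flags inconsistent with dCrit"
})

#' ValidationReport: internal and external model statistics
#'
#' @slot r2 determination coefficient on the training set.
#' @slot q2Loo leave-one-out cross-validated Q2.
#' @slot q2F1,q2F2 external predictivity metrics.
#' @slot rmseTrain,rmseTest root mean square errors.
#' @slot see standard error of estimate; \code{fStat} variance ratio;
#'   \code{df} its degrees-of-freedom pair.
#' @slot yRand list with Y-randomization results (n permutations,
#'   intercepts, per-permutation records) or empty list.
#' @export
setClass("ValidationReport",
  representation(r2 = "numeric", q2Loo = "numeric", q2F1 = "numeric",
                 q2F2 = "numeric", rmseTrain = "numeric", rmseTest = "numeric",
                 see = "numeric", fStat = "numeric", df = "numeric",
                 yRand = "list"))

setValidity("ValidationReport", function(object) {
  msg <- character()
  for (s in c("r2", "q2F1", "q2F2"))
    if (length(slot(object, s)) && is.finite(slot(object, s)) &&
        slot(object, s) > 1 + 1e-12)
      msg <- c(msg, paste(s, "cannot exceed 1"))
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: recipe for a synthetic molecule/activity set
#'
#' @slot nCompounds number of molecules to generate.
#' @slot heteroWeight probability that a generated substituent carries
#'   heteroatoms (controls the oxygenated fraction of the set).
#' @slot maxSubstituents maximum substituent count per scaffold.
#' @slot trueSubset descriptor names carrying the activity signal.
#' @slot trueCoefficients coefficients on autoscaled descriptors.
#' @slot noiseSd standard deviation of the Gaussian activity noise.
#' @slot seed integer seed making generation reproducible.
#' @export
setClass("SyntheticSpec",
  representation(nCompounds = "integer", heteroWeight = "numeric",
                 maxSubstituents = "integer", trueSubset = "character",
                 trueCoefficients = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (is.finite(object@noiseSd) && object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@trueSubset) != length(object@trueCoefficients))
    msg <- c(msg, "trueSubset and trueCoefficients must align")
  if (object@nCompounds < 1L) msg <- c(msg, "nCompounds must be >= 1")
  if (length(msg)) msg else TRUE
})
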