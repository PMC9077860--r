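# Conformance check against an external reference descriptor table.
# Users who hold the published supplementary tables of a larvicide panel
# (structures + tabulated values of the five modelling descriptors and a
# train/test membership) can verify this implementation against them.

#' Check descriptor and model conformance against reference tables
#'
#' Recomputes the five modelling descriptors (\code{ETA_dEpsilon_D},
#' \code{ETA_EtaP_F}, \code{ETA_dAlpha_B}, \code{ETA_BetaP_s},
#' \code{ETA_dEpsilon_C}) for the listed structures and compares them with
#' the tabulated reference values; then fits the PLS model with the given
#' latent-variable count on the reference train/test membership and
#' reports the usual statistics (R2, Q2LOO, Q2F1, SEE train/test,
#' component weights, Y-randomization intercepts) for comparison with the
#' published ones.
#'
#' @param structures data.frame with columns \code{id}, \code{smiles} and
#'   either \code{pLC50} or \code{LC50}.
#' @param reference data.frame with columns \code{id}, \code{set}
#'   (\code{"train"}/\code{"test"}) and one column per modelling
#'   descriptor.
#' @param nLv latent variables (default 3).
#' @param tol descriptor agreement tolerance (default 1e-3).
#' @param nPerm Y-randomization permutations (default 100).
#' @param seed seed for the permutations.
#' @return list with \code{descriptorAgreement} (logical matrix),
#'   \code{maxAbsDiff}, \code{stats} (named numeric), \code{weights}
#'   (p x 2 matrix, first two components) and \code{yRand}.
#' @export
checkReferenceConformance <- function(structures, reference, nLv = 3,
                                      tol = 1e-3, nPerm = 100, seed = 1) {
  need <- c("ETA_dEpsilon_D", "ETA_EtaP_F", "ETA_dAlpha_B",
            "ETA_BetaP_s", "ETA_dEpsilon_C")
  if (!all(c("id", "smiles") %in% names(structures)))
    stop("structures needs columns id, smiles")
  if (!all(c("id", "set", need) %in% names(reference)))
    stop("reference needs columns id, set and the five model descriptors")
  mols <- mapply(.parseSmiles, structures$smiles, structures$id,
                 SIMPLIFY = FALSE)
  desc <- etaDescriptors(mols)[reference$id, need, drop = FALSE]
  refm <- as.matrix(reference[, need])
  rownames(refm) <- reference$id
  diff <- abs(desc - refm)
  act <- if ("pLC50" %in% names(structures))
    stats::setNames(structures$pLC50, structures$id)
  else stats::setNames(-log10(structures$LC50), structures$id)
  tab <- descriptorTable(desc, act[reference$id])
  train <- tab[reference$id[reference$set == "train"], ]
  test <- tab[reference$id[reference$set == "test"], ]
  fitv <- validateModel(train, test, nLv = nLv, nPerm = nPerm, seed = seed)
  rep <- fitv$report
  w <- plsWeights(fitv$model)
  list(descriptorAgreement = diff <= tol,
       maxAbsDiff = apply(diff, 2, max),
       stats = c(r2 = rep@r2, q2Loo = rep@q2Loo, q2F1 = rep@q2F1,
                 seeTrain = rep@see,
                 seeTest = standardError(response(test),
                                         predict(fitv$model,
                                                 descriptorValues(test)),
                                         nLv)),
       weights = w[, seq_len(min(2L, ncol(w))), drop = FALSE],
       yRand = rep@yRand[c("r2Intercept", "q2Intercept")])
}
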