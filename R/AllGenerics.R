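# Generics and accessors. Slot access from user code goes through these.

#' @rdname Molecule-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("molId", function(object) standardGeneric("molId"))
#' @rdname Molecule-class
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))
#' @rdname Molecule-class
#' @export
setGeneric("bondTable", function(object) standardGeneric("bondTable"))
#' @rdname Molecule-class
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
#' @rdname Molecule-class
#' @export
setGeneric("nHeavyAtoms", function(object) standardGeneric("nHeavyAtoms"))

#' @rdname Molecule-class
#' @export
setMethod("molId", "Molecule", function(object) object@id)
#' @rdname Molecule-class
#' @export
setMethod("atomTable", "Molecule", function(object) object@atoms)
#' @rdname Molecule-class
#' @export
setMethod("bondTable", "Molecule", function(object) object@bonds)
#' @rdname Molecule-class
#' @export
setMethod("nAtoms", "Molecule", function(object) nrow(object@atoms))
#' @rdname Molecule-class
#' @export
setMethod("nHeavyAtoms", "Molecule", function(object) sum(!object@atoms$isH))

setMethod("show", "Molecule", function(object) {
  heavy <- sum(!object@atoms$isH)
  cat("Molecule", object@id,
      if (length(object@name) && nzchar(object@name[1]))
        paste0("(", object@name[1], ")") else "",
      "\n  ", heavy, "heavy atoms,", sum(object@atoms$isH), "hydrogens,",
      nrow(object@bonds), "bonds\n")
})

#' @rdname DescriptorTable-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))
#' @rdname DescriptorTable-class
#' @export
setGeneric("descriptorNames", function(object) standardGeneric("descriptorNames"))
#' @rdname DescriptorTable-class
#' @export
setGeneric("descriptorValues", function(object) standardGeneric("descriptorValues"))
#' @rdname DescriptorTable-class
#' @export
setGeneric("response", function(object) standardGeneric("response"))

#' @rdname DescriptorTable-class
#' @export
setMethod("compoundIds", "DescriptorTable", function(object) object@ids)
#' @rdname DescriptorTable-class
#' @export
setMethod("descriptorNames", "DescriptorTable", function(object) colnames(object@values))
#' @rdname DescriptorTable-class
#' @export
setMethod("descriptorValues", "DescriptorTable", function(object) {
  m <- object@values
  rownames(m) <- object@ids
  m
})
#' @rdname DescriptorTable-class
#' @export
setMethod("response", "DescriptorTable", function(object) {
  stats::setNames(object@response, object@ids)
})

setMethod("show", "DescriptorTable", function(object) {
  cat("DescriptorTable:", length(object@ids), "compounds x",
      ncol(object@values), "descriptors;",
      sum(!is.na(object@response)), "responses\n")
})

#' Subset a DescriptorTable by compound id or descriptor name
#'
#' @param x a \linkS4class{DescriptorTable}.
#' @param i compound ids (character) or row indices.
#' @param j descriptor names (character) or column indices.
#' @param ... ignored.
#' @param drop ignored; a DescriptorTable is always returned.
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
  ri <- if (missing(i)) seq_along(x@ids) else
    if (is.character(i)) match(i, x@ids) else i
  if (anyNA(ri)) stop("unknown compound id")
  ci <- if (missing(j)) seq_len(ncol(x@values)) else
    if (is.character(j)) match(j, colnames(x@values)) else j
  if (anyNA(ci)) stop("unknown descriptor name")
  new("DescriptorTable", ids = x@ids[ri],
      values = x@values[ri, ci, drop = FALSE], response = x@response[ri])
})

#' @rdname SplitResult-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("trainIds", function(object) standardGeneric("trainIds"))
#' @rdname SplitResult-class
#' @export
setGeneric("testIds", function(object) standardGeneric("testIds"))
#' @rdname SplitResult-class
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))
#' @rdname SplitResult-class
#' @export
setGeneric("medoidIds", function(object) standardGeneric("medoidIds"))

#' @rdname SplitResult-class
#' @export
setMethod("trainIds", "SplitResult", function(object) object@trainIds)
#' @rdname SplitResult-class
#' @export
setMethod("testIds", "SplitResult", function(object) object@testIds)
#' @rdname SplitResult-class
#' @export
setMethod("clusterAssignments", "SplitResult", function(object) object@clusters)
#' @rdname SplitResult-class
#' @export
setMethod("medoidIds", "SplitResult", function(object) object@medoids)

setMethod("show", "SplitResult", function(object) {
  cat("SplitResult:", length(object@clusters), "compounds in",
      length(unique(object@clusters)), "clusters")
  if (length(object@trainIds))
    cat(";", length(object@trainIds), "train /", length(object@testIds), "test")
  cat("\n")
})

#' @rdname PLSModel-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("nLatent", function(object) standardGeneric("nLatent"))
#' @rdname PLSModel-class
#' @export
setGeneric("plsScores", function(object) standardGeneric("plsScores"))
#' @rdname PLSModel-class
#' @export
setGeneric("plsWeights", function(object) standardGeneric("plsWeights"))
#' @rdname PLSModel-class
#' @export
setGeneric("plsLoadings", function(object) standardGeneric("plsLoadings"))

#' @rdname PLSModel-class
#' @export
setMethod("nLatent", "PLSModel", function(object) object@nLv)
#' @rdname PLSModel-class
#' @export
setMethod("plsScores", "PLSModel", function(object) object@scores)
#' @rdname PLSModel-class
#' @export
setMethod("plsLoadings", "PLSModel", function(object) object@P)

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", nrow(object@scores), "observations,",
      length(object@xMean), "descriptors,", object@nLv, "latent variables\n")
  cat("  cumulative y-variance explained:",
      round(cumsum(object@yVar), 4), "\n")
})

setMethod("show", "AdReport", function(object) {
  cat("AdReport at", object@confidence, "confidence:",
      sum(!object@inDomain), "of", length(object@ids),
      "compounds outside the applicability domain",
      sprintf("(D-crit = %.4f)\n", object@dCrit))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport\n  R2 = %.3f  Q2(LOO) = %.3f  SEE = %.3f  F = %.1f\n",
              object@r2, object@q2Loo, object@see, object@fStat))
  if (length(object@q2F1) && is.finite(object@q2F1))
    cat(sprintf("  external: Q2F1 = %.3f  Q2F2 = %.3f  RMSEP = %.3f\n",
                object@q2F1, object@q2F2, object@rmseTest))
  if (length(object@yRand))
    cat(sprintf("  Y-randomization (%d perms): R2 intercept = %.3f, Q2 intercept = %.3f\n",
                object@yRand$nPerm, object@yRand$r2Intercept,
                object@yRand$q2Intercept))
})
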