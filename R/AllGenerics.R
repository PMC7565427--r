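#' Gene identifiers of an object
#' @param x an object carrying gene ids
#' @return character vector of gene ids
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#' @param x an object carrying sample ids
#' @return character vector of sample ids
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Drug identifiers of an object
#' @param x an object carrying drug ids
#' @return character vector of distinct drug ids, in order of first appearance
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' Genes selected by a COXEN run
#' @param x a SelectionResult
#' @return character vector of N2 genes, best generalization score first
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @describeIn ExpressionMatrix gene ids (rownames)
#' @param x object
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @describeIn ExpressionMatrix sample ids (colnames)
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @describeIn ResponseTable sample ids referenced by the records
#' @param x object
#' @export
setMethod("sampleIds", "ResponseTable", function(x) unique(x@records$sample))

#' @describeIn ResponseTable distinct drugs (D), order of first appearance
#' @export
setMethod("drugIds", "ResponseTable", function(x) unique(x@records$drug))

#' @describeIn DescriptorMatrix drug ids (rownames)
#' @param x object
#' @export
setMethod("drugIds", "DescriptorMatrix", function(x) rownames(x))

#' @describeIn GeneRanking ranked gene ids, strongest prediction power first
#' @param x object
#' @export
setMethod("geneIds", "GeneRanking", function(x) x@geneIds)

#' @describeIn CandidatePool pool gene ids
#' @param x object
#' @export
setMethod("geneIds", "CandidatePool", function(x) x@geneIds)

#' @describeIn GeneralizationScores pool gene ids
#' @param x object
#' @export
setMethod("geneIds", "GeneralizationScores", function(x) x@geneIds)

#' @describeIn SelectionResult the selected genes
#' @param x object
#' @export
setMethod("selectedGenes", "SelectionResult", function(x) x@selectedGenes)

#' Records of a ResponseTable
#' @param x a ResponseTable
#' @return the underlying data.frame (sample, drug, auc)
#' @export
responseRecords <- function(x) {
  stopifnot(is(x, "ResponseTable"))
  x@records
}

#' Pool size L of a CandidatePool
#' @param x a CandidatePool
#' @return integer L
#' @export
poolSize <- function(x) {
  stopifnot(is(x, "CandidatePool"))
  x@poolSize
}

#' Per-drug depth reached by the union loop
#' @param x a CandidatePool
#' @return integer l
#' @export
poolDepth <- function(x) {
  stopifnot(is(x, "CandidatePool"))
  x@lFinal
}

#' Generalization scores of a selection, aligned with \code{geneIds}
#' @param x a GeneralizationScores or SelectionResult
#' @return named numeric vector of scores in [-1, 1]
#' @export
geneScores <- function(x) {
  if (is(x, "SelectionResult")) x <- x@scores
  stopifnot(is(x, "GeneralizationScores"))
  stats::setNames(x@scores, x@geneIds)
}

#' Prediction-power scores of a ranking, aligned with \code{geneIds}
#' @param x a GeneRanking
#' @return named numeric vector of PPM scores in [0, 1]
#' @export
ppmScores <- function(x) {
  stopifnot(is(x, "GeneRanking"))
  stats::setNames(x@ppmScores, x@geneIds)
}

## show methods ----------------------------------------------------------

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(object), ncol(object)))
})

setMethod("show", "ResponseTable", function(object) {
  r <- object@records
  cat(sprintf("ResponseTable: %d experiments, %d samples, %d drugs\n",
              nrow(r), length(unique(r$sample)), length(unique(r$drug))))
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix: %d drugs x %d descriptors (%d missing values)\n",
              nrow(object), ncol(object), sum(is.na(object@.Data))))
})

setMethod("show", "CandidatePool", function(object) {
  cat(sprintf("CandidatePool (%s): L = %d genes, per-drug depth l = %d\n",
              object@method, object@poolSize, object@lFinal))
})

setMethod("show", "GeneRanking", function(object) {
  cat(sprintf("GeneRanking for drug '%s': %d genes, top score %.3f\n",
              object@drugId, length(object@geneIds),
              if (length(object@ppmScores)) object@ppmScores[1L] else NA_real_))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d genes selected from a pool of %d (%s, %s scores)\n",
    length(object@selectedGenes), object@pool@poolSize, object@pool@method,
    object@scores@method))
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf(
    "SigmoidFit: eInf = %.4f, log10(EC50) = %.4f, hill = %.4f, rss = %.3g%s\n",
    object@eInf, object@log10EC50, object@hill, object@rss,
    if (object@converged) "" else " (flat-curve fallback)"))
})

setMethod("show", "VariationDecomposition", function(object) {
  cat(sprintf(
    "VariationDecomposition: St = %.4f = Sb %.4f + Sw %.4f over %d classes\n",
    object@sTotal, object@sBetween, object@sWithin, object@kClasses))
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %d repeats x %d folds = %d trials over %d cell lines\n",
              object@nRepeats, object@nFolds, nrow(object@trials),
              length(object@folds[[1L]])))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat("BenchmarkReport\n")
  print(object@summary, row.names = FALSE)
  if (length(object@pip)) {
    cat("PIP (%):\n")
    print(round(object@pip, 2))
  }
  if (length(object@adjustedP)) {
    cat("BH-adjusted paired-t p-values:\n")
    print(signif(object@adjustedP, 3))
  }
})

setMethod("show", "SyntheticDataset", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SyntheticDataset: %d genes, %d + %d cell lines, %d drugs, seed %d\n",
    cfg@nGenes, cfg@nCcls1, cfg@nCcls2, cfg@nDrugs, cfg@seed))
})
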