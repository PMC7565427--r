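#' @import methods
NULL

## ---- input containers -------------------------------------------------

#' ExpressionMatrix: genes x samples expression values
#'
#' A numeric matrix of expression values with genes in rows and cancer cases
#' (cell lines, tumors) in columns. Row names are gene identifiers, column
#' names are sample identifiers; both must be unique and all values finite.
#' Correlations require at least two samples. Values are taken on whatever
#' analysis scale the caller provides (raw or log); the package never
#' transforms them.
#'
#' @slot .Data numeric matrix, genes x samples
#' @export
setClass("ExpressionMatrix", contains = "matrix")

setValidity("ExpressionMatrix", function(object) {
  v <- object@.Data
  if (!is.numeric(v)) return("expression values must be numeric")
  if (nrow(v) < 1L) return("need at least one gene")
  if (ncol(v) < 2L) return("need at least 2 samples (correlations require >= 2)")
  if (is.null(rownames(v)) || anyNA(rownames(v)) || any(rownames(v) == ""))
    return("all genes must have non-empty identifiers (rownames)")
  if (is.null(colnames(v)) || anyNA(colnames(v)) || any(colnames(v) == ""))
    return("all samples must have non-empty identifiers (colnames)")
  if (anyDuplicated(rownames(v))) {
    d <- rownames(v)[duplicated(rownames(v))][1L]
    return(sprintf("duplicate gene id: '%s'", d))
  }
  if (anyDuplicated(colnames(v))) {
    d <- colnames(v)[duplicated(colnames(v))][1L]
    return(sprintf("duplicate sample id: '%s'", d))
  }
  if (!all(is.finite(v))) return("expression values must all be finite")
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene rownames and sample colnames
#' @return an \linkS4class{ExpressionMatrix}
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values) {
  new("ExpressionMatrix", as.matrix(values))
}

#' ResponseTable: long-format drug response records
#'
#' One record per (sample, drug) experiment carrying the normalized
#' dose-response AUC in [0, 1] (0 = complete response, 1 = no response).
#' Each (sample, drug) pair appears at most once.
#'
#' @slot records data.frame with character columns \code{sample}, \code{drug}
#'   and numeric column \code{auc}
#' @export
setClass("ResponseTable", representation(records = "data.frame"))

setValidity("ResponseTable", function(object) {
  r <- object@records
  if (!all(c("sample", "drug", "auc") %in% names(r)))
    return("records must have columns sample, drug, auc")
  if (nrow(r) == 0L) return("no records")
  if (!is.numeric(r$auc)) return("auc must be numeric")
  if (anyNA(r$auc) || any(r$auc < 0 | r$auc > 1))
    return("auc values must lie in [0, 1]")
  key <- paste(r$sample, r$drug, sep = "\r")
  if (anyDuplicated(key)) {
    d <- r[duplicated(key), , drop = FALSE][1L, ]
    return(sprintf("duplicate (sample, drug) pair: ('%s', '%s')",
                   d$sample, d$drug))
  }
  TRUE
})

#' Construct a ResponseTable
#'
#' @param records data.frame with columns \code{sample}, \code{drug},
#'   \code{auc}
#' @return a \linkS4class{ResponseTable}
#' @export
ResponseTable <- function(records) {
  records <- as.data.frame(records)
  records$sample <- as.character(records$sample)
  records$drug <- as.character(records$drug)
  new("ResponseTable", records = records)
}

#' DescriptorMatrix: drugs x molecular descriptors
#'
#' Numeric matrix of molecular descriptors, one row per drug. Missing entries
#' (NA) are permitted until \code{\link{filterDescriptorsComplete}} removes
#' incomplete descriptor columns.
#'
#' @export
setClass("DescriptorMatrix", contains = "matrix")

setValidity("DescriptorMatrix", function(object) {
  v <- object@.Data
  if (!is.numeric(v)) return("descriptor values must be numeric")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("drug ids (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    return("descriptor names (colnames) must be present and unique")
  TRUE
})

#' Construct a DescriptorMatrix
#'
#' @param values numeric matrix, drugs in rows, descriptors in columns
#' @return a \linkS4class{DescriptorMatrix}
#' @export
DescriptorMatrix <- function(values) {
  new("DescriptorMatrix", as.matrix(values))
}

## ---- configuration ----------------------------------------------------

#' CoxenConfig: parameters of a COXEN gene-selection run
#'
#' @slot n1 candidate pool size target N1
#' @slot n2 number of genes finally selected, N2 (N1 > N2 > 1)
#' @slot ppm prediction power measure; only \code{"abs_pearson"} ships
#' @slot generalization agreement statistic for co-expression preservation,
#'   \code{"ccc"} (Lin's concordance) or \code{"pearson"}
#' @slot nFolds,nRepeats cross-validation layout (default 10 x 10)
#' @slot seed integer seed driving all randomness downstream
#' @slot nrounds,earlyStoppingRounds gradient-boosting schedule: maximal
#'   boosting steps and the early-stopping patience on the validation fold
#' @export
setClass("CoxenConfig", representation(
  n1 = "integer", n2 = "integer", ppm = "character",
  generalization = "character", nFolds = "integer", nRepeats = "integer",
  seed = "integer", nrounds = "integer", earlyStoppingRounds = "integer"))

setValidity("CoxenConfig", function(object) {
  if (object@n1 <= object@n2 || object@n2 <= 1L)
    return("need N1 > N2 > 1")
  if (!object@ppm %in% "abs_pearson")
    return("unknown prediction power measure")
  if (!object@generalization %in% c("ccc", "pearson"))
    return("generalization must be 'ccc' or 'pearson'")
  if (object@nFolds < 2L || object@nRepeats < 1L)
    return("need nFolds >= 2 and nRepeats >= 1")
  if (object@nrounds < 1L || object@earlyStoppingRounds < 1L)
    return("boosting schedule must be positive")
  TRUE
})

#' Create a COXEN run configuration
#'
#' @param n1,n2 pool size and final selection size, N1 > N2 > 1
#' @param ppm prediction power measure (only \code{"abs_pearson"})
#' @param generalization \code{"ccc"} or \code{"pearson"}
#' @param nFolds,nRepeats cross-validation layout
#' @param seed integer seed
#' @param nrounds,earlyStoppingRounds boosting schedule defaults (1500 steps,
#'   stop if validation loss fails to improve for 150 steps)
#' @return a \linkS4class{CoxenConfig}
#' @export
coxenConfig <- function(n1, n2, ppm = "abs_pearson", generalization = "ccc",
                        nFolds = 10L, nRepeats = 10L, seed = 1L,
                        nrounds = 1500L, earlyStoppingRounds = 150L) {
  new("CoxenConfig", n1 = as.integer(n1), n2 = as.integer(n2),
      ppm = ppm, generalization = generalization,
      nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
      seed = as.integer(seed), nrounds = as.integer(nrounds),
      earlyStoppingRounds = as.integer(earlyStoppingRounds))
}

## ---- selection results ------------------------------------------------

#' GeneRanking: genes ordered by prediction power for one drug
#'
#' @slot drugId the drug
#' @slot geneIds all genes, ordered by descending prediction power
#'   (ties keep input order)
#' @slot ppmScores aligned prediction-power scores in [0, 1]
#' @export
setClass("GeneRanking", representation(
  drugId = "character", geneIds = "character", ppmScores = "numeric"))

setValidity("GeneRanking", function(object) {
  if (length(object@geneIds) != length(object@ppmScores))
    return("geneIds and ppmScores must align")
  if (is.unsorted(rev(object@ppmScores))) return("scores must be non-increasing")
  TRUE
})

#' CandidatePool: the L-gene predictive candidate pool
#'
#' @slot geneIds pool genes in deterministic first-appearance order
#' @slot lFinal per-drug depth reached by the union loop (enhanced path) or
#'   N1 (original path)
#' @slot poolSize L = number of pool genes
#' @slot method \code{"enhanced"} or \code{"original"}
#' @export
setClass("CandidatePool", representation(
  geneIds = "character", lFinal = "integer", poolSize = "integer",
  method = "character"))

setValidity("CandidatePool", function(object) {
  if (anyDuplicated(object@geneIds)) return("pool genes must be unique")
  if (object@poolSize != length(object@geneIds))
    return("poolSize must equal the number of pool genes")
  TRUE
})

#' GeneralizationScores: per-pool-gene co-expression preservation scores
#'
#' @slot geneIds pool genes
#' @slot scores agreement of the gene's co-expression vectors between the two
#'   datasets, in [-1, 1]
#' @slot method \code{"ccc"} or \code{"pearson"}
#' @export
setClass("GeneralizationScores", representation(
  geneIds = "character", scores = "numeric", method = "character"))

setValidity("GeneralizationScores", function(object) {
  if (length(object@geneIds) != length(object@scores))
    return("one score per pool gene required")
  TRUE
})

#' SelectionResult: the final N2 selected genes
#'
#' @slot selectedGenes N2 genes ordered by descending generalization score
#' @slot pool the \linkS4class{CandidatePool} they were drawn from
#' @slot scores the \linkS4class{GeneralizationScores} over the pool
#' @slot config the \linkS4class{CoxenConfig} used
#' @export
setClass("SelectionResult", representation(
  selectedGenes = "character", pool = "CandidatePool",
  scores = "GeneralizationScores", config = "CoxenConfig"))

setValidity("SelectionResult", function(object) {
  if (!all(object@selectedGenes %in% object@pool@geneIds))
    return("selected genes must come from the candidate pool")
  TRUE
})

## ---- dose response ----------------------------------------------------

#' SigmoidFit: three-parameter Hill dose-response fit
#'
#' Growth(dose) = eInf + (1 - eInf) / (1 + 10^(hill * (log10(dose) -
#' log10EC50))), the standard three-parameter Hill (sigmoid) model with the
#' upper asymptote fixed at 1 (untreated control growth).
#'
#' @slot eInf lower asymptote (growth fraction at saturating dose)
#' @slot log10EC50 log10 of the half-effect concentration (molar)
#' @slot hill positive slope parameter
#' @slot rss residual sum of squares of the fit
#' @slot converged FALSE when the flat-curve fallback was used
#' @export
setClass("SigmoidFit", representation(
  eInf = "numeric", log10EC50 = "numeric", hill = "numeric",
  rss = "numeric", converged = "logical"))

setValidity("SigmoidFit", function(object) {
  if (object@hill <= 0) return("hill slope must be positive")
  if (object@rss < 0) return("rss must be nonnegative")
  TRUE
})

## ---- evaluation -------------------------------------------------------

#' VariationDecomposition: between/within-class sum-of-squares split
#'
#' Total variation of a response vector decomposed over a class labeling:
#' St = Sb + Sw, where Sb sums Nk * (class mean - grand mean)^2 over the K
#' classes and Sw sums squared deviations from class means.
#'
#' @slot sTotal,sBetween,sWithin the three components (St = Sb + Sw)
#' @slot kClasses number of classes K
#' @slot classSizes experiments per class, Nk
#' @export
setClass("VariationDecomposition", representation(
  sTotal = "numeric", sBetween = "numeric", sWithin = "numeric",
  kClasses = "integer", classSizes = "integer"))

#' CVPlan: repeated cell-line-disjoint cross-validation layout
#'
#' Within each repeat the cell lines (not experiments) are partitioned into
#' folds, so no fold shares a cell line with another; every experiment of a
#' cell line travels with its fold. Each fold serves as the test fold exactly
#' once per repeat; the validation fold rotates one step behind it.
#'
#' @slot nFolds,nRepeats layout
#' @slot folds list (one per repeat) of named integer vectors mapping cell
#'   line id to fold index
#' @slot trials data.frame with columns trial, rep, testFold, valFold
#' @export
setClass("CVPlan", representation(
  nFolds = "integer", nRepeats = "integer", folds = "list",
  trials = "data.frame"))

#' BenchmarkReport: cross-validated comparison of gene selectors
#'
#' @slot trialR2 data.frame (trial, selector, r2), NA for failed trials
#' @slot summary data.frame (selector, meanR2, sdR2) over completed trials
#' @slot pip named vector: performance improvement percentage of the enhanced
#'   arm over each baseline arm, on the basis of the descriptors-only arm
#' @slot adjustedP named vector of BH-adjusted paired t-test p-values,
#'   enhanced vs each baseline
#' @slot variation list of \linkS4class{VariationDecomposition} for the input
#'   responses with drugs and with cell lines as classes
#' @export
setClass("BenchmarkReport", representation(
  trialR2 = "data.frame", summary = "data.frame", pip = "numeric",
  adjustedP = "numeric", variation = "list"))

## ---- synthetic data ---------------------------------------------------

#' SyntheticConfig: parameters of the two-dataset synthetic benchmark
#'
#' The generator plants a latent-factor co-expression module structure shared
#' (for a controllable fraction of modules) between two expression datasets,
#' plants predictive genes per drug, and drives AUC responses from those genes
#' plus noise, with drug mean effects dominating the response variation as in
#' real multi-drug cell-line screens.
#'
#' @slot nGenes,nCcls1,nCcls2,nDrugs problem dimensions
#' @slot nPredictivePerDrug planted predictive genes per drug
#' @slot overlapFraction fraction of each drug's planted set shared by all
#'   drugs
#' @slot nModules number of latent-factor co-expression blocks
#' @slot preservedFraction fraction of modules whose loading structure is kept
#'   in dataset 2 (the rest become independent genes there)
#' @slot effectSize response signal scale (AUC units per unit of the planted
#'   genes' weighted mean expression)
#' @slot drugEffectSd spread of per-drug mean AUC around 0.5
#' @slot noiseSd residual AUC noise
#' @slot nDescriptors descriptor columns (drug-identity column plus noise)
#' @slot seed master seed; stage-specific substreams derive from it
#' @export
setClass("SyntheticConfig", representation(
  nGenes = "integer", nCcls1 = "integer", nCcls2 = "integer",
  nDrugs = "integer", nPredictivePerDrug = "integer",
  overlapFraction = "numeric", nModules = "integer",
  preservedFraction = "numeric", effectSize = "numeric",
  drugEffectSd = "numeric", noiseSd = "numeric", nDescriptors = "integer",
  seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (any(c(object@nGenes, object@nCcls1, object@nCcls2, object@nDrugs,
            object@nPredictivePerDrug, object@nModules,
            object@nDescriptors) < 1L))
    return("all counts must be positive")
  if (object@nPredictivePerDrug > object@nGenes)
    return("cannot plant more predictive genes than genes")
  if (object@overlapFraction < 0 || object@overlapFraction > 1 ||
      object@preservedFraction < 0 || object@preservedFraction > 1)
    return("fractions must lie in [0, 1]")
  if (object@effectSize <= 0 || object@noiseSd <= 0 || object@drugEffectSd < 0)
    return("effectSize and noiseSd must be positive, drugEffectSd nonnegative")
  npd <- object@nPredictivePerDrug
  nShared <- round(object@overlapFraction * npd)
  need <- nShared + object@nDrugs * (npd - nShared)
  if (need > object@nGenes)
    return("not enough genes for the requested planted sets")
  TRUE
})

#' SyntheticDataset: a generated two-dataset benchmark
#'
#' @slot expr1,expr2 the two \linkS4class{ExpressionMatrix} datasets (samples
#'   differ; genes shared)
#' @slot responses \linkS4class{ResponseTable} over dataset-1 cell lines
#' @slot descriptors \linkS4class{DescriptorMatrix} over the drugs
#' @slot truth named list: per drug, the planted predictive gene ids
#' @slot preservedGenes genes whose co-expression structure is preserved in
#'   dataset 2
#' @slot config the \linkS4class{SyntheticConfig} echo
#' @export
setClass("SyntheticDataset", representation(
  expr1 = "ExpressionMatrix", expr2 = "ExpressionMatrix",
  responses = "ResponseTable", descriptors = "DescriptorMatrix",
  truth = "list", preservedGenes = "character", config = "SyntheticConfig"))
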