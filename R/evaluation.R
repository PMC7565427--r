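# Evaluation machinery: R^2, between/within-class variance decomposition of
# drug response, PIP, cell-line-disjoint repeated cross-validation, and
# BH-corrected paired tests.

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot. May be negative for predictions worse than the
#' mean; never exceeds 1.
#'
#' @param observed,predicted aligned numeric vectors, length >= 2
#' @return R^2
#' @export
rSquared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must align")
  if (length(observed) < 2L) stop("need >= 2 observations")
  ssTot <- sum((observed - mean(observed))^2)
  if (ssTot == 0) stop("observed values are constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / ssTot
}

#' Between/within-class variance decomposition of drug responses
#'
#' Splits the total sum of squares of the response values around the grand
#' mean into a between-class part (class sizes times squared deviations of
#' class means from the grand mean) and a within-class part (squared
#' deviations from class means), with classes given by the labels — drugs or
#' cell lines in a multi-drug screen. The parts add up exactly:
#' St = Sb + Sw.
#'
#' @param responses numeric response values, one per experiment
#' @param labels class label per response (drug id or cell-line id)
#' @return a \linkS4class{VariationDecomposition}
#' @export
variationDecomposition <- function(responses, labels) {
  if (length(responses) == 0L) stop("no responses")
  if (length(responses) != length(labels))
    stop("responses and labels must align")
  labels <- as.character(labels)
  grand <- mean(responses)
  classMeans <- tapply(responses, labels, mean)
  classSizes <- as.integer(table(labels)[names(classMeans)])
  sTotal <- sum((responses - grand)^2)
  sBetween <- sum(classSizes * (classMeans - grand)^2)
  sWithin <- sum((responses - classMeans[labels])^2)
  new("VariationDecomposition", sTotal = sTotal, sBetween = sBetween,
      sWithin = sWithin, kClasses = length(classMeans),
      classSizes = classSizes)
}

#' Ratio of between-class variations under two labelings
#'
#' Sb(labelsA) / Sb(labelsB); with drugs as labelsA and cell lines as
#' labelsB this quantifies how strongly the drug difference dominates the
#' response variation.
#'
#' @param responses numeric response values
#' @param labelsA,labelsB two labelings covering all responses
#' @return the ratio
#' @export
betweenClassRatio <- function(responses, labelsA, labelsB) {
  sbA <- variationDecomposition(responses, labelsA)@sBetween
  sbB <- variationDecomposition(responses, labelsB)@sBetween
  if (sbB == 0) stop("between-class variation of the second labeling is 0")
  sbA / sbB
}

#' Performance improvement percentage (PIP)
#'
#' (mean R^2 of the enhanced selector - mean R^2 of a baseline selector) /
#' (mean R^2 of the baseline - mean R^2 of a descriptors-only model) x 100.
#' Measures the improvement of the enhanced selector relative to the
#' baseline's own "pure" gene-expression contribution on top of drug
#' descriptors.
#'
#' @param meanR2Enhanced,meanR2Baseline,meanR2Descriptors trial-mean R^2 of
#'   the enhanced arm, the baseline arm, and the descriptors-only arm
#' @return PIP in percent
#' @export
performanceImprovement <- function(meanR2Enhanced, meanR2Baseline,
                                   meanR2Descriptors) {
  den <- meanR2Baseline - meanR2Descriptors
  if (den == 0)
    stop("baseline adds nothing over descriptors; PIP undefined")
  (meanR2Enhanced - meanR2Baseline) / den * 100
}

#' Build a cell-line-disjoint repeated cross-validation plan
#'
#' For each repeat, the cell lines are shuffled with a repeat-derived seed
#' (seed + repeat index) and dealt into \code{nFolds} folds of near-equal
#' size, so folds never share a cell line. Every trial is one (repeat, test
#' fold) pair; the validation fold is the next fold cyclically, the
#' remaining folds train.
#'
#' @param cclIds cell-line identifiers
#' @param nFolds,nRepeats layout (default 10 x 10 = 100 trials)
#' @param seed integer seed
#' @return a \linkS4class{CVPlan}
#' @export
makeCVPlan <- function(cclIds, nFolds = 10L, nRepeats = 10L, seed = 1L) {
  cclIds <- as.character(cclIds)
  if (anyDuplicated(cclIds)) stop("cell-line ids must be unique")
  nFolds <- as.integer(nFolds); nRepeats <- as.integer(nRepeats)
  if (length(cclIds) < nFolds) stop("fewer cell lines than folds")
  folds <- lapply(seq_len(nRepeats), function(r) {
    set.seed(as.integer(seed) + r)
    shuffled <- sample(cclIds)
    stats::setNames(rep_len(seq_len(nFolds), length(shuffled))[
      match(cclIds, shuffled)], cclIds)
  })
  trials <- expand.grid(testFold = seq_len(nFolds), rep = seq_len(nRepeats))
  trials <- data.frame(trial = seq_len(nrow(trials)), rep = trials$rep,
                       testFold = trials$testFold,
                       valFold = trials$testFold %% nFolds + 1L)
  new("CVPlan", nFolds = nFolds, nRepeats = nRepeats, folds = folds,
      trials = trials)
}

#' Paired t-tests with Benjamini-Hochberg correction
#'
#' Two-sided paired t-tests for each requested column pair of a trials x
#' methods R^2 matrix, BH step-up adjusted across the supplied comparison
#' family. Zero-variance differences give p = 1 with a warning.
#'
#' @param r2ByTrial numeric matrix, trials in rows, methods in named columns
#' @param comparisons list of length-2 character vectors of column names
#' @return named numeric vector of BH-adjusted p-values
#' @export
pairedTTestsBH <- function(r2ByTrial, comparisons) {
  r2ByTrial <- as.matrix(r2ByTrial)
  if (nrow(r2ByTrial) < 2L) stop("need >= 2 trials")
  raw <- vapply(comparisons, function(cmp) {
    d <- r2ByTrial[, cmp[1L]] - r2ByTrial[, cmp[2L]]
    d <- d[is.finite(d)]
    if (length(d) < 2L) stop("need >= 2 complete trials for ", cmp[1L],
                             " vs ", cmp[2L])
    if (stats::sd(d) == 0) {
      warning(sprintf("zero-variance differences for %s vs %s; p set to 1",
                      cmp[1L], cmp[2L]))
      return(1)
    }
    stats::t.test(d)$p.value
  }, numeric(1L))
  names(raw) <- vapply(comparisons, paste, character(1L), collapse = "_vs_")
  stats::p.adjust(raw, method = "BH")
}
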