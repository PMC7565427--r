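# Cross-validated comparison of gene selectors. Per trial, the training
# folds play the role of dataset 1 (expression + responses) and the
# validation + test folds combined play dataset 2 (expression only), so the
# COXEN selectors extrapolate toward exactly the cell lines they will be
# judged on. Selected gene expressions are concatenated with the drug
# descriptors as regressor input.

.knownSelectors <- c("enhanced", "original", "random-all", "random-list",
                     "fixed-list")

.featureMatrix <- function(rec, expr, desc, genes) {
  g <- if (length(genes)) t(expr@.Data[genes, rec$sample, drop = FALSE])
       else matrix(0, nrow(rec), 0L)
  cbind(g, desc@.Data[rec$drug, , drop = FALSE])
}

.armGenes <- function(selector, expr1, respTrain, expr2, config, geneList,
                      armSeed) {
  switch(selector,
    "enhanced" = selectedGenes(enhancedCoxen(expr1, respTrain, expr2, config)),
    "original" = selectedGenes(originalCoxen(expr1, respTrain, expr2, config)),
    "random-all" = {
      set.seed(armSeed)
      sample(geneIds(expr1), config@n2)
    },
    "random-list" = {
      if (is.null(geneList)) stop("random-list arm needs a gene list")
      set.seed(armSeed)
      sample(intersect(geneList, geneIds(expr1)), config@n2)
    },
    "fixed-list" = {
      if (is.null(geneList)) stop("fixed-list arm needs a gene list")
      intersect(geneList, geneIds(expr1))
    },
    stop("unknown selector: ", selector))
}

#' Benchmark gene selectors by cell-line-disjoint cross-validation
#'
#' Runs every trial of the plan: gene selection on the training folds
#' (dataset 1) against the combined validation and test folds (dataset 2),
#' regressor training on concatenated selected-gene expressions and drug
#' descriptors with early stopping on the validation fold, and R^2 scoring
#' on the test experiments. A descriptors-only arm is always included as the
#' reference for PIP. Random-gene arms redraw their genes each trial with a
#' trial-derived seed. A trial in which any arm fails is excluded with a
#' warning; more than 10 percent failed trials is an error.
#'
#' The report carries per-trial R^2 values, per-selector means and standard
#' deviations, the PIP of the enhanced arm over each baseline arm, BH-adjusted
#' paired t-tests of the enhanced arm against each baseline, and the variance
#' decomposition of the input responses with drugs and with cell lines as
#' classes.
#'
#' @param expr \linkS4class{ExpressionMatrix} over all cell lines in the plan
#' @param responses \linkS4class{ResponseTable}; samples must appear in the
#'   plan and the expression data
#' @param descriptors complete \linkS4class{DescriptorMatrix} covering the
#'   response table's drugs
#' @param selectors subset of \code{c("enhanced", "original", "random-all",
#'   "random-list", "fixed-list")}
#' @param regressor a regressor list, e.g. \code{\link{xgboostRegressor}()}
#' @param plan a \linkS4class{CVPlan} over the cell lines
#' @param config a \linkS4class{CoxenConfig}
#' @param geneList optional gene universe for the list-based arms
#' @return a \linkS4class{BenchmarkReport}
#' @export
runBenchmark <- function(expr, responses, descriptors, selectors, regressor,
                         plan, config, geneList = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"), is(responses, "ResponseTable"),
            is(descriptors, "DescriptorMatrix"), is(plan, "CVPlan"),
            is(config, "CoxenConfig"))
  bad <- setdiff(selectors, .knownSelectors)
  if (length(bad)) stop("unknown selectors: ", paste(bad, collapse = ", "))
  if (anyNA(descriptors@.Data))
    stop("descriptors contain missing values; run filterDescriptorsComplete")
  rec <- responses@records
  ccls <- names(plan@folds[[1L]])
  if (length(setdiff(rec$sample, ccls)))
    stop("response samples missing from the CV plan")
  if (length(setdiff(rec$sample, sampleIds(expr))))
    stop("response samples missing from the expression data")
  if (length(setdiff(rec$drug, drugIds(descriptors))))
    stop("response drugs missing from the descriptors")

  arms <- c(selectors, "descriptors-only")
  trials <- plan@trials
  r2 <- matrix(NA_real_, nrow(trials), length(arms),
               dimnames = list(NULL, arms))
  failed <- 0L
  for (t in seq_len(nrow(trials))) {
    fold <- plan@folds[[trials$rep[t]]]
    testCcls <- names(fold)[fold == trials$testFold[t]]
    valCcls <- names(fold)[fold == trials$valFold[t]]
    trainCcls <- setdiff(ccls, c(testCcls, valCcls))
    recTrain <- rec[rec$sample %in% trainCcls, , drop = FALSE]
    recVal <- rec[rec$sample %in% valCcls, , drop = FALSE]
    recTest <- rec[rec$sample %in% testCcls, , drop = FALSE]
    trialSeed <- config@seed + 7919L * t
    row <- tryCatch({
      if (nrow(recTrain) < 2L || nrow(recVal) < 1L || nrow(recTest) < 2L)
        stop("trial folds too small")
      expr1 <- ExpressionMatrix(expr@.Data[, trainCcls, drop = FALSE])
      expr2 <- ExpressionMatrix(
        expr@.Data[, c(valCcls, testCcls), drop = FALSE])
      respTrain <- ResponseTable(recTrain)
      out <- numeric(length(arms))
      names(out) <- arms
      for (a in seq_along(arms)) {
        genes <- if (arms[a] == "descriptors-only") character(0)
                 else .armGenes(arms[a], expr1, respTrain, expr2, config,
                                geneList, trialSeed + a)
        model <- regressor$fit(
          .featureMatrix(recTrain, expr, descriptors, genes), recTrain$auc,
          .featureMatrix(recVal, expr, descriptors, genes), recVal$auc)
        pred <- regressor$predict(
          model, .featureMatrix(recTest, expr, descriptors, genes))
        out[a] <- rSquared(recTest$auc, pred)
      }
      out
    }, error = function(e) {
      warning(sprintf("trial %d failed and was excluded: %s", t,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(row)) failed <- failed + 1L else r2[t, ] <- row
  }
  if (failed > 0.1 * nrow(trials))
    stop(failed, " of ", nrow(trials), " trials failed (> 10%)")

  trialR2 <- data.frame(
    trial = rep(trials$trial, length(arms)),
    selector = rep(arms, each = nrow(trials)),
    r2 = as.vector(r2))
  summary <- data.frame(
    selector = arms,
    meanR2 = apply(r2, 2L, mean, na.rm = TRUE),
    sdR2 = apply(r2, 2L, stats::sd, na.rm = TRUE),
    row.names = NULL)

  baselines <- setdiff(selectors, "enhanced")
  pip <- numeric(0)
  adjP <- numeric(0)
  if ("enhanced" %in% selectors && length(baselines)) {
    means <- colMeans(r2, na.rm = TRUE)
    pip <- vapply(baselines, function(b)
      performanceImprovement(means[["enhanced"]], means[[b]],
                             means[["descriptors-only"]]), numeric(1L))
    names(pip) <- baselines
    adjP <- pairedTTestsBH(r2[stats::complete.cases(r2), , drop = FALSE],
                           lapply(baselines, function(b) c("enhanced", b)))
  }
  variation <- list(
    drug = variationDecomposition(rec$auc, rec$drug),
    ccl = variationDecomposition(rec$auc, rec$sample))
  new("BenchmarkReport", trialR2 = trialR2, summary = summary, pip = pip,
      adjustedP = adjP, variation = variation)
}

#' Write a BenchmarkReport to a directory
#'
#' Writes \code{trial_r2.csv} (trial, selector, r2), \code{summary.csv}
#' (per-selector mean/sd plus PIP and adjusted p against each baseline) and
#' \code{variation.csv} (St, Sb, Sw per labeling).
#'
#' @param report a \linkS4class{BenchmarkReport}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeBenchmarkReport <- function(report, dir) {
  stopifnot(is(report, "BenchmarkReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@trialR2, file.path(dir, "trial_r2.csv"),
                   row.names = FALSE)
  s <- report@summary
  for (b in names(report@pip)) {
    s[[paste0("pip_vs_", b)]] <-
      ifelse(s$selector == "enhanced", report@pip[[b]], NA_real_)
    s[[paste0("adj_p_vs_", b)]] <-
      ifelse(s$selector == "enhanced",
             report@adjustedP[[paste0("enhanced_vs_", b)]], NA_real_)
  }
  utils::write.csv(s, file.path(dir, "summary.csv"), row.names = FALSE)
  v <- do.call(rbind, lapply(names(report@variation), function(nm) {
    d <- report@variation[[nm]]
    data.frame(classes = nm, sTotal = d@sTotal, sBetween = d@sBetween,
               sWithin = d@sWithin, k = d@kClasses)
  }))
  utils::write.csv(v, file.path(dir, "variation.csv"), row.names = FALSE)
  invisible(dir)
}
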