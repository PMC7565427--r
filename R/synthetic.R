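# Synthetic two-dataset benchmark generator. Co-expression is induced by
# latent-factor modules (one standard-normal factor per module, gene loadings
# uniform on [0.5, 1], idiosyncratic noise scaled so genes are unit
# variance). Dataset 2 keeps the loading structure of "preserved" modules
# (new factor values, same co-expression pattern) and regenerates the other
# modules' genes independently, destroying their co-expression. Per drug,
# AUC(c, d) = clip01(mu_d + effectSize * weighted mean of planted-gene
# expressions + Gaussian noise), so drug mean effects dominate the response
# variation as in real multi-drug screens.

#' Build a synthetic benchmark configuration
#'
#' Defaults describe a desk-scale two-dataset screen: 500 genes in 25
#' co-expression modules of 20, 200 + 100 cell lines, 5 drugs with 20
#' planted predictive genes each (a quarter shared by all drugs), 60 percent
#' of modules preserved in dataset 2, response signal scale 0.25 against
#' residual noise 0.05, and a per-drug mean AUC spread of 0.15 calibrated so
#' the drug difference dominates the response variation at ratios comparable
#' to real cell-line screens (roughly 5-9).
#'
#' @param nGenes,nCcls1,nCcls2,nDrugs problem dimensions
#' @param nPredictivePerDrug planted predictive genes per drug
#' @param overlapFraction fraction of each planted set shared across drugs
#' @param nModules co-expression modules
#' @param preservedFraction fraction of modules preserved in dataset 2
#' @param effectSize response signal scale
#' @param drugEffectSd spread of per-drug mean AUC around 0.5
#' @param noiseSd residual AUC noise
#' @param nDescriptors descriptor columns (drug-mean column plus noise)
#' @param seed master seed
#' @return a \linkS4class{SyntheticConfig}
#' @export
syntheticConfig <- function(nGenes = 500L, nCcls1 = 200L, nCcls2 = 100L,
                            nDrugs = 5L, nPredictivePerDrug = 20L,
                            overlapFraction = 0.25, nModules = 25L,
                            preservedFraction = 0.6, effectSize = 0.25,
                            drugEffectSd = 0.15, noiseSd = 0.05,
                            nDescriptors = 20L, seed = 42L) {
  new("SyntheticConfig", nGenes = as.integer(nGenes),
      nCcls1 = as.integer(nCcls1), nCcls2 = as.integer(nCcls2),
      nDrugs = as.integer(nDrugs),
      nPredictivePerDrug = as.integer(nPredictivePerDrug),
      overlapFraction = overlapFraction, nModules = as.integer(nModules),
      preservedFraction = preservedFraction, effectSize = effectSize,
      drugEffectSd = drugEffectSd, noiseSd = noiseSd,
      nDescriptors = as.integer(nDescriptors), seed = as.integer(seed))
}

#' Generate a synthetic two-dataset benchmark
#'
#' All randomness derives from \code{config@seed} through stage-specific
#' substreams (structure, expression 1, expression 2, responses,
#' descriptors), so the same seed reproduces the dataset bit for bit and
#' stages are independently reproducible.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @return a \linkS4class{SyntheticDataset}
#' @export
generateSyntheticDataset <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg@nGenes))
  ccls1 <- sprintf("CCL1_%03d", seq_len(cfg@nCcls1))
  ccls2 <- sprintf("CCL2_%03d", seq_len(cfg@nCcls2))
  drugs <- sprintf("D%02d", seq_len(cfg@nDrugs))

  ## structure: modules, loadings, preserved set, planted genes, weights
  set.seed(cfg@seed + 1L)
  module <- rep_len(seq_len(cfg@nModules), cfg@nGenes)
  loadings <- stats::runif(cfg@nGenes, 0.5, 1)
  nPreserved <- round(cfg@preservedFraction * cfg@nModules)
  preservedModules <- sort(sample(cfg@nModules, nPreserved))
  npd <- cfg@nPredictivePerDrug
  nShared <- round(cfg@overlapFraction * npd)
  sharedGenes <- sample(cfg@nGenes, nShared)
  rest <- setdiff(seq_len(cfg@nGenes), sharedGenes)
  truth <- vector("list", cfg@nDrugs)
  names(truth) <- drugs
  weights <- vector("list", cfg@nDrugs)
  for (d in seq_len(cfg@nDrugs)) {
    specific <- sample(rest, npd - nShared)
    rest <- setdiff(rest, specific)
    truth[[d]] <- sort(c(sharedGenes, specific))
    weights[[d]] <- stats::runif(npd, 0.5, 1)
  }

  factorBlock <- function(nCcl) matrix(stats::rnorm(cfg@nModules * nCcl),
                                       cfg@nModules, nCcl)
  exprFrom <- function(f, nCcl, indep) {
    x <- loadings * f[module, , drop = FALSE] +
      sqrt(1 - loadings^2) * matrix(stats::rnorm(cfg@nGenes * nCcl),
                                    cfg@nGenes, nCcl)
    if (length(indep))
      x[indep, ] <- stats::rnorm(length(indep) * nCcl)
    x
  }

  ## dataset 1: all modules structured
  set.seed(cfg@seed + 2L)
  x1 <- exprFrom(factorBlock(cfg@nCcls1), cfg@nCcls1, integer(0))
  dimnames(x1) <- list(genes, ccls1)

  ## dataset 2: new factors; non-preserved modules become independent genes
  set.seed(cfg@seed + 3L)
  indep <- which(!(module %in% preservedModules))
  x2 <- exprFrom(factorBlock(cfg@nCcls2), cfg@nCcls2, indep)
  dimnames(x2) <- list(genes, ccls2)

  ## responses on dataset-1 cell lines, all (ccl, drug) pairs
  set.seed(cfg@seed + 4L)
  drugMeans <- stats::rnorm(cfg@nDrugs, 0.5, cfg@drugEffectSd)
  rec <- do.call(rbind, lapply(seq_len(cfg@nDrugs), function(d) {
    w <- weights[[d]]
    signal <- cfg@effectSize *
      colSums(w * x1[truth[[d]], , drop = FALSE]) / sum(w)
    auc <- drugMeans[d] + signal + stats::rnorm(cfg@nCcls1, 0, cfg@noiseSd)
    data.frame(sample = ccls1, drug = drugs[d],
               auc = pmin(1, pmax(0, auc)), stringsAsFactors = FALSE)
  }))

  ## descriptors: drug-mean column (drug identity recoverable) plus noise
  set.seed(cfg@seed + 5L)
  desc <- cbind(drugMeans,
                matrix(stats::rnorm(cfg@nDrugs * (cfg@nDescriptors - 1L)),
                       cfg@nDrugs, cfg@nDescriptors - 1L))
  dimnames(desc) <- list(drugs, c("mu", sprintf("noise%03d",
                                                seq_len(cfg@nDescriptors - 1L))))

  new("SyntheticDataset",
      expr1 = ExpressionMatrix(x1), expr2 = ExpressionMatrix(x2),
      responses = ResponseTable(rec), descriptors = DescriptorMatrix(desc),
      truth = lapply(truth, function(ix) genes[ix]),
      preservedGenes = genes[module %in% preservedModules],
      config = cfg)
}

#' Drug-dominance ratio of a synthetic dataset
#'
#' Ratio of the between-class response variation with drugs as classes to
#' that with cell lines as classes; used to check that a generated benchmark
#' sits in the drug-dominated regime of real multi-drug screens.
#'
#' @param ds a \linkS4class{SyntheticDataset}
#' @return the ratio
#' @export
drugDominanceCheck <- function(ds) {
  stopifnot(is(ds, "SyntheticDataset"))
  rec <- ds@responses@records
  if (length(unique(rec$drug)) < 2L)
    stop("drug dominance is undefined for a single drug")
  betweenClassRatio(rec$auc, rec$drug, rec$sample)
}

#' Write a synthetic dataset to a directory
#'
#' Writes expr1.csv, expr2.csv, response.csv, descriptors.csv and truth.json
#' (planted genes, preserved genes, config echo).
#'
#' @param ds a \linkS4class{SyntheticDataset}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeSyntheticDataset <- function(ds, dir) {
  stopifnot(is(ds, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(ds@expr1, file.path(dir, "expr1.csv"))
  writeExpression(ds@expr2, file.path(dir, "expr2.csv"))
  writeResponseTable(ds@responses, file.path(dir, "response.csv"))
  writeDescriptors(ds@descriptors, file.path(dir, "descriptors.csv"))
  cfg <- ds@config
  cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(cfgList) <- slotNames(cfg)
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing truth.json requires the jsonlite package")
  jsonlite::write_json(
    list(truth = ds@truth, preserved_genes = ds@preservedGenes,
         config = cfgList),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
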