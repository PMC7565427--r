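# Core COXEN machinery: per-drug predictive-gene ranking, candidate-pool
# construction (multi-drug union and single-pool variants), co-expression
# preservation scoring, and the two end-to-end selectors.

.isConstant <- function(x) max(x) == min(x)

# stable descending order: ties keep first-appearance order
.orderDesc <- function(scores) order(-scores, seq_along(scores))

#' Prediction power of one gene for one drug
#'
#' The absolute Pearson correlation between a gene's expression values and
#' the aligned drug-response (AUC) values. A constant vector on either side
#' yields a defined-degenerate score of 0.
#'
#' @param exprVector per-sample expression values
#' @param responseVector aligned AUC values
#' @return score in [0, 1]
#' @export
predictionPower <- function(exprVector, responseVector) {
  if (length(exprVector) != length(responseVector))
    stop("expression and response vectors must align")
  if (length(exprVector) < 2L) stop("need >= 2 paired observations")
  if (.isConstant(exprVector) || .isConstant(responseVector)) return(0)
  abs(stats::cor(exprVector, responseVector))
}

#' Rank all genes by prediction power for one drug
#'
#' Extracts the expression profiles of the cancer cases treated by the drug
#' and their response values, scores every gene by
#' \code{\link{predictionPower}}, and orders genes by descending score, ties
#' broken by input gene order.
#'
#' @param expr an \linkS4class{ExpressionMatrix}
#' @param responses a \linkS4class{ResponseTable}
#' @param drugId the drug to rank for
#' @return a \linkS4class{GeneRanking}
#' @export
rankGenesForDrug <- function(expr, responses, drugId) {
  stopifnot(is(expr, "ExpressionMatrix"), is(responses, "ResponseTable"))
  rec <- responses@records[responses@records$drug == drugId, , drop = FALSE]
  missing <- setdiff(rec$sample, sampleIds(expr))
  if (length(missing))
    stop(sprintf("drug '%s': samples not in expression data: %s", drugId,
                 paste(missing, collapse = ", ")))
  if (nrow(rec) < 2L)
    stop(sprintf("drug '%s' has fewer than 2 treated samples", drugId))
  scores <- .ppmAgainst(expr@.Data[, rec$sample, drop = FALSE], rec$auc)
  o <- .orderDesc(scores)
  new("GeneRanking", drugId = as.character(drugId),
      geneIds = rownames(expr)[o], ppmScores = unname(scores[o]))
}

# vectorized abs-Pearson of every row of m against y, constants scored 0
.ppmAgainst <- function(m, y) {
  if (.isConstant(y)) return(rep(0, nrow(m)))
  r <- suppressWarnings(as.vector(stats::cor(t(m), y)))
  r[!is.finite(r)] <- 0
  abs(r)
}

#' Multi-drug candidate pool: union of per-drug top predictive genes
#'
#' The per-drug depth l starts at ceiling(N1 / D). The union of the top-l
#' genes of all D drug rankings is taken; while its size L is smaller than
#' N1, l grows by one and the union is recomputed. The final pool has
#' L >= N1 genes, ordered by first appearance (drug-major, then rank).
#'
#' @param rankings list of \linkS4class{GeneRanking}, one per drug, over a
#'   shared gene universe
#' @param n1 pool size target N1 (<= number of genes)
#' @return a \linkS4class{CandidatePool}
#' @export
buildCandidatePoolEnhanced <- function(rankings, n1) {
  if (length(rankings) < 1L) stop("need at least one drug ranking")
  stopifnot(all(vapply(rankings, is, logical(1L), "GeneRanking")))
  p <- length(rankings[[1L]]@geneIds)
  if (any(vapply(rankings, function(r) length(r@geneIds), integer(1L)) != p))
    stop("rankings must share one gene universe")
  n1 <- as.integer(n1)
  if (n1 > p) stop("N1 exceeds the number of genes (", p, ")")
  if (n1 < 1L) stop("N1 must be >= 1")
  d <- length(rankings)
  l <- as.integer(ceiling(n1 / d))
  repeat {
    pool <- unique(unlist(lapply(rankings,
                                 function(r) r@geneIds[seq_len(l)])))
    if (length(pool) >= n1 || l >= p) break
    l <- l + 1L
  }
  new("CandidatePool", geneIds = pool, lFinal = l,
      poolSize = length(pool), method = "enhanced")
}

#' Single-pool candidate genes, ignoring the drug difference
#'
#' The original selector's Step 1 applied to a multi-drug table: one pooled
#' response vector is formed across all experiments (a sample's expression
#' row is repeated once for every experiment involving it), every gene is
#' scored by absolute Pearson correlation against it, and the top N1 genes
#' form the pool (ordered by descending score).
#'
#' @param expr an \linkS4class{ExpressionMatrix}
#' @param responses a \linkS4class{ResponseTable}
#' @param n1 pool size N1
#' @return a \linkS4class{CandidatePool}
#' @export
buildCandidatePoolOriginal <- function(expr, responses, n1) {
  stopifnot(is(expr, "ExpressionMatrix"), is(responses, "ResponseTable"))
  n1 <- as.integer(n1)
  if (n1 > nrow(expr)) stop("N1 exceeds the number of genes (", nrow(expr), ")")
  if (n1 < 1L) stop("N1 must be >= 1")
  rec <- responses@records
  missing <- setdiff(rec$sample, sampleIds(expr))
  if (length(missing))
    stop("samples not in expression data: ", paste(missing, collapse = ", "))
  scores <- .ppmAgainst(expr@.Data[, rec$sample, drop = FALSE], rec$auc)
  keep <- .orderDesc(scores)[seq_len(n1)]
  new("CandidatePool", geneIds = rownames(expr)[keep], lFinal = n1,
      poolSize = n1, method = "original")
}

#' Co-expression vector of one pool gene
#'
#' Pearson correlations of the gene's expression with every other pool gene,
#' in pool order; correlations involving a constant gene are the
#' defined-degenerate 0.
#'
#' @param gene a pool gene id
#' @param pool a \linkS4class{CandidatePool}
#' @param expr an \linkS4class{ExpressionMatrix} containing the pool genes
#' @return numeric vector of length poolSize - 1
#' @export
coexpressionVector <- function(gene, pool, expr) {
  stopifnot(is(pool, "CandidatePool"), is(expr, "ExpressionMatrix"))
  if (!gene %in% pool@geneIds) stop(sprintf("gene '%s' is not in the pool", gene))
  missing <- setdiff(pool@geneIds, geneIds(expr))
  if (length(missing))
    stop("pool genes missing from expression data: ",
         paste(missing, collapse = ", "))
  others <- setdiff(pool@geneIds, gene)
  r <- suppressWarnings(
    as.vector(stats::cor(expr@.Data[gene, ],
                         t(expr@.Data[others, , drop = FALSE]))))
  r[!is.finite(r)] <- 0
  stats::setNames(r, others)
}

#' Lin's concordance correlation coefficient
#'
#' CCC(c1, c2) = 2 cov(c1, c2) / (var(c1) + var(c2) + (mean(c1) -
#' mean(c2))^2), with population (divide-by-n) moments. It is 1 iff the
#' vectors are identical, -1 iff they reversely match, and shrinks the
#' Pearson correlation by the deviation of the point cloud from the identity
#' line. Degenerate cases are defined: both vectors constant and equal gives
#' 1, both constant and unequal gives 0, exactly one constant gives 0.
#'
#' @param c1,c2 numeric vectors of equal length >= 2
#' @return value in [-1, 1]
#' @export
concordanceCorrelation <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("vectors must have equal length")
  if (length(c1) < 2L) stop("need length >= 2")
  const1 <- .isConstant(c1)
  const2 <- .isConstant(c2)
  if (const1 && const2) return(if (c1[1L] == c2[1L]) 1 else 0)
  if (const1 || const2) return(0)
  if (identical(c1, c2)) return(1)   # exact agreement, no fp round-off
  m1 <- mean(c1); m2 <- mean(c2)
  v1 <- mean((c1 - m1)^2)
  v2 <- mean((c2 - m2)^2)
  cv <- mean((c1 - m1) * (c2 - m2))
  2 * cv / (v1 + v2 + (m1 - m2)^2)
}

# Pearson with the same degenerate conventions (constant -> 0)
.pearsonOrZero <- function(a, b) {
  if (.isConstant(a) || .isConstant(b)) return(0)
  if (identical(a, b)) return(1)     # exact agreement, no fp round-off
  stats::cor(a, b)
}

#' Co-expression preservation scores over a candidate pool
#'
#' For every pool gene, its co-expression vector (Pearson correlations with
#' the other pool genes) is computed in each of the two expression datasets;
#' the generalization score is the agreement of the two vectors, by Lin's
#' concordance correlation (\code{method = "ccc"}, the enhanced selector) or
#' plain Pearson correlation (\code{method = "pearson"}, the original
#' selector). Pools of fewer than 3 genes give length-<2 co-expression
#' vectors; their scores are the degenerate 0, with a warning.
#'
#' @param pool a \linkS4class{CandidatePool}
#' @param expr1,expr2 the two \linkS4class{ExpressionMatrix} datasets (genes
#'   shared, samples differing)
#' @param method \code{"ccc"} or \code{"pearson"}
#' @return a \linkS4class{GeneralizationScores}
#' @export
generalizationScores <- function(pool, expr1, expr2,
                                 method = c("ccc", "pearson")) {
  method <- match.arg(method)
  stopifnot(is(pool, "CandidatePool"))
  for (e in list(expr1, expr2)) {
    stopifnot(is(e, "ExpressionMatrix"))
    missing <- setdiff(pool@geneIds, geneIds(e))
    if (length(missing))
      stop(sprintf("pool gene missing from expression data: '%s'",
                   missing[1L]))
  }
  genes <- pool@geneIds
  np <- length(genes)
  if (np - 1L < 2L) {
    warning("co-expression vectors have length < 2; scores degenerate to 0")
    return(new("GeneralizationScores", geneIds = genes,
               scores = rep(0, np), method = method))
  }
  corMat <- function(e) {
    m <- suppressWarnings(stats::cor(t(e@.Data[genes, , drop = FALSE])))
    m[!is.finite(m)] <- 0
    m
  }
  m1 <- corMat(expr1)
  m2 <- corMat(expr2)
  agree <- if (method == "ccc") concordanceCorrelation else .pearsonOrZero
  scores <- vapply(seq_len(np),
                   function(i) agree(m1[i, -i], m2[i, -i]), numeric(1L))
  new("GeneralizationScores", geneIds = genes, scores = scores,
      method = method)
}

#' Select the N2 best-generalizing genes from a pool
#'
#' Takes the N2 pool genes with the highest generalization scores, ties
#' broken by pool order.
#'
#' @param pool a \linkS4class{CandidatePool}
#' @param scores a \linkS4class{GeneralizationScores} over the pool
#' @param config a \linkS4class{CoxenConfig} (supplies N2 and is echoed)
#' @return a \linkS4class{SelectionResult}
#' @export
selectGenes <- function(pool, scores, config) {
  stopifnot(is(pool, "CandidatePool"), is(scores, "GeneralizationScores"),
            is(config, "CoxenConfig"))
  if (!identical(pool@geneIds, scores@geneIds))
    stop("scores must cover exactly the pool genes, in pool order")
  n2 <- config@n2
  if (n2 > pool@poolSize) stop("N2 exceeds the pool size (", pool@poolSize, ")")
  keep <- .orderDesc(scores@scores)[seq_len(n2)]
  new("SelectionResult", selectedGenes = pool@geneIds[keep], pool = pool,
      scores = scores, config = config)
}

#' Enhanced COXEN gene selection (multi-drug)
#'
#' Ranks all genes by prediction power for each drug in the response table,
#' pools the union of per-drug top predictive genes until the pool reaches
#' N1 genes, scores each pool gene's co-expression preservation between the
#' two datasets with Lin's concordance correlation (by default), and keeps
#' the N2 best-preserved genes.
#'
#' @param expr1 dataset-1 \linkS4class{ExpressionMatrix} (responses known)
#' @param responses \linkS4class{ResponseTable} over dataset-1 samples
#' @param expr2 dataset-2 \linkS4class{ExpressionMatrix} (to be predicted)
#' @param config a \linkS4class{CoxenConfig}
#' @return a \linkS4class{SelectionResult}
#' @export
enhancedCoxen <- function(expr1, responses, expr2, config) {
  stopifnot(is(config, "CoxenConfig"))
  drugs <- drugIds(responses)
  rankings <- lapply(drugs, function(d) rankGenesForDrug(expr1, responses, d))
  pool <- buildCandidatePoolEnhanced(rankings, config@n1)
  scores <- generalizationScores(pool, expr1, expr2,
                                 method = config@generalization)
  selectGenes(pool, scores, config)
}

#' Original COXEN gene selection (single pool)
#'
#' The classic three-step selector applied ignoring the drug difference: one
#' pooled candidate set of the N1 genes most correlated with the pooled
#' response vector, co-expression preservation scored by Pearson correlation
#' (by default), and the N2 best-preserved genes kept.
#'
#' @inheritParams enhancedCoxen
#' @param generalization agreement statistic for Step 2; defaults to
#'   \code{"pearson"} as in the classic formulation
#' @return a \linkS4class{SelectionResult}
#' @export
originalCoxen <- function(expr1, responses, expr2, config,
                          generalization = "pearson") {
  stopifnot(is(config, "CoxenConfig"))
  pool <- buildCandidatePoolOriginal(expr1, responses, config@n1)
  scores <- generalizationScores(pool, expr1, expr2, method = generalization)
  selectGenes(pool, scores, config)
}
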