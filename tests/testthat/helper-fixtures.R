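# Fixtures are built in code; nothing is read from disk except the
# published-benchmark summary tables under inst/extdata.

makeExpr <- function(values, genes = sprintf("g%d", seq_len(nrow(values))),
                     samples = sprintf("s%d", seq_len(ncol(values)))) {
  m <- as.matrix(values)
  dimnames(m) <- list(genes, samples)
  ExpressionMatrix(m)
}

randomExpr <- function(nGenes, nSamples, seed = 1) {
  set.seed(seed)
  makeExpr(matrix(rnorm(nGenes * nSamples), nGenes, nSamples))
}

# a small, fast synthetic configuration for unit tests
smallSynthConfig <- function(seed = 7, ...) {
  args <- list(nGenes = 120L, nCcls1 = 60L, nCcls2 = 40L, nDrugs = 3L,
               nPredictivePerDrug = 8L, nModules = 12L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(syntheticConfig, args)
}

# independent oracle for Lin's concordance correlation: plain sums, no
# shared code with the implementation
oracleCCC <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  va <- sum((a - ma)^2) / n
  vb <- sum((b - mb)^2) / n
  cab <- sum((a - ma) * (b - mb)) / n
  2 * cab / (va + vb + (ma - mb)^2)
}

# independent Pearson correlation oracle
oraclePearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
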