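# Delimiter is taken from the file extension: .tsv/.txt -> tab, else comma.
# UTF-8, "." decimal separator, header row required.
.delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = .delim(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "\"", fileEncoding = "UTF-8")
}

.writeTable <- function(df, path) {
  utils::write.table(df, path, sep = .delim(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
}

#' Read a genes x samples expression matrix
#'
#' First column holds gene ids, remaining header names are sample ids, body is
#' numeric. Row and column order are preserved from the file.
#'
#' @param path CSV/TSV file
#' @return an \linkS4class{ExpressionMatrix}
#' @export
readExpression <- function(path) {
  df <- .readTable(path)
  if (ncol(df) < 3L) stop("expression file needs >= 2 sample columns")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id: '%s'", genes[duplicated(genes)][1L]))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                   genes[bad], names(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  ExpressionMatrix(m)
}

#' Write an ExpressionMatrix
#' @param x an \linkS4class{ExpressionMatrix}
#' @param path CSV/TSV output path
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x), x@.Data, check.names = FALSE)
  .writeTable(df, path)
  invisible(path)
}

#' Read a long-format drug response table
#'
#' Expects header \code{sample,drug,auc}; AUC values must lie in [0, 1] and
#' each (sample, drug) pair may appear only once.
#'
#' @param path CSV/TSV file
#' @return a \linkS4class{ResponseTable}
#' @export
readResponseTable <- function(path) {
  df <- .readTable(path)
  if (!all(c("sample", "drug", "auc") %in% names(df)))
    stop("response file needs columns sample, drug, auc")
  if (nrow(df) == 0L) stop("no records")
  ResponseTable(df[, c("sample", "drug", "auc")])
}

#' Write a ResponseTable
#' @param x a \linkS4class{ResponseTable}
#' @param path CSV/TSV output path
#' @export
writeResponseTable <- function(x, path) {
  stopifnot(is(x, "ResponseTable"))
  .writeTable(x@records, path)
  invisible(path)
}

#' Read a drugs x descriptors matrix
#'
#' First column holds drug ids; empty cells are missing values.
#'
#' @param path CSV/TSV file
#' @return a \linkS4class{DescriptorMatrix}
#' @export
readDescriptors <- function(path) {
  df <- .readTable(path)
  drugs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- drugs
  DescriptorMatrix(m)
}

#' Write a DescriptorMatrix
#' @param x a \linkS4class{DescriptorMatrix}
#' @param path CSV/TSV output path
#' @export
writeDescriptors <- function(x, path) {
  stopifnot(is(x, "DescriptorMatrix"))
  df <- data.frame(drug_id = rownames(x), x@.Data, check.names = FALSE)
  .writeTable(df, path)
  invisible(path)
}

#' Read a newline-delimited gene list
#' @param path plain-text file, one gene id per line
#' @return character vector of unique gene ids in file order
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("empty gene list")
  if (anyDuplicated(x))
    stop(sprintf("duplicate gene id in list: '%s'", x[duplicated(x)][1L]))
  x
}

#' Write a gene list
#' @param genes character vector of gene ids
#' @param path output path
#' @export
writeGeneList <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Check which response-table samples resolve in an expression matrix
#'
#' Sample-intersection policy is dataset-specific; this only reports which
#' response samples are absent from the expression data.
#'
#' @param responses a \linkS4class{ResponseTable}
#' @param expr an \linkS4class{ExpressionMatrix}
#' @return character vector of unmatched sample ids (empty when all resolve)
#' @export
unmatchedSamples <- function(responses, expr) {
  setdiff(sampleIds(responses), sampleIds(expr))
}

#' Read a run configuration from YAML
#'
#' Recognized fields mirror \code{\link{coxenConfig}} arguments (n1, n2, ppm,
#' generalization, nFolds, nRepeats, seed, nrounds, earlyStoppingRounds);
#' explicit arguments in \code{...} override file values.
#'
#' @param path YAML file
#' @param ... overrides passed on to \code{\link{coxenConfig}}
#' @return a \linkS4class{CoxenConfig}
#' @export
readCoxenConfig <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(coxenConfig))
  cfg <- cfg[intersect(names(cfg), allowed)]
  over <- list(...)
  cfg[names(over)] <- over
  do.call(coxenConfig, cfg)
}
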