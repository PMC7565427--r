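#' Drop the genes with the smallest average expression
#'
#' Keeps the \code{keepN} genes whose mean expression across samples is
#' largest, mirroring the preprocessing that discards the lowest-expressed
#' genes before gene selection. Original gene order is preserved among
#' survivors; ties at the cutoff are broken by input order (first listed
#' wins). Alternatively a quantile can be given: \code{keepFraction = 0.8}
#' keeps the top 80\% of genes by mean expression.
#'
#' @param expr an \linkS4class{ExpressionMatrix}
#' @param keepN number of genes to keep (1..P)
#' @param keepFraction alternative to \code{keepN}: fraction of genes to keep
#' @return the filtered \linkS4class{ExpressionMatrix}
#' @export
filterLowExpression <- function(expr, keepN = NULL, keepFraction = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"))
  p <- nrow(expr)
  if (is.null(keepN)) {
    if (is.null(keepFraction)) stop("give keepN or keepFraction")
    if (keepFraction <= 0 || keepFraction > 1)
      stop("keepFraction must lie in (0, 1]")
    keepN <- max(1L, as.integer(floor(keepFraction * p)))
  }
  keepN <- as.integer(keepN)
  if (keepN < 1L) stop("keepN must be >= 1")
  if (keepN > p) stop("keepN exceeds the number of genes (", p, ")")
  means <- rowMeans(expr@.Data)
  # stable: among equal means the earlier-listed gene wins the cutoff
  keep <- sort(order(-means, seq_len(p))[seq_len(keepN)])
  ExpressionMatrix(expr@.Data[keep, , drop = FALSE])
}

#' Keep only descriptors observed for every drug
#'
#' Removes every descriptor column containing at least one missing value,
#' preserving column order.
#'
#' @param desc a \linkS4class{DescriptorMatrix}
#' @return the filtered, complete \linkS4class{DescriptorMatrix}
#' @export
filterDescriptorsComplete <- function(desc) {
  stopifnot(is(desc, "DescriptorMatrix"))
  complete <- colSums(is.na(desc@.Data)) == 0L
  if (!any(complete)) stop("no complete descriptors")
  DescriptorMatrix(desc@.Data[, complete, drop = FALSE])
}
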