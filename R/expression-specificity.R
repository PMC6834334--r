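#' Normalize expression per gene by median and MAD
#'
#' Centers and standardizes each gene's expression across cell types:
#' \deqn{e_{g,c} = (E_{g,c} - M_g) / MAD_g}
#' where \eqn{M_g} is the median and \eqn{MAD_g} the raw median absolute
#' deviation (no consistency constant) of gene \eqn{g} across all cell
#' types.  This makes expression levels comparable between genes.  Genes
#' with \eqn{MAD_g = 0} (constant or near-constant profiles) carry no
#' specificity signal and are excluded; their symbols are recorded in
#' `metadata(result)$excluded`.
#'
#' @param expr SummarizedExperiment with assay `"exprs"` (see
#'   [readExpressionMatrix()]), or a numeric matrix with gene rownames
#'   and cell-type colnames.
#' @return a [NormalizedExpression-class].
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 100), g2 = c(5, 5, 5, 5, 5))
#' colnames(m) <- paste0("ct", 1:5)
#' norm <- normalizeExpression(m)
#' SummarizedExperiment::assay(norm, "e")["g1", ]  # -2 -1 0 1 97
#' S4Vectors::metadata(norm)$excluded              # "g2"
#' @export
normalizeExpression <- function(expr) {
  if (is.matrix(expr)) expr <- makeExpressionSE(expr)
  stopifnot(is(expr, "SummarizedExperiment"))
  if (ncol(expr) < 2)
    stop("at least 2 cell-type columns are required")
  E <- SummarizedExperiment::assay(expr, 1)
  M <- apply(E, 1, stats::median)
  MAD <- apply(abs(E - M), 1, stats::median)
  excluded <- rownames(E)[MAD == 0]
  if (length(excluded))
    message(length(excluded), " gene(s) excluded for MAD = 0")
  keep <- MAD > 0
  e <- (E[keep, , drop = FALSE] - M[keep]) / MAD[keep]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(e = e),
    rowData = S4Vectors::DataFrame(M = M[keep], MAD = MAD[keep],
                                   row.names = rownames(E)[keep]),
    colData = SummarizedExperiment::colData(expr))
  S4Vectors::metadata(se)$excluded <- excluded
  new("NormalizedExpression", se)
}

#' Call cell-type-specific genes by the k x IQR rule
#'
#' A gene \eqn{g} is specific to cell type \eqn{c} iff its absolute
#' normalized expression satisfies \eqn{|e_{g,c}| \ge k \cdot
#' IQR(e_{g,\cdot})}, where the interquartile range is computed on the
#' signed normalized values across all cell types (linear-interpolation
#' quantiles, the common type-7 convention) and \eqn{k} defaults to 1.5
#' (the conventional outlier fence multiplier).  Genes with zero IQR are
#' never specific and are reported in the result.
#'
#' @param norm a [NormalizedExpression-class].
#' @param k positive threshold multiplier (default 1.5).
#' @return a [SpecificityCalls-class].
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 100))
#' colnames(m) <- paste0("ct", 1:5)
#' calls <- callSpecificGenes(normalizeExpression(m))
#' specificGenes(calls)$ct5  # "g1": only the outlying cell type
#' @export
callSpecificGenes <- function(norm, k = 1.5) {
  stopifnot(is(norm, "NormalizedExpression"))
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a single positive number")
  e <- SummarizedExperiment::assay(norm, "e")
  iqr <- apply(e, 1, stats::IQR, type = 7)
  names(iqr) <- rownames(e)
  zeroIqr <- rownames(e)[iqr == 0]
  spec <- abs(e) >= k * iqr & iqr > 0
  calls <- lapply(stats::setNames(colnames(e), colnames(e)),
                  function(ct) rownames(e)[spec[, ct]])
  new("SpecificityCalls", calls = calls, k = k, iqr = iqr,
      zeroIqrGenes = zeroIqr)
}
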