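# Expression level, tissue-specificity index tau, and annotation-breadth
# counts.

#' Mean expression level of a profile
#'
#' The expression level used throughout the class comparison: the
#' arithmetic mean over all samples.
#'
#' @param values Non-negative expression values, one per sample.
#' @return Arithmetic mean.
#' @export
expression_level <- function(values) {
  if (!length(values)) stop("empty expression profile", call. = FALSE)
  mean(values)
}

#' Tissue-specificity index tau
#'
#' `tau = sum_j (1 - log S_j / log S_max) / (n - 1)` over the `n` tissues,
#' where `S_max` is the gene's highest expression. Values are floored at
#' `floor` (default 1) before taking logs, which keeps the index defined
#' and inside \[0, 1\]; when `S_max <= floor` (so `log S_max = 0`) tau is
#' undefined and `NA` is returned. Uniform profiles give 0, single-tissue
#' profiles give 1, and the index is invariant to the logarithm base.
#'
#' @param values Non-negative expression values, one per tissue (`n >= 2`).
#' @param floor Floor applied before logs; default 1.
#' @return Tau in \[0, 1\], or `NA`.
#' @examples
#' tau(c(100, 10, 1))  # 0.75
#' @export
tau <- function(values, floor = 1) {
  n <- length(values)
  if (n < 2L) stop("tau requires at least 2 tissues", call. = FALSE)
  if (any(values < 0)) stop("negative expression values", call. = FALSE)
  v <- pmax(values, floor)
  smax <- max(v)
  if (log(smax) <= 0) return(NA_real_)
  sum(1 - log(v) / log(smax)) / (n - 1)
}

#' Read an expression matrix TSV
#'
#' First column gene ids, remaining columns one per sample; header required.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 3L)
    stop("expression matrix needs a gene_id column and >= 2 samples",
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Per-gene expression summaries from an expression matrix
#'
#' @param expr Matrix from [read_expression_matrix()].
#' @param gene_ids Genes to report; genes absent from the matrix get `NA`.
#' @param tau_floor Floor for [tau()].
#' @return Data frame with gene_id, expression_level, tau.
#' @export
expression_features <- function(expr, gene_ids, tau_floor = 1) {
  idx <- match(gene_ids, rownames(expr))
  lev <- rep(NA_real_, length(gene_ids))
  tv <- rep(NA_real_, length(gene_ids))
  ok <- !is.na(idx)
  lev[ok] <- rowMeans(expr[idx[ok], , drop = FALSE])
  tv[ok] <- apply(expr[idx[ok], , drop = FALSE], 1L, tau, floor = tau_floor)
  data.frame(gene_id = gene_ids, expression_level = lev, tau = tv)
}
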