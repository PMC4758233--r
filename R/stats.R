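# The statistical battery: Mann-Whitney U, Spearman rank correlation,
# coefficient of variation, two-proportion z test, PCA with loading
# retention, and percent-frequency histograms. All tests are two-sided.

new_test_result <- function(statistic, p_value, n1, n2, method,
                            flags = character(0)) {
  structure(list(statistic = statistic, p_value = p_value, n1 = n1, n2 = n2,
                 method = method, sidedness = "two-sided", flags = flags),
            class = "rh_test")
}

#' @export
print.rh_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, two-sided p = %.4g (n1 = %d, n2 = %d)%s\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic is computed from midranks of the pooled sample. The
#' two-sided p-value is exact (full enumeration) when the pooled size is at
#' most 12 and there are no ties, otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. A pooled sample
#' with zero variance returns p = 1 with a `zero_variance` flag.
#'
#' @param x,y Numeric vectors; missing values are dropped.
#' @return An `rh_test` with `statistic` = U for the first sample
#'   (`U_x + U_y = n1 * n2`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(new_test_result(U, 1, n1, n2, "Mann-Whitney U",
                           flags = "zero_variance"))
  ties <- anyDuplicated(pooled) > 0L
  exact <- (n1 + n2 <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  new_test_result(U, wt$p.value, n1, n2, "Mann-Whitney U")
}

#' Spearman rank correlation (two-sided)
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t-approximation with n - 2 degrees of freedom. Incomplete pairs are
#' dropped. Zero rank variance in either vector yields `NA` with a flag.
#'
#' @param x,y Paired numeric vectors (n >= 3 complete pairs).
#' @return An `rh_test` with `statistic` = rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    return(new_test_result(NA_real_, NA_real_, n, n, "Spearman rank correlation",
                           flags = "zero_rank_variance"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  new_test_result(unname(ct$estimate), ct$p.value, n, n,
                  "Spearman rank correlation")
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean;
#' undefined (`NA`) for zero mean. Scale-invariant for positive scalings.
#'
#' @param x Numeric vector.
#' @return SD/mean, or `NA`.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

#' Two-proportion z test (pooled variance, two-sided)
#'
#' `z = (p1 - p2) / sqrt(pp (1 - pp) (1/n1 + 1/n2))` with the pooled
#' proportion `pp = (k1 + k2)/(n1 + n2)`; no continuity correction. The
#' sign follows the first group (smaller first proportion gives z < 0).
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @return An `rh_test` with `statistic` = z; undefined (`NA` with flag)
#'   when the pooled proportion is 0 or 1.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  if (n1 < 1L || n2 < 1L || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("invalid counts", call. = FALSE)
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    return(new_test_result(NA_real_, NA_real_, n1, n2, "two-proportion z",
                           flags = "degenerate_pooled_proportion"))
  z <- (k1 / n1 - k2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  new_test_result(z, 2 * stats::pnorm(-abs(z)), n1, n2, "two-proportion z")
}

#' Principal component analysis of a feature matrix
#'
#' Complete-case rows only; variables are standardized and the correlation
#' matrix is eigendecomposed (unrotated extraction). Loadings are
#' `eigenvector * sqrt(eigenvalue)`; the sign of each component is fixed so
#' its largest-magnitude loading is positive. Per component, the retained
#' set is the variables with `|loading| > loading_threshold`.
#'
#' @param features Numeric matrix or data frame (genes x variables).
#' @param loading_threshold Retention cut on absolute loadings; default 0.5.
#' @return An object of class `feature_pca`: list with
#'   `component_variance_pct` (sums to 100), `loadings`
#'   (variables x components), `retained` (per-component character vectors),
#'   and `n_complete_cases`.
#' @export
feature_pca <- function(features, loading_threshold = 0.5) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 complete-case rows", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  if (nrow(x) < ncol(x))
    warning("fewer complete cases than variables; proceeding")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eigval <- pc$sdev^2
  load <- pc$rotation %*% diag(pc$sdev, length(pc$sdev))
  colnames(load) <- colnames(pc$rotation)
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  retained <- lapply(seq_len(ncol(load)), function(j) {
    rownames(load)[abs(load[, j]) > loading_threshold]
  })
  names(retained) <- colnames(load)
  structure(list(
    component_variance_pct = 100 * eigval / sum(eigval),
    loadings = load,
    retained = retained,
    n_complete_cases = nrow(x),
    loading_threshold = loading_threshold,
    scores = pc$x
  ), class = "feature_pca")
}

#' @export
print.feature_pca <- function(x, ...) {
  cat(sprintf("<feature_pca> %d complete cases, %d components\n",
              x$n_complete_cases, length(x$component_variance_pct)))
  v <- x$component_variance_pct
  cat(sprintf("  variance %%: %s\n",
              paste(sprintf("%.2f", v[seq_len(min(5, length(v)))]),
                    collapse = ", ")))
  for (j in seq_len(min(2L, length(x$retained)))) {
    cat(sprintf("  PC%d retained (|loading| > %.2f): %s\n", j,
                x$loading_threshold,
                paste(x$retained[[j]], collapse = ", ")))
  }
  invisible(x)
}

#' Percent-frequency histogram with fixed-width bins
#'
#' Left-closed right-open bins anchored at 0; frequencies are percentages
#' of the non-missing values.
#'
#' @param values Numeric vector.
#' @param bin_width Positive bin width.
#' @return Data frame with `bin_center` and `frequency_pct`; the center of
#'   the modal bin is attached as attribute `mode_bin`.
#' @export
freq_histogram <- function(values, bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  v <- values[is.finite(values)]
  if (!length(v)) {
    out <- data.frame(bin_center = numeric(0), frequency_pct = numeric(0))
    attr(out, "mode_bin") <- NA_real_
    return(out)
  }
  idx <- floor(v / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(i) sum(idx == i), numeric(1))
  out <- data.frame(bin_center = (rng + 0.5) * bin_width,
                    frequency_pct = 100 * counts / length(v))
  attr(out, "mode_bin") <- out$bin_center[which.max(counts)]
  out
}
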