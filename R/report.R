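# Class-comparison report: per-class rate summaries, Mann-Whitney battery,
# Spearman correlation table, intron/domain stratifications and PCA
# attribution, assembled into a single classed object.

rate_vars <- c("dN", "dS", "omega")
feature_vars <- c("gene_length", "utr5_length", "utr3_length", "intron_number",
                  "mean_intron_length", "gc_gene", "gc_utr5", "gc_utr3",
                  "gc3", "enc", "domain_number", "expression_level", "tau",
                  "po_count", "goslim_count")
# variables entering the PCA (the correlation battery minus mean intron
# length and gene-body GC, which the class analysis treats descriptively)
pca_vars <- c("gene_length", "utr5_length", "utr3_length", "intron_number",
              "gc_utr5", "gc_utr3", "gc3", "enc", "domain_number",
              "expression_level", "tau", "po_count", "goslim_count")

#' Stratify the class comparison by intron number
#'
#' Genes are split into intronless genes, genes with up to ten introns
#' (boundary included), and genes with more than ten introns; within each
#' group the two gene classes are compared by Mann-Whitney U for dN, dS and
#' dN/dS. Groups empty in either class report n only, tests skipped.
#'
#' @param records Feature table with columns class, intron_number, dN, dS,
#'   omega.
#' @return Data frame with group, variable, n_primary, n_secondary, U, p.
#' @export
stratify_by_intron <- function(records) {
  grp <- cut(records$intron_number, c(-Inf, 0, 10, Inf),
             labels = c("intronless", "1-10 introns", ">10 introns"))
  rows <- list()
  for (g in levels(grp)) {
    sub <- records[!is.na(grp) & grp == g, , drop = FALSE]
    for (v in rate_vars) {
      xp <- sub[[v]][sub$class == "primary"]
      xs <- sub[[v]][sub$class == "secondary"]
      xp <- xp[is.finite(xp)]
      xs <- xs[is.finite(xs)]
      if (length(xp) && length(xs)) {
        t <- mann_whitney_u(xp, xs)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = v, n_primary = length(xp),
          n_secondary = length(xs), U = t$statistic, p = t$p_value)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = v, n_primary = length(xp),
          n_secondary = length(xs), U = NA_real_, p = NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}

#' Domain-class proportions per gene class, with two-proportion z tests
#'
#' Proteins with at least one domain are classified single/double/multi
#' (1 / 2 / >= 3 domains); the percentage of each class is compared between
#' the two gene classes with the pooled two-proportion z test.
#'
#' @param records Feature table with columns class, domain_number.
#' @return List with `proportions` (class, domain_class, n, pct) and
#'   `tests` (domain_class, z, p, n_primary, n_secondary).
#' @export
domain_class_proportions <- function(records) {
  dc <- domain_class(records$domain_number)
  keep <- !is.na(dc)
  cls <- records$class[keep]
  dc <- dc[keep]
  props <- list()
  tests <- list()
  n_by_class <- table(cls)
  for (d in levels(dc)) {
    for (cl in names(n_by_class)) {
      k <- sum(dc == d & cls == cl)
      props[[length(props) + 1L]] <- data.frame(
        class = cl, domain_class = d, n = k,
        pct = 100 * k / as.integer(n_by_class[[cl]]))
    }
    t <- two_proportion_z(sum(dc == d & cls == "primary"),
                          as.integer(n_by_class[["primary"]]),
                          sum(dc == d & cls == "secondary"),
                          as.integer(n_by_class[["secondary"]]))
    tests[[length(tests) + 1L]] <- data.frame(
      domain_class = d, z = t$statistic, p = t$p_value,
      n_primary = as.integer(n_by_class[["primary"]]),
      n_secondary = as.integer(n_by_class[["secondary"]]))
  }
  list(proportions = do.call(rbind, props), tests = do.call(rbind, tests))
}

#' Compare GC3 between intronless and intron-containing genes
#'
#' Within each gene class, GC3 of intronless genes is compared with GC3 of
#' intron-containing genes by Mann-Whitney U. Rows with missing GC3 are
#' excluded from both groups.
#'
#' @param records Feature table with columns class, gc3, intron_number.
#' @return Data frame with class, n_intronless, n_with_intron, medians, U, p.
#' @export
gc3_by_intron_presence <- function(records) {
  rows <- list()
  for (cl in unique(records$class)) {
    sub <- records[records$class == cl & is.finite(records$gc3), , drop = FALSE]
    g0 <- sub$gc3[sub$intron_number == 0]
    g1 <- sub$gc3[sub$intron_number > 0]
    if (length(g0) && length(g1)) {
      t <- mann_whitney_u(g0, g1)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, n_intronless = length(g0), n_with_intron = length(g1),
        median_gc3_intronless = stats::median(g0),
        median_gc3_with_intron = stats::median(g1),
        U = t$statistic, p = t$p_value)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, n_intronless = length(g0), n_with_intron = length(g1),
        median_gc3_intronless = NA_real_, median_gc3_with_intron = NA_real_,
        U = NA_real_, p = NA_real_)
    }
  }
  do.call(rbind, rows)
}

summarise_rates <- function(records) {
  rows <- list()
  for (v in rate_vars) {
    xp <- records[[v]][records$class == "primary"]
    xs <- records[[v]][records$class == "secondary"]
    xp <- xp[is.finite(xp)]
    xs <- xs[is.finite(xs)]
    p <- if (length(xp) && length(xs)) mann_whitney_u(xp, xs)$p_value else NA_real_
    for (cl in c("primary", "secondary")) {
      x <- if (cl == "primary") xp else xs
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, variable = v, n = length(x), mean = mean(x),
        sd = stats::sd(x), cv = coefficient_of_variation(x),
        min = min(x), max = max(x), mwu_p = p)
    }
  }
  do.call(rbind, rows)
}

#' Run the full class-comparison battery on a per-gene feature table
#'
#' The central analysis constructor. Given a merged per-gene table of
#' divergence estimates (dN, dS, omega) and features for the two gene
#' classes, it computes: per-class rate summaries (mean, SD, CV, range,
#' Mann-Whitney p); Mann-Whitney class comparisons for every feature;
#' the Spearman correlation battery of every feature against dN, dS and
#' omega on the pooled gene set (pairwise deletion); intron-number
#' stratification; domain-class proportions with z tests; the
#' GC3-by-intron-presence comparison; and a PCA of the feature battery
#' (complete cases) with loading retention and Spearman correlations of the
#' first two component scores with the rates.
#'
#' @param records Data frame with columns gene_id, class and the rate and
#'   feature variables (missing features allowed).
#' @param loading_threshold PCA loading retention cut; default 0.5.
#' @return An object of class `pathway_comparison`.
#' @seealso [run_pipeline()] for the file-based end-to-end driver.
#' @export
compare_pathway_classes <- function(records, loading_threshold = 0.5) {
  if (!all(c("class", "dN", "dS", "omega") %in% names(records)))
    stop("records must contain class, dN, dS, omega", call. = FALSE)
  records$class <- as.character(records$class)
  if (!all(records$class %in% c("primary", "secondary")))
    stop("class labels must be 'primary' or 'secondary'", call. = FALSE)

  fvars <- intersect(feature_vars, names(records))

  class_tests <- do.call(rbind, lapply(fvars, function(v) {
    xp <- records[[v]][records$class == "primary"]
    xs <- records[[v]][records$class == "secondary"]
    xp <- xp[is.finite(xp)]
    xs <- xs[is.finite(xs)]
    if (!length(xp) || !length(xs))
      return(data.frame(variable = v, mean_primary = NA_real_,
                        mean_secondary = NA_real_, n_primary = length(xp),
                        n_secondary = length(xs), U = NA_real_, p = NA_real_))
    t <- mann_whitney_u(xp, xs)
    data.frame(variable = v, mean_primary = mean(xp),
               mean_secondary = mean(xs), n_primary = length(xp),
               n_secondary = length(xs), U = t$statistic, p = t$p_value)
  }))

  correlations <- do.call(rbind, lapply(fvars, function(v) {
    row <- data.frame(variable = v)
    for (r in rate_vars) {
      ok <- is.finite(records[[v]]) & is.finite(records[[r]])
      res <- if (sum(ok) >= 3L) spearman_rho(records[[v]][ok], records[[r]][ok])
             else NULL
      row[[paste0("rho_", r)]] <- if (is.null(res)) NA_real_ else res$statistic
      row[[paste0("p_", r)]] <- if (is.null(res)) NA_real_ else res$p_value
    }
    row
  }))

  pvars <- intersect(pca_vars, names(records))
  pca_in <- records[, pvars, drop = FALSE]
  pca_res <- tryCatch(feature_pca(pca_in, loading_threshold),
                      error = function(e) NULL)
  pc_rate_cor <- NULL
  if (!is.null(pca_res)) {
    cc <- stats::complete.cases(pca_in)
    sc <- pca_res$scores
    pc_rate_cor <- do.call(rbind, lapply(1:2, function(j) {
      row <- data.frame(component = paste0("PC", j),
                        variance_pct = pca_res$component_variance_pct[j])
      for (r in rate_vars) {
        rv <- records[[r]][cc]
        ok <- is.finite(rv)
        res <- if (sum(ok) >= 3L) spearman_rho(sc[ok, j], rv[ok]) else NULL
        row[[paste0("rho_", r)]] <- if (is.null(res)) NA_real_ else res$statistic
        row[[paste0("p_", r)]] <- if (is.null(res)) NA_real_ else res$p_value
      }
      row
    }))
  }

  structure(list(
    n_genes = table(factor(records$class, c("primary", "secondary"))),
    rate_summary = summarise_rates(records),
    class_tests = class_tests,
    correlations = correlations,
    intron_strata = stratify_by_intron(records),
    domain_classes = domain_class_proportions(records),
    gc3_intron = gc3_by_intron_presence(records),
    pca = pca_res,
    pc_rate_cor = pc_rate_cor,
    loading_threshold = loading_threshold,
    records = records
  ), class = "pathway_comparison")
}

#' @export
print.pathway_comparison <- function(x, digits = 4, ...) {
  cat("Pathway-class comparison of evolutionary rates\n")
  cat(sprintf("  genes analyzed: %d primary, %d secondary\n\n",
              x$n_genes[["primary"]], x$n_genes[["secondary"]]))
  rs <- x$rate_summary
  for (v in unique(rs$variable)) {
    sub <- rs[rs$variable == v, ]
    cat(sprintf("  %-6s primary %.4f (SD %.4f)  secondary %.4f (SD %.4f)  MWU p = %.3g\n",
                v, sub$mean[sub$class == "primary"],
                sub$sd[sub$class == "primary"],
                sub$mean[sub$class == "secondary"],
                sub$sd[sub$class == "secondary"], sub$mwu_p[1L]))
  }
  if (!is.null(x$pca))
    cat(sprintf("\n  PCA: PC1+PC2 explain %.3f%% of total variance\n",
                sum(x$pca$component_variance_pct[1:2])))
  invisible(x)
}

#' @export
summary.pathway_comparison <- function(object, ...) {
  x <- object
  print(x)
  cat("\nClass comparisons (Mann-Whitney U):\n")
  print(x$class_tests, digits = 4, row.names = FALSE)
  cat("\nSpearman correlations with dN, dS, dN/dS (pooled genes):\n")
  print(x$correlations, digits = 3, row.names = FALSE)
  cat("\nIntron-number stratification:\n")
  print(x$intron_strata, digits = 3, row.names = FALSE)
  cat("\nDomain-class proportions:\n")
  print(x$domain_classes$proportions, digits = 4, row.names = FALSE)
  print(x$domain_classes$tests, digits = 3, row.names = FALSE)
  cat("\nGC3 by intron presence:\n")
  print(x$gc3_intron, digits = 3, row.names = FALSE)
  if (!is.null(x$pca)) {
    cat("\nPCA loadings retained (|loading| >", x$loading_threshold, "):\n")
    for (j in 1:2)
      cat(sprintf("  PC%d (%.3f%%): %s\n", j,
                  x$pca$component_variance_pct[j],
                  paste(x$pca$retained[[j]], collapse = ", ")))
    if (!is.null(x$pc_rate_cor)) {
      cat("\nComponent-score correlations with rates:\n")
      print(x$pc_rate_cor, digits = 3, row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
plot.pathway_comparison <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in rate_vars) {
    graphics::boxplot(x$records[[v]] ~ x$records$class, col = c("white", "grey"),
                      main = v, xlab = "", ylab = v, ...)
  }
  invisible(x)
}

#' Write the report's table mirrors as TSV files
#'
#' Writes table1-style per-class rate summaries, the table2-style Spearman
#' battery, the table3-style PCA summary, and the stratified analyses.
#'
#' @param x A `pathway_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  w(x$rate_summary, "table1_rates.tsv")
  w(x$correlations, "table2_correlations.tsv")
  if (!is.null(x$pca)) {
    t3 <- data.frame(
      component = names(x$pca$retained),
      variance_pct = x$pca$component_variance_pct,
      retained = vapply(x$pca$retained, paste, character(1), collapse = ","))
    w(t3, "table3_pca.tsv")
  }
  w(x$class_tests, "class_tests.tsv")
  # group boundary convention recorded in the header name: "1-10" includes 10
  w(x$intron_strata, "intron_strata.tsv")
  w(x$domain_classes$proportions, "domain_class_proportions.tsv")
  w(x$domain_classes$tests, "domain_class_tests.tsv")
  w(x$gc3_intron, "gc3_by_intron.tsv")
  invisible(dir)
}
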