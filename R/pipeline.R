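# End-to-end driver: read a bundle of input files, apply QC and
# longest-isoform selection, estimate divergence, assemble features and run
# the class comparison. Deterministic given fixed inputs.

#' Build a pipeline configuration from a bundle directory
#'
#' Maps the standard file names written by [simulate_study()] to the
#' configuration keys [run_pipeline()] expects.
#'
#' @param dir Bundle directory.
#' @param loading_threshold PCA loading retention cut.
#' @param tau_floor Expression floor for [tau()].
#' @return A named list of paths and parameters.
#' @export
bundle_config <- function(dir, loading_threshold = 0.5, tau_floor = 1) {
  list(
    gff3 = file.path(dir, "genes.gff3"),
    genome_fasta = file.path(dir, "genome.fa"),
    pairs_fasta = file.path(dir, "pairs.fa"),
    expression_tsv = file.path(dir, "expression.tsv"),
    domains_tsv = file.path(dir, "domains.tsv"),
    go_tsv = file.path(dir, "go_slim.tsv"),
    po_tsv = file.path(dir, "po_terms.tsv"),
    class_map_tsv = file.path(dir, "class_map.tsv"),
    loading_threshold = loading_threshold,
    tau_floor = tau_floor
  )
}

#' Run the full comparative-rate pipeline on a file bundle
#'
#' Stages: (1) read the gene class map; (2) read gene models from GFF3 plus
#' genome FASTA and keep the longest isoform per gene; (3) apply the CDS
#' quality rules; (4) estimate pairwise dN/dS from the aligned ortholog
#' pairs; (5) compute architecture/GC/codon-usage features, domain and
#' PO/GO-slim term counts and expression summaries; (6) merge and run
#' [compare_pathway_classes()]. Every gene of the class map ends up either
#' in the analyzed set or in a logged exclusion category (QC fail, no
#' ortholog pair, divergence estimation failed, missing model). Genes with
#' missing expression stay in the analysis with `NA` expression columns.
#'
#' @param config Named list of paths (gff3, genome_fasta, pairs_fasta,
#'   expression_tsv, domains_tsv, go_tsv, po_tsv, class_map_tsv) and
#'   parameters (loading_threshold, tau_floor), e.g. from [bundle_config()].
#' @param out_dir Optional directory; when given, all intermediate tables
#'   and the report TSV mirrors are written there.
#' @return An object of class `rate_pipeline`: list with `comparison` (a
#'   `pathway_comparison`), `records`, `divergence`, `qc_report`,
#'   `exclusions` (gene_id, reason) and `counts` (per-stage gene counts).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  lt <- config$loading_threshold %||% 0.5
  tf <- config$tau_floor %||% 1

  class_map <- utils::read.delim(config$class_map_tsv, header = TRUE,
                                 stringsAsFactors = FALSE)
  names(class_map)[1:2] <- c("gene_id", "class")
  all_ids <- class_map$gene_id

  genome <- read_fasta(config$genome_fasta)
  models <- read_gff3(config$gff3, genome = genome)
  models <- collapse_isoforms(models)
  model_ids <- vapply(models, `[[`, character(1), "gene_id")

  qc <- qc_gene_models(models)
  pass_ids <- vapply(qc$pass, `[[`, character(1), "gene_id")

  pairs <- read_pair_fasta(config$pairs_fasta)
  div <- batch_divergence(pairs)

  exclusions <- list()
  note <- function(ids, reason) {
    if (length(ids))
      exclusions[[length(exclusions) + 1L]] <<- data.frame(
        gene_id = ids, reason = reason)
  }
  note(setdiff(all_ids, model_ids), "no_gene_model")
  note(intersect(all_ids, qc$report$failed_ids), "qc_fail")
  note(setdiff(intersect(all_ids, pass_ids), div$gene_id), "no_ortholog_pair")
  div_fail <- div$gene_id[startsWith(div$flags, "error:")]
  note(intersect(intersect(all_ids, pass_ids), div_fail), "divergence_failed")

  excl_df <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(gene_id = character(0), reason = character(0))
  analyzed_ids <- setdiff(all_ids, excl_df$gene_id)

  keep <- qc$pass[match(analyzed_ids, pass_ids)]
  feats <- gene_features(keep, class_map, domains = config$domains_tsv)

  expr <- read_expression_matrix(config$expression_tsv)
  ef <- expression_features(expr, analyzed_ids, tau_floor = tf)
  feats$expression_level <- ef$expression_level[match(feats$gene_id, ef$gene_id)]
  feats$tau <- ef$tau[match(feats$gene_id, ef$gene_id)]
  feats$po_count <- unname(term_count(config$po_tsv, feats$gene_id))
  feats$goslim_count <- unname(term_count(config$go_tsv, feats$gene_id))

  di <- match(feats$gene_id, div$gene_id)
  feats$dN <- div$dN[di]
  feats$dS <- div$dS[di]
  feats$omega <- div$omega[di]

  comparison <- compare_pathway_classes(feats, loading_threshold = lt)
  counts <- data.frame(
    stage = c("class_map", "gene_models", "qc_pass", "pairs", "analyzed",
              "analyzed_primary", "analyzed_secondary"),
    n = c(length(all_ids), length(models), length(pass_ids), nrow(pairs),
          length(analyzed_ids),
          sum(feats$class == "primary"), sum(feats$class == "secondary")))

  out <- structure(list(
    comparison = comparison, records = feats, divergence = div,
    qc_report = qc$report, exclusions = excl_df, counts = counts,
    config = config
  ), class = "rate_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_features(feats, file.path(out_dir, "features.tsv"))
    utils::write.table(div, file.path(out_dir, "divergence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    write_qc_report(qc$report, models, file.path(out_dir, "qc_report.tsv"))
    utils::write.table(excl_df, file.path(out_dir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(counts, file.path(out_dir, "stage_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(comparison, out_dir)
  }
  out
}

#' @export
print.rate_pipeline <- function(x, ...) {
  cat("Comparative-rate pipeline result\n")
  print(x$counts, row.names = FALSE)
  if (nrow(x$exclusions)) {
    cat("exclusions:\n")
    print(table(x$exclusions$reason))
  }
  cat("\n")
  print(x$comparison)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
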