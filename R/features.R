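# Per-gene architecture, GC, codon-usage (GC3, ENc) and domain-count
# features - the predictor battery for the class comparison.

#' Gene-architecture features of a gene model
#'
#' @param model A `gene_model` (see [read_gff3()]).
#' @return A one-row data frame with gene_length (`end - start + 1`),
#'   utr5_length and utr3_length (sums of all UTR segment lengths per side;
#'   0 when no UTR is annotated), intron_number (`max(0, exons - 1)`) and
#'   mean_intron_length (mean inclusive inter-exon gap,
#'   `next_start - prev_end - 1`; `NA` for intronless genes).
#' @export
architecture_features <- function(model) {
  ex <- model$exons
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
    stop("overlapping exons in gene ", model$gene_id, call. = FALSE)
  n_intron <- max(0L, nrow(ex) - 1L)
  mean_intron <- if (n_intron > 0L) {
    mean(ex$start[-1L] - ex$end[-nrow(ex)] - 1L)
  } else NA_real_
  data.frame(
    gene_id = model$gene_id,
    gene_length = model$end - model$start + 1L,
    utr5_length = sum(model$utr5_segments$end - model$utr5_segments$start + 1L),
    utr3_length = sum(model$utr3_segments$end - model$utr3_segments$start + 1L),
    intron_number = n_intron,
    mean_intron_length = mean_intron
  )
}

#' GC content of a nucleotide string
#'
#' N bases are excluded from both numerator and denominator; an empty or
#' all-N sequence yields `NA`.
#'
#' @param seq Nucleotide string.
#' @return Fraction of G+C among A/C/G/T bases, or `NA`.
#' @export
gc_content <- function(seq) {
  if (is.null(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    return(NA_real_)
  seq <- toupper(seq)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(seq) - nchar(gsub(b, "", seq, fixed = TRUE))
  }, numeric(1))
  denom <- sum(counts)
  if (denom == 0) return(NA_real_)
  unname((counts["G"] + counts["C"]) / denom)
}

#' GC content at third codon positions
#'
#' Fraction of G or C at the third positions of all sense codons of a
#' validated CDS; the terminal stop codon is excluded. This is plain GC3
#' over all third positions, not the synonymous-only GC3s variant.
#'
#' @param cds_seq A CDS passing [validate_cds()].
#' @return Fraction in \[0, 1\].
#' @export
gc3 <- function(cds_seq) {
  v <- validate_cds(cds_seq)
  if (!v$pass)
    stop("CDS fails quality control (", paste(v$reasons, collapse = ", "),
         ")", call. = FALSE)
  cds_seq <- toupper(cds_seq)
  cod <- split_codons(cds_seq)
  cod <- cod[-length(cod)]                     # drop terminal stop
  third <- substr(cod, 3L, 3L)
  third <- third[third %in% c("A", "C", "G", "T")]
  if (!length(third)) return(NA_real_)
  mean(third %in% c("G", "C"))
}

#' Effective number of codons (ENc)
#'
#' Wright's (1990) codon-usage-bias statistic. For each amino-acid family
#' observed with `n >= 2` codons the homozygosity is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; class averages over observed
#' 2-, 3-, 4- and 6-fold families give
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (the Met and Trp singleton
#' families contribute the constant 2). When no 3-fold (Ile) family is
#' observed, `F3` is replaced by `(F2 + F4)/2`, Wright's recommendation.
#' The result is clamped to \[20, 61\].
#'
#' @param cds_seq A CDS passing [validate_cds()] (terminal stop excluded).
#' @return ENc in \[20, 61\], or `NA` (with a warning) when too few family
#'   classes are observed.
#' @export
enc <- function(cds_seq) {
  v <- validate_cds(cds_seq)
  if (!v$pass)
    stop("CDS fails quality control (", paste(v$reasons, collapse = ", "),
         ")", call. = FALSE)
  tab <- codon_tables()
  cod <- split_codons(toupper(cds_seq))
  cod <- cod[-length(cod)]
  idx <- match(cod, tab$sense)
  idx <- idx[!is.na(idx)]                      # codons with N are ignored
  counts <- tabulate(idx, nbins = length(tab$sense))

  fam_F <- lapply(tab$fam, function(members) {
    k <- length(members)
    n <- sum(counts[members])
    if (k == 1L || n < 2L) return(NULL)        # singletons & unobserved excluded
    p <- counts[members] / n
    list(size = k, F = (n * sum(p^2) - 1) / (n - 1))
  })
  fam_F <- fam_F[!vapply(fam_F, is.null, logical(1))]
  sizes <- vapply(fam_F, `[[`, numeric(1), "size")
  Fs <- vapply(fam_F, `[[`, numeric(1), "F")
  Fbar <- function(k) if (any(sizes == k)) mean(Fs[sizes == k]) else NA_real_

  F2 <- Fbar(2)
  F3 <- Fbar(3)
  F4 <- Fbar(4)
  F6 <- Fbar(6)
  if (is.na(F2)) {
    warning("ENc undefined: no 2-fold family observed with >= 2 codons")
    return(NA_real_)
  }
  if (is.na(F4) || is.na(F6)) {
    warning("ENc undefined: 4- or 6-fold family class unobserved")
    return(NA_real_)
  }
  if (is.na(F3)) F3 <- (F2 + F4) / 2
  val <- 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6
  min(61, max(20, val))
}

#' Count protein domains per gene
#'
#' @param annotation Data frame (or TSV path) with columns gene_id and
#'   domain id; duplicate rows are counted.
#' @param gene_ids Genes to report; genes absent from the table get 0.
#' @return Named integer vector of domain counts.
#' @export
count_domains <- function(annotation, gene_ids) {
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- utils::read.delim(annotation, header = TRUE,
                                    stringsAsFactors = FALSE)
  tab <- table(factor(annotation[[1L]], levels = gene_ids))
  stats::setNames(as.integer(tab), gene_ids)
}

#' Count distinct annotation terms per gene
#'
#' Used for Plant Ontology terms (breadth of expression) and GO-slim
#' biological-process terms (multifunctionality). Duplicate (gene, term)
#' rows collapse to one.
#'
#' @param annotation Data frame (or TSV path) with columns gene_id, term_id.
#' @param gene_ids Genes to report; absent genes get 0.
#' @return Named integer vector of distinct-term counts.
#' @export
term_count <- function(annotation, gene_ids) {
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- utils::read.delim(annotation, header = TRUE,
                                    stringsAsFactors = FALSE)
  annotation <- unique(annotation[, 1:2])
  tab <- table(factor(annotation[[1L]], levels = gene_ids))
  stats::setNames(as.integer(tab), gene_ids)
}

#' Domain-count class of a protein
#'
#' @param count Domain count per gene (vector allowed).
#' @return Factor with levels single (1), double (2), multi (>= 3);
#'   counts of 0 yield `NA` (excluded from domain-class analyses).
#' @export
domain_class <- function(count) {
  out <- ifelse(count >= 3, "multi",
                ifelse(count == 2, "double",
                       ifelse(count == 1, "single", NA_character_)))
  factor(out, levels = c("single", "double", "multi"))
}

#' Assemble the per-gene feature table
#'
#' Combines architecture, GC, codon-usage and domain-count features for a
#' set of gene models (one longest isoform per gene, post-QC). Genes lacking
#' annotated UTRs get UTR length 0 and `NA` UTR GC.
#'
#' @param models List of `gene_model` objects with sequence fields filled.
#' @param class_map Data frame with columns gene_id, class
#'   (`primary`/`secondary`).
#' @param domains Optional domain annotation (data frame or TSV path).
#' @return Data frame with columns gene_id, class, gene_length, utr5_length,
#'   utr3_length, intron_number, mean_intron_length, gc_gene, gc_utr5,
#'   gc_utr3, gc3, enc, domain_number.
#' @export
gene_features <- function(models, class_map, domains = NULL) {
  arch <- do.call(rbind, lapply(models, architecture_features))
  gids <- arch$gene_id
  cls <- class_map$class[match(gids, class_map$gene_id)]
  f <- data.frame(
    gene_id = gids,
    class = cls,
    arch[, -1L],
    gc_gene = vapply(models, function(m) gc_content(m$gene_seq), numeric(1)),
    gc_utr5 = vapply(models, function(m) gc_content(m$utr5_seq), numeric(1)),
    gc_utr3 = vapply(models, function(m) gc_content(m$utr3_seq), numeric(1)),
    gc3 = vapply(models, function(m) gc3(m$cds_seq), numeric(1)),
    enc = vapply(models, function(m) enc(m$cds_seq), numeric(1)),
    row.names = NULL
  )
  f$domain_number <- if (is.null(domains)) NA_integer_ else
    unname(count_domains(domains, gids))
  f
}

#' Write the feature table with its canonical headers
#'
#' @param features Data frame from [gene_features()].
#' @param path Output TSV path; missing values are written as `NA`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
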