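# FASTA/GFF3 input, gene-model assembly, CDS quality control and
# longest-isoform selection.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is converted to T so that downstream codon
#' machinery sees DNA only.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return Named character vector of sequences, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  stats::setNames(unname(seqs), ids)
}

#' Validate a coding sequence against the three CDS quality rules
#'
#' A CDS passes when it begins with an ATG start codon, ends with a stop
#' codon (TAG/TAA/TGA) and has length a multiple of three. All violated
#' rules are reported; internal stop codons are deliberately not checked.
#'
#' @param cds_seq Non-empty nucleotide string over A/C/G/T/N.
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   subset of `"start"`, `"stop"`, `"frame"`; empty on pass).
#' @examples
#' validate_cds("ATGAAATAG")   # pass
#' validate_cds("ATGAAATAGA")  # frame failure
#' @export
validate_cds <- function(cds_seq) {
  if (!is.character(cds_seq) || length(cds_seq) != 1L || !nzchar(cds_seq))
    stop("'cds_seq' must be a single non-empty string", call. = FALSE)
  cds_seq <- toupper(cds_seq)
  if (grepl("[^ACGTN]", cds_seq))
    stop("'cds_seq' contains characters outside {A,C,G,T,N}", call. = FALSE)
  reasons <- character(0)
  if (substr(cds_seq, 1L, 3L) != "ATG") reasons <- c(reasons, "start")
  n <- nchar(cds_seq)
  if (n < 3L || !(substr(cds_seq, n - 2L, n) %in% c("TAG", "TAA", "TGA")))
    reasons <- c(reasons, "stop")
  if (n %% 3L != 0L) reasons <- c(reasons, "frame")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

new_gene_model <- function(gene_id, isoform_id, chrom, start, end, strand,
                           exons, utr5_segments, utr3_segments, cds_segments,
                           cds_seq = NA_character_, gene_seq = NA_character_,
                           utr5_seq = NA_character_, utr3_seq = NA_character_) {
  stopifnot(start <= end, strand %in% c("+", "-"))
  if (nrow(exons)) {
    exons <- exons[order(exons$start), , drop = FALSE]
    if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
      stop("overlapping exons in gene ", gene_id, call. = FALSE)
  }
  structure(list(
    gene_id = gene_id, isoform_id = isoform_id, chrom = chrom,
    start = start, end = end, strand = strand,
    exons = exons, utr5_segments = utr5_segments,
    utr3_segments = utr3_segments, cds_segments = cds_segments,
    cds_seq = cds_seq, gene_seq = gene_seq,
    utr5_seq = utr5_seq, utr3_seq = utr3_seq
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (isoform %s) %s:%d-%d(%s)\n",
              x$gene_id, x$isoform_id, x$chrom, x$start, x$end, x$strand))
  cat(sprintf("  exons: %d  introns: %d  CDS: %s nt  UTR5: %d nt  UTR3: %d nt\n",
              nrow(x$exons), max(0L, nrow(x$exons) - 1L),
              if (is.na(x$cds_seq)) "?" else nchar(x$cds_seq),
              sum(x$utr5_segments$end - x$utr5_segments$start + 1L),
              sum(x$utr3_segments$end - x$utr3_segments$start + 1L)))
  invisible(x)
}

seg_df <- function(start = integer(0), end = integer(0)) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

# concatenate genomic slices in genomic order; reverse-complement on minus
extract_tx_seq <- function(chrom_seq, segs, strand) {
  if (!nrow(segs)) return("")
  segs <- segs[order(segs$start), , drop = FALSE]
  s <- paste(substring(chrom_seq, segs$start, segs$end), collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Read gene models from a GFF3 file
#'
#' Assembles one [gene model][read_gff3] per (gene, mRNA) from standard
#' gene/mRNA/exon/five_prime_UTR/three_prime_UTR/CDS features. Coordinates
#' are kept 1-based inclusive as in GFF3; exons are stored in genomic order
#' and, when a genome is supplied, sequence fields of minus-strand genes are
#' reverse-complemented so they read in transcript orientation.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional named character vector of chromosome/scaffold
#'   sequences (e.g. from [read_fasta()]); when supplied, `cds_seq`,
#'   `gene_seq`, `utr5_seq` and `utr3_seq` are filled in.
#' @return A list of `gene_model` objects.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated columns, got %d",
                 bad, nf[which(nf != 9L)[1L]]), call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) as.list(gr$Parent) else
    rep(list(character(0)), length(gr))

  genes <- which(type == "gene")
  mrnas <- which(type %in% c("mRNA", "transcript"))
  gene_ids <- id[genes]
  mrna_ids <- id[mrnas]

  known <- c(gene_ids, mrna_ids)
  all_parents <- unique(unlist(parent))
  orphan <- setdiff(all_parents, known)
  if (length(orphan))
    stop("feature with unknown Parent: ", paste(orphan, collapse = ", "),
         call. = FALSE)

  mrna_parent <- vapply(parent[mrnas], function(p) p[1L], character(1))
  if (any(is.na(mrna_parent)))
    stop("mRNA feature without Parent gene", call. = FALSE)

  child_parent <- parent
  models <- vector("list", length(mrnas))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))

  # index children by parent mRNA id
  child_idx <- which(!type %in% c("gene", "mRNA", "transcript"))
  reps <- lengths(child_parent[child_idx])
  pmap <- split(rep(child_idx, reps), unlist(child_parent[child_idx]))

  for (m in seq_along(mrnas)) {
    mi <- mrnas[m]
    tid <- mrna_ids[m]
    gid <- mrna_parent[m]
    gi <- genes[match(gid, gene_ids)]
    kids <- pmap[[tid]]
    pick <- function(t) {
      k <- kids[type[kids] == t]
      seg_df(st[k], en[k])
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    utr5 <- pick("five_prime_UTR")
    utr3 <- pick("three_prime_UTR")
    chrom_seq <- if (!is.null(genome)) genome[[chrom[mi]]] else NULL
    mdl <- new_gene_model(
      gene_id = gid, isoform_id = tid, chrom = chrom[mi],
      start = st[gi], end = en[gi], strand = strand[mi],
      exons = exons, utr5_segments = utr5, utr3_segments = utr3,
      cds_segments = cds
    )
    if (!is.null(chrom_seq)) {
      mdl$cds_seq <- extract_tx_seq(chrom_seq, cds, strand[mi])
      mdl$utr5_seq <- extract_tx_seq(chrom_seq, utr5, strand[mi])
      mdl$utr3_seq <- extract_tx_seq(chrom_seq, utr3, strand[mi])
      g <- substring(chrom_seq, st[gi], en[gi])
      mdl$gene_seq <- if (strand[mi] == "-") revcomp(g) else g
    }
    models[[m]] <- mdl
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3()] at the coordinate level: writing a model set and
#' re-reading it yields identical coordinates and strands.
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  acc <- list(chrom = list(), start = list(), end = list(), strand = list(),
              type = list(), ID = list(), Parent = list(), phase = list())
  push <- function(chrom, start, end, strand, type, ID, Parent, phase) {
    n <- length(start)
    i <- length(acc$start) + 1L
    acc$chrom[[i]] <<- rep_len(chrom, n)
    acc$start[[i]] <<- start
    acc$end[[i]] <<- end
    acc$strand[[i]] <<- rep_len(strand, n)
    acc$type[[i]] <<- rep_len(type, n)
    acc$ID[[i]] <<- rep_len(ID, n)
    acc$Parent[[i]] <<- rep_len(Parent, n)
    acc$phase[[i]] <<- phase
  }
  seen_gene <- character(0)
  for (m in models) {
    if (!m$gene_id %in% seen_gene) {
      push(m$chrom, m$start, m$end, m$strand, "gene", m$gene_id,
           NA_character_, NA_integer_)
      seen_gene <- c(seen_gene, m$gene_id)
    }
    push(m$chrom, m$start, m$end, m$strand, "mRNA", m$isoform_id,
         m$gene_id, NA_integer_)
    if (nrow(m$exons))
      push(m$chrom, m$exons$start, m$exons$end, m$strand, "exon",
           NA_character_, m$isoform_id, rep(NA_integer_, nrow(m$exons)))
    if (nrow(m$cds_segments)) {
      segs <- m$cds_segments[order(m$cds_segments$start), , drop = FALSE]
      len <- segs$end - segs$start + 1L
      # phase counts from the transcript 5' end
      cum <- if (m$strand == "+") cumsum(c(0L, len[-length(len)])) else
        rev(cumsum(c(0L, rev(len)[-length(len)])))
      push(m$chrom, segs$start, segs$end, m$strand, "CDS", NA_character_,
           m$isoform_id, as.integer((3L - cum %% 3L) %% 3L))
    }
    if (nrow(m$utr5_segments))
      push(m$chrom, m$utr5_segments$start, m$utr5_segments$end, m$strand,
           "five_prime_UTR", NA_character_, m$isoform_id,
           rep(NA_integer_, nrow(m$utr5_segments)))
    if (nrow(m$utr3_segments))
      push(m$chrom, m$utr3_segments$start, m$utr3_segments$end, m$strand,
           "three_prime_UTR", NA_character_, m$isoform_id,
           rep(NA_integer_, nrow(m$utr3_segments)))
  }
  par <- unlist(acc$Parent)
  gr <- GenomicRanges::GRanges(
    seqnames = unlist(acc$chrom),
    ranges = IRanges::IRanges(start = unlist(acc$start),
                              end = unlist(acc$end)),
    strand = unlist(acc$strand))
  gr$type <- unlist(acc$type)
  gr$phase <- unlist(acc$phase)
  gr$ID <- unlist(acc$ID)
  plist <- as.list(par)
  plist[is.na(par)] <- list(character(0))
  gr$Parent <- IRanges::CharacterList(plist)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Select the longest isoform of a gene
#'
#' Returns the model with the longest CDS; ties are broken deterministically
#' by the lexicographically smallest isoform id.
#'
#' @param models Non-empty list of `gene_model` objects sharing one gene id.
#' @return A single `gene_model`.
#' @export
select_longest_isoform <- function(models) {
  if (!length(models)) stop("empty model list", call. = FALSE)
  gids <- vapply(models, `[[`, character(1), "gene_id")
  if (length(unique(gids)) != 1L)
    stop("models do not share a single gene_id", call. = FALSE)
  len <- vapply(models, function(m) nchar(m$cds_seq), integer(1))
  iso <- vapply(models, `[[`, character(1), "isoform_id")
  ord <- order(-len, iso)
  models[[ord[1L]]]
}

# one longest isoform per gene across a mixed model list
collapse_isoforms <- function(models) {
  gids <- vapply(models, `[[`, character(1), "gene_id")
  lapply(split(models, gids), select_longest_isoform)
}

#' Apply CDS quality control to a set of gene models
#'
#' Each model's CDS is checked against the three rules of [validate_cds()].
#' Every input gene lands in exactly one of the pass or fail sets.
#'
#' @param models List of `gene_model` objects (one per gene).
#' @return A list with `pass` (the passing models) and `report`, a
#'   `qc_report` object with counts per failure rule and the failed ids.
#' @export
qc_gene_models <- function(models) {
  res <- lapply(models, function(m) validate_cds(m$cds_seq))
  pass <- vapply(res, `[[`, logical(1), "pass")
  reasons <- lapply(res, `[[`, "reasons")
  gids <- vapply(models, `[[`, character(1), "gene_id")
  report <- structure(list(
    n_input = length(models),
    n_pass = sum(pass),
    n_fail_start = sum(vapply(reasons, function(r) "start" %in% r, logical(1))),
    n_fail_stop = sum(vapply(reasons, function(r) "stop" %in% r, logical(1))),
    n_fail_frame = sum(vapply(reasons, function(r) "frame" %in% r, logical(1))),
    failed_ids = gids[!pass],
    reasons = stats::setNames(reasons[!pass], gids[!pass])
  ), class = "qc_report")
  list(pass = models[pass], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d input, %d pass, %d fail (start %d, stop %d, frame %d)\n",
              x$n_input, x$n_pass, length(x$failed_ids),
              x$n_fail_start, x$n_fail_stop, x$n_fail_frame))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report`.
#' @param models The model list the report was computed from.
#' @param path Output TSV path (columns gene_id, pass, reasons).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, models, path) {
  gids <- vapply(models, `[[`, character(1), "gene_id")
  pass <- !gids %in% report$failed_ids
  reasons <- vapply(gids, function(g) {
    r <- report$reasons[[g]]
    if (is.null(r)) "" else paste(r, collapse = ",")
  }, character(1))
  utils::write.table(
    data.frame(gene_id = gids, pass = pass, reasons = reasons),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
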