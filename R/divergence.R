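# Pairwise dN/dS estimation for codon-aligned ortholog CDS pairs:
# Nei-Gojobori (1986) site and pathway-averaged difference counting with
# Jukes-Cantor correction.

#' Estimate pairwise dN, dS and dN/dS for one aligned CDS pair
#'
#' Nei-Gojobori (1986) counting: expected synonymous/nonsynonymous sites are
#' averaged over the two sequences across compared codon columns, differences
#' are pathway-averaged per codon, and the resulting proportions are
#' Jukes-Cantor corrected, `d = -3/4 * log(1 - 4p/3)`. Codon columns
#' containing a gap, an ambiguous base or a stop codon are skipped and
#' counted, as are the rare columns where every substitution pathway passes
#' through a stop codon. `omega = dN/dS` is `NA` when `dS = 0`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length, a multiple
#'   of three, with gaps (`-`) codon-aligned.
#' @param gene_id Optional identifier carried into the result.
#' @return An object of class `divergence_estimate`: a list with
#'   `n_codons_compared`, `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`,
#'   `dS`, `dN`, `omega`, `skipped` (named counts: gap, ambiguous, stop,
#'   pathway_blocked) and `flags`.
#' @examples
#' a <- strrep("ATGGGGAAA", 10)
#' estimate_divergence(a, a)$dS  # identical pair: 0
#' @export
estimate_divergence <- function(seq_a, seq_b, gene_id = NA_character_) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences differ in length", call. = FALSE)
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length is not a multiple of three", call. = FALSE)
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)

  gap_a <- grepl("-", ca, fixed = TRUE)
  gap_b <- grepl("-", cb, fixed = TRUE)
  partial <- (gap_a & ca != "---") | (gap_b & cb != "---")
  if (any(partial))
    stop("gaps are not codon-aligned (partial-gap codon at column ",
         which(partial)[1L], ")", call. = FALSE)
  gap <- gap_a | gap_b

  tab <- codon_tables()
  ia <- match(ca, tab$sense)
  ib <- match(cb, tab$sense)
  is_stop <- (!gap) & ((ca %in% names(tab$aa_of)[tab$aa_of == "*"]) |
                       (cb %in% names(tab$aa_of)[tab$aa_of == "*"]))
  ambig <- (!gap) & (!is_stop) & (is.na(ia) | is.na(ib))
  usable <- !gap & !is_stop & !ambig

  blocked <- logical(length(ca))
  blocked[usable] <- tab$blocked[cbind(ia[usable], ib[usable])]
  cmp <- usable & !blocked

  skipped <- c(gap = sum(gap), ambiguous = sum(ambig), stop = sum(is_stop),
               pathway_blocked = sum(blocked))
  if (!any(cmp))
    stop("zero comparable codon columns", call. = FALSE)

  s_a <- tab$s_sites[ia[cmp]]
  s_b <- tab$s_sites[ib[cmp]]
  S_sites <- (sum(s_a) + sum(s_b)) / 2
  N_sites <- 3 * sum(cmp) - S_sites
  Sd <- sum(tab$sd_mat[cbind(ia[cmp], ib[cmp])])
  Nd <- sum(tab$nd_mat[cbind(ia[cmp], ib[cmp])])

  pS <- if (S_sites > 0) Sd / S_sites else 0
  pN <- if (N_sites > 0) Nd / N_sites else 0
  if (pS >= 0.75 || pN >= 0.75)
    stop("Jukes-Cantor correction undefined (saturation)", call. = FALSE)
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  flags <- character(0)
  omega <- if (dS > 0) dN / dS else {
    flags <- c(flags, "omega_undefined")
    NA_real_
  }
  structure(list(
    gene_id = gene_id, n_codons_compared = sum(cmp),
    S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
    pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
    skipped = skipped, flags = flags
  ), class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate>%s %d codons compared\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              x$n_codons_compared))
  cat(sprintf("  dN = %.4f  dS = %.4f  dN/dS = %s\n", x$dN, x$dS,
              if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega)))
  cat(sprintf("  S sites %.2f, N sites %.2f; Sd %.2f, Nd %.2f\n",
              x$S_sites, x$N_sites, x$Sd, x$Nd))
  if (any(x$skipped > 0))
    cat("  skipped columns:",
        paste(sprintf("%s %d", names(x$skipped), x$skipped)[x$skipped > 0],
              collapse = ", "), "\n")
  invisible(x)
}

#' Estimate divergence for a batch of aligned pairs
#'
#' Per-pair failures (saturation, no comparable columns) do not abort the
#' batch; they surface as flagged rows with missing estimates. Undefined
#' omegas are emitted as `NA`, never 0.
#'
#' @param pairs A data frame with columns `gene_id`, `seq_a`, `seq_b`
#'   (e.g. from [read_pair_fasta()]).
#' @return A data frame with one row per pair: gene_id, n_codons_compared,
#'   S_sites, N_sites, Sd, Nd, pS, pN, dS, dN, omega, n_skipped, flags.
#' @export
batch_divergence <- function(pairs) {
  cols <- c("gene_id", "n_codons_compared", "S_sites", "N_sites", "Sd", "Nd",
            "pS", "pN", "dS", "dN", "omega", "n_skipped", "flags")
  if (!nrow(pairs)) {
    out <- data.frame(gene_id = character(0), n_codons_compared = integer(0),
                      S_sites = numeric(0), N_sites = numeric(0),
                      Sd = numeric(0), Nd = numeric(0), pS = numeric(0),
                      pN = numeric(0), dS = numeric(0), dN = numeric(0),
                      omega = numeric(0), n_skipped = integer(0),
                      flags = character(0))
    return(out)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    est <- tryCatch(
      estimate_divergence(pairs$seq_a[i], pairs$seq_b[i], pairs$gene_id[i]),
      error = function(e) e)
    if (inherits(est, "error")) {
      data.frame(gene_id = pairs$gene_id[i], n_codons_compared = NA_integer_,
                 S_sites = NA_real_, N_sites = NA_real_, Sd = NA_real_,
                 Nd = NA_real_, pS = NA_real_, pN = NA_real_, dS = NA_real_,
                 dN = NA_real_, omega = NA_real_, n_skipped = NA_integer_,
                 flags = paste0("error:", conditionMessage(est)))
    } else {
      data.frame(gene_id = est$gene_id, n_codons_compared = est$n_codons_compared,
                 S_sites = est$S_sites, N_sites = est$N_sites, Sd = est$Sd,
                 Nd = est$Nd, pS = est$pS, pN = est$pN, dS = est$dS,
                 dN = est$dN, omega = est$omega,
                 n_skipped = sum(est$skipped),
                 flags = paste(est$flags, collapse = ","))
    }
  })
  do.call(rbind, rows)
}

#' Read a paired FASTA of aligned ortholog CDS pairs
#'
#' Expects two records per gene with ids `<gene>|a` and `<gene>|b`.
#'
#' @param path Path to the paired FASTA.
#' @return Data frame with columns `gene_id`, `seq_a`, `seq_b`.
#' @export
read_pair_fasta <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  side <- sub("^.*\\|", "", ids)
  gene <- sub("\\|[ab]$", "", ids)
  if (!all(side %in% c("a", "b")))
    stop("pair FASTA ids must end in '|a' or '|b'", call. = FALSE)
  genes <- unique(gene)
  a <- seqs[match(paste0(genes, "|a"), ids)]
  b <- seqs[match(paste0(genes, "|b"), ids)]
  if (anyNA(a) || anyNA(b))
    stop("pair FASTA is missing one side for gene(s): ",
         paste(genes[is.na(a) | is.na(b)], collapse = ", "), call. = FALSE)
  data.frame(gene_id = genes, seq_a = unname(a), seq_b = unname(b))
}
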