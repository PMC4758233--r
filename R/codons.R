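# Standard nuclear genetic code machinery shared by the divergence and
# codon-usage modules. All tables are derived from Biostrings::GENETIC_CODE
# once per session and cached; only the standard code is supported.

.rh_cache <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE
codon_tables <- function() {
  if (!is.null(.rh_cache$tab)) return(.rh_cache$tab)

  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  sense_idx <- which(aa != "*")
  sense <- codons[sense_idx]
  aa_sense <- aa[sense_idx]
  nts <- c("A", "C", "G", "T")
  cod_mat <- do.call(rbind, strsplit(sense, ""))
  aa_of <- stats::setNames(aa, codons)

  n_sense <- length(sense)  # 61
  s_sites <- numeric(n_sense)
  syn_nb <- vector("list", n_sense)
  nonsyn_nb <- vector("list", n_sense)

  for (i in seq_len(n_sense)) {
    s <- 0
    sn <- character(0)
    nn <- character(0)
    for (pos in 1:3) {
      syn_k <- 0L
      sense_k <- 0L
      for (nt in setdiff(nts, cod_mat[i, pos])) {
        nb <- cod_mat[i, ]
        nb[pos] <- nt
        nb <- paste(nb, collapse = "")
        if (aa_of[[nb]] == "*") next   # stop neighbours excluded from the denominator
        sense_k <- sense_k + 1L
        if (aa_of[[nb]] == aa_sense[i]) {
          syn_k <- syn_k + 1L
          sn <- c(sn, nb)
        } else {
          nn <- c(nn, nb)
        }
      }
      if (sense_k > 0L) s <- s + syn_k / sense_k
    }
    s_sites[i] <- s
    syn_nb[[i]] <- match(sn, sense)
    nonsyn_nb[[i]] <- match(nn, sense)
  }

  # Pathway-averaged difference counts for every ordered sense-codon pair:
  # enumerate all orderings of the differing positions, drop orderings that
  # pass through a stop codon, average synonymous/nonsynonymous step counts.
  perms <- list(
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  sd_mat <- matrix(0, n_sense, n_sense)
  nd_mat <- matrix(0, n_sense, n_sense)
  blocked <- matrix(FALSE, n_sense, n_sense)

  for (i in seq_len(n_sense)) {
    for (j in seq_len(n_sense)) {
      if (j <= i) next
      dpos <- which(cod_mat[i, ] != cod_mat[j, ])
      k <- length(dpos)
      if (k == 0L) next
      sd_tot <- 0
      nd_tot <- 0
      n_ok <- 0L
      for (ord in perms[[k]]) {
        cur <- cod_mat[i, ]
        sd_p <- 0L
        nd_p <- 0L
        ok <- TRUE
        for (pos in dpos[ord]) {
          from_aa <- aa_of[[paste(cur, collapse = "")]]
          cur[pos] <- cod_mat[j, pos]
          to_aa <- aa_of[[paste(cur, collapse = "")]]
          if (to_aa == "*") { ok <- FALSE; break }
          if (to_aa == from_aa) sd_p <- sd_p + 1L else nd_p <- nd_p + 1L
        }
        if (ok) {
          sd_tot <- sd_tot + sd_p
          nd_tot <- nd_tot + nd_p
          n_ok <- n_ok + 1L
        }
      }
      if (n_ok == 0L) {
        blocked[i, j] <- blocked[j, i] <- TRUE
        sd_mat[i, j] <- sd_mat[j, i] <- NA_real_
        nd_mat[i, j] <- nd_mat[j, i] <- NA_real_
      } else {
        sd_mat[i, j] <- sd_mat[j, i] <- sd_tot / n_ok
        nd_mat[i, j] <- nd_mat[j, i] <- nd_tot / n_ok
      }
    }
  }

  # third-position G/C indicator and per-amino-acid codon families,
  # used by the codon-usage (GC3/ENc) and simulation modules
  gc3_flag <- cod_mat[, 3] %in% c("G", "C")
  fam <- split(seq_len(n_sense), aa_sense)

  .rh_cache$tab <- list(
    codons = codons, aa_of = aa_of,
    sense = sense, aa_sense = aa_sense,
    s_sites = s_sites, n_sites = 3 - s_sites,
    syn_nb = syn_nb, nonsyn_nb = nonsyn_nb,
    sd_mat = sd_mat, nd_mat = nd_mat, blocked = blocked,
    gc3_flag = gc3_flag, fam = fam
  )
  .rh_cache$tab
}

check_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop(sprintf("'%s' must be a single 3-mer", arg), call. = FALSE)
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon))
    stop(sprintf("'%s' contains a base outside {A,C,G,T}: %s", arg, codon),
         call. = FALSE)
  tab <- codon_tables()
  if (tab$aa_of[[codon]] == "*")
    stop(sprintf("'%s' is a stop codon: %s", arg, codon), call. = FALSE)
  codon
}

#' Expected synonymous and nonsynonymous sites of a codon
#'
#' Nei-Gojobori (1986) site counting for a single sense codon of the
#' standard nuclear code. At each of the three positions the fraction of
#' single-nucleotide changes that are synonymous is computed, counting only
#' changes to sense codons in the denominator; the synonymous site count
#' `s` is the sum over positions and `n = 3 - s`.
#'
#' @param codon A single sense codon (3-character string over A/C/G/T).
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n == 3`.
#' @examples
#' codon_site_counts("GGG")  # 4-fold third position: s = 1
#' codon_site_counts("ATG")  # Met: s = 0
#' @export
codon_site_counts <- function(codon) {
  codon <- check_codon(codon)
  tab <- codon_tables()
  s <- tab$s_sites[match(codon, tab$sense)]
  c(s = s, n = 3 - s)
}

#' Pathway-averaged synonymous and nonsynonymous differences between codons
#'
#' For two sense codons differing at `k` positions, all `k!` orderings of the
#' single-nucleotide changes are enumerated; orderings passing through a stop
#' codon are discarded and synonymous/nonsynonymous step counts are averaged
#' over the remaining pathways (classic Nei-Gojobori equal weighting).
#'
#' @param codon_a,codon_b Sense codons (3-character strings over A/C/G/T).
#' @return A list with elements `sd`, `nd` (averaged counts, `sd + nd`
#'   equals the number of differing positions when a legal pathway exists)
#'   and `n_paths` (number of stop-free pathways). When every pathway passes
#'   through a stop codon, `sd` and `nd` are `NA` and `n_paths` is 0.
#' @examples
#' codon_differences("GGG", "GGC")  # synonymous third-position change
#' codon_differences("TTT", "GTA")  # two changes, two pathways averaged
#' @export
codon_differences <- function(codon_a, codon_b) {
  codon_a <- check_codon(codon_a, "codon_a")
  codon_b <- check_codon(codon_b, "codon_b")
  tab <- codon_tables()
  i <- match(codon_a, tab$sense)
  j <- match(codon_b, tab$sense)
  if (tab$blocked[i, j])
    return(list(sd = NA_real_, nd = NA_real_, n_paths = 0L))
  k <- sum(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  n_paths <- if (k == 0L) 1L else {
    tot <- factorial(k)
    # recount legal pathways for reporting
    if (is.na(tab$sd_mat[i, j])) 0L else tot  # placeholder, refined below
  }
  # exact legal-path count is not stored; recompute cheaply for k <= 3
  n_paths <- count_legal_paths(codon_a, codon_b, tab)
  list(sd = tab$sd_mat[i, j], nd = tab$nd_mat[i, j], n_paths = n_paths)
}

count_legal_paths <- function(codon_a, codon_b, tab) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  dpos <- which(a != b)
  k <- length(dpos)
  if (k == 0L) return(1L)
  perms <- switch(k,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  n_ok <- 0L
  for (ord in perms) {
    cur <- a
    ok <- TRUE
    for (pos in dpos[ord]) {
      cur[pos] <- b[pos]
      if (tab$aa_of[[paste(cur, collapse = "")]] == "*") { ok <- FALSE; break }
    }
    if (ok) n_ok <- n_ok + 1L
  }
  n_ok
}

# split a nucleotide string into codons
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

# reverse complement for plain uppercase A/C/G/T/N strings
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}
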