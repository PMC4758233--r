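# Independent brute-force oracles used to check the package's estimators.
# They re-derive everything from the genetic code with different code paths
# than the implementation (recursive enumeration, direct formulas).

GC_TABLE <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) unname(GC_TABLE[codon])

# NG86 site counts by direct neighbour enumeration
oracle_site_counts <- function(codon) {
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    sense <- 0
    for (nt in nts[nts != ch[pos]]) {
      nb <- ch
      nb[pos] <- nt
      nb <- paste(nb, collapse = "")
      if (oracle_translate(nb) == "*") next
      sense <- sense + 1
      if (oracle_translate(nb) == oracle_translate(codon)) syn <- syn + 1
    }
    if (sense > 0) s <- s + syn / sense
  }
  c(s = s, n = 3 - s)
}

# pathway enumeration by depth-first recursion over remaining positions
oracle_differences <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  dpos <- which(ca != cb)
  paths <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      nxt_str <- paste(nxt, collapse = "")
      if (oracle_translate(nxt_str) == "*") next
      syn <- oracle_translate(paste(cur, collapse = "")) ==
        oracle_translate(nxt_str)
      walk(nxt, setdiff(remaining, pos), sd + as.integer(syn),
           nd + as.integer(!syn))
    }
  }
  walk(ca, dpos, 0L, 0L)
  if (!length(paths)) return(list(sd = NA_real_, nd = NA_real_, n_paths = 0L))
  m <- do.call(rbind, paths)
  list(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]), n_paths = nrow(m))
}

# full NG86 + Jukes-Cantor estimate assembled codon-by-codon from the two
# oracles above
oracle_estimate <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n - 2, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n - 2, 3), seq(3, n, 3))
  S <- 0; Sd <- 0; Nd <- 0; ncod <- 0
  for (k in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[k]) || grepl("[^ACGT]", cb[k])) next
    if (oracle_translate(ca[k]) == "*" || oracle_translate(cb[k]) == "*") next
    d <- oracle_differences(ca[k], cb[k])
    if (d$n_paths == 0L) next
    S <- S + (oracle_site_counts(ca[k])["s"] + oracle_site_counts(cb[k])["s"]) / 2
    Sd <- Sd + d$sd
    Nd <- Nd + d$nd
    ncod <- ncod + 1
  }
  N <- 3 * ncod - S
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S_sites = unname(S), N_sites = unname(N), Sd = Sd, Nd = Nd,
       pS = unname(pS), pN = unname(pN), dS = unname(jc(pS)),
       dN = unname(jc(pN)), n_codons = ncod)
}

# Wright's ENc by direct per-family formula from a codon-count table
oracle_enc <- function(cds_seq) {
  n <- nchar(cds_seq)
  cods <- substring(cds_seq, seq(1, n - 2, 3), seq(3, n, 3))
  cods <- cods[-length(cods)]
  aa <- vapply(cods, oracle_translate, character(1))
  fam_of <- split(cods, aa)
  sizes <- table(GC_TABLE[GC_TABLE != "*"])
  Fk <- list()
  for (a in names(fam_of)) {
    k <- as.integer(sizes[[a]])
    if (k == 1L) next
    cnt <- table(fam_of[[a]])
    nn <- sum(cnt)
    if (nn < 2L) next
    p <- as.numeric(cnt) / nn
    Fk[[a]] <- c(size = k, F = (nn * sum(p^2) - 1) / (nn - 1))
  }
  m <- do.call(rbind, Fk)
  Fbar <- function(k) mean(m[m[, "size"] == k, "F"])
  F2 <- Fbar(2); F3 <- Fbar(3); F4 <- Fbar(4); F6 <- Fbar(6)
  if (is.nan(F3)) F3 <- (F2 + F4) / 2
  min(61, max(20, 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6))
}

# exact two-sided Mann-Whitney p by enumeration of all labelings
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  mid <- n1 * (length(y)) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mid) >= abs(obs - mid))
}

oracle_two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

# tau evaluated directly in an arbitrary log base
oracle_tau <- function(values, base) {
  v <- pmax(values, 1)
  smax <- max(v)
  sum(1 - log(v, base) / log(smax, base)) / (length(v) - 1)
}

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  paste(c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA"),
        collapse = "")
}
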