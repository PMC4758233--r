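# Synthetic-data generator: self-contained ortholog-pair, gene-model,
# expression and annotation bundles with the statistical structure the
# class-comparison analysis assumes. Class-level defaults are the observed
# reference conditions for plant primary/secondary metabolic gene classes;
# all randomness flows from one seed recorded in the bundle manifest.

#' Default simulation configuration
#'
#' Per-class targets default to the magnitudes observed for primary and
#' secondary metabolic pathway genes in an *A. thaliana* / *A. lyrata*
#' ortholog comparison: divergence
#' means/SDs (dN 0.02/0.016 vs 0.026/0.016; dS 0.147/0.044 vs 0.157/0.043),
#' UTR lengths (128.6/96.5 and 231.1/192.9 nt), intron numbers (6.17/4.30),
#' UTR GC (0.3427/0.31 and 0.2958/0.2742), GC3 (0.412/0.423), expression
#' level (9025.8/4430.3), tissue specificity tau (0.236/0.287) and Poisson
#' means for domain (1.53/1.26), GO-slim (12.95/10.91) and PO (28.25/22.48)
#' counts, with 1035 primary and 241 secondary genes. In each per-class
#' pair the first element is the primary class. Quantities without an
#' observed reference value (length and count distribution shapes,
#' codon-usage bias strength realizing the ENc contrast, tissue number)
#' carry realistic fixed defaults documented in the package vignette.
#'
#' @param n_primary,n_secondary Gene counts per class.
#' @param seed Integer seed recorded in the bundle manifest.
#' @param ... Overrides for any default listed below.
#' @return A named list (class `sim_config`).
#' @export
sim_config <- function(n_primary = 1035, n_secondary = 241, seed = 1, ...) {
  cfg <- list(
    n_primary = n_primary, n_secondary = n_secondary, seed = seed,
    classes = c("primary", "secondary"),
    dn_mean = c(primary = 0.02, secondary = 0.026),
    dn_sd = c(primary = 0.016, secondary = 0.016),
    ds_mean = c(primary = 0.147, secondary = 0.157),
    ds_sd = c(primary = 0.044, secondary = 0.043),
    cds_median_codons = 400, cds_sdlog = 0.35, cds_min_codons = 60,
    utr5_mean = c(primary = 128.6, secondary = 96.49),
    utr3_mean = c(primary = 231.06, secondary = 192.87),
    utr_sdlog = 0.6, utr_absent_frac = 0.05,
    intron_mean = c(primary = 6.17, secondary = 4.30),
    intron_size = 0.8,
    intron_len_median = 180, intron_len_sdlog = 0.6, intron_len_min = 30,
    gc_utr5 = c(primary = 0.3427, secondary = 0.31),
    gc_utr3 = c(primary = 0.2958, secondary = 0.2742),
    gc_utr_sd = 0.05, gc_intron = 0.32,
    gc3_mean = c(primary = 0.412, secondary = 0.423),
    gc3_sd = 0.05, gc3_intronless_shift = 0.05,
    enc_bias = c(primary = 0.24, secondary = 0.24),
    expr_mean = c(primary = 9025.77, secondary = 4430.29),
    expr_sdlog = 1.0, expr_missing_frac = 0.03,
    tau_mean = c(primary = 0.236, secondary = 0.287),
    tau_conc = 8, n_tissues = 20, expr_noise_sd = 0.15,
    domain_lambda = c(primary = 1.53, secondary = 1.26),
    go_lambda = c(primary = 12.95, secondary = 10.91),
    po_lambda = c(primary = 28.25, secondary = 22.48),
    isoform_frac = 0.15, qc_fail_frac = 0.02, minus_strand_frac = 0.5
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  stopifnot(cfg$n_primary > 0, cfg$n_secondary > 0,
            all(cfg$dn_mean > 0 & cfg$dn_mean < 0.75),
            all(cfg$ds_mean > 0 & cfg$ds_mean < 0.75))
  structure(cfg, class = "sim_config")
}

random_seq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Codon sampling weights over the 61 sense codons: a within-family bias
# component (interpolating uniform usage toward one preferred codon per
# family, which lowers ENc) times r^gc3, with r solved so the expected
# third-position GC under uniform amino-acid usage hits the target.
codon_weights <- function(gc3_target, bias) {
  tab <- codon_tables()
  bias <- min(bias, 0.999)   # keep every codon reachable
  base <- numeric(length(tab$sense))
  for (members in tab$fam) {
    m <- length(members)
    pref <- members[1L]
    base[members] <- 1 - bias
    base[pref] <- (1 - bias) + bias * m
  }
  g <- as.numeric(tab$gc3_flag)
  expected_gc3 <- function(logr) {
    r <- exp(logr)
    w <- base * r^g
    mean(vapply(tab$fam, function(members) {
      sum(w[members] * g[members]) / sum(w[members])
    }, numeric(1)))
  }
  # clamp the target into the range achievable under these bias weights
  lo <- expected_gc3(-15)
  hi <- expected_gc3(15)
  target <- min(max(gc3_target, lo + 1e-6), hi - 1e-6)
  logr <- stats::uniroot(function(lr) expected_gc3(lr) - target,
                         lower = -15, upper = 15, tol = 1e-6)$root
  base * exp(logr)^g
}

#' Simulate a quality-conforming coding sequence
#'
#' Draws amino acids uniformly and codons within each family from weights
#' that realize a target third-position GC content and a codon-usage bias
#' level, prepends ATG and appends a stop codon. The realized GC3 is within
#' about 0.05 of the target for sequences of 300 codons or more.
#'
#' @param length_codons Total codon count including start and stop
#'   (minimum 10).
#' @param gc3_target Target GC3 in \[0, 1\].
#' @param bias Within-family codon-usage bias in \[0, 1\]: 0 is uniform
#'   usage within families (high ENc), 1 concentrates each family on one
#'   codon (low ENc).
#' @return A CDS string passing [validate_cds()], with no internal stops.
#' @export
simulate_cds <- function(length_codons, gc3_target, bias = 0) {
  if (gc3_target < 0 || gc3_target > 1)
    stop("gc3_target must be in [0, 1]", call. = FALSE)
  if (length_codons < 10L)
    stop("length_codons must be at least 10", call. = FALSE)
  tab <- codon_tables()
  w <- codon_weights(gc3_target, bias)
  n_body <- length_codons - 2L
  fam_names <- names(tab$fam)
  aa_draw <- sample(fam_names, n_body, replace = TRUE)
  body <- character(n_body)
  for (f in fam_names) {
    pos <- which(aa_draw == f)
    if (!length(pos)) next
    members <- tab$fam[[f]]
    body[pos] <- tab$sense[members[sample.int(
      length(members), length(pos), replace = TRUE, prob = w[members])]]
  }
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste(c("ATG", body, stop_codon), collapse = "")
}

#' Evolve an aligned ortholog pair from an ancestral CDS
#'
#' Two descendant sequences are produced by independent per-codon Bernoulli
#' substitutions, each lineage receiving half the divergence. Substitution
#' probabilities are calibrated in the estimator's own currency: the target
#' dS and dN are inverted through the Jukes-Cantor correction to expected
#' difference proportions, and each codon's synonymous (nonsynonymous)
#' substitution probability is that proportion times its Nei-Gojobori
#' synonymous (nonsynonymous) site count. Substitutions are drawn uniformly
#' from the codon's single-nucleotide sense neighbours, so no stop codons
#' are ever introduced and the pair stays gap-free and in frame. The start
#' codon is held fixed, as in real ortholog pairs.
#'
#' @param ancestor_cds A CDS passing [validate_cds()], at least 10 codons.
#' @param target_dS,target_dN Divergence targets in \[0, 0.7).
#' @return List with `seq_a` and `seq_b`, equal-length CDS strings.
#' @export
evolve_pair <- function(ancestor_cds, target_dS, target_dN) {
  if (target_dS < 0 || target_dS >= 0.7 || target_dN < 0 || target_dN >= 0.7)
    stop("divergence targets must be in [0, 0.7)", call. = FALSE)
  tab <- codon_tables()
  cod <- split_codons(toupper(ancestor_cds))
  if (length(cod) < 10L)
    stop("ancestor too short for the requested divergence", call. = FALSE)
  last <- cod[length(cod)]
  idx <- match(cod[-length(cod)], tab$sense)
  if (anyNA(idx))
    stop("ancestor contains internal stop or ambiguous codons", call. = FALSE)

  inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  pS <- inv_jc(target_dS)
  pN <- inv_jc(target_dN)

  mutate_lineage <- function(idx) {
    q_s <- pS * tab$s_sites[idx] / 2
    q_n <- pN * tab$n_sites[idx] / 2
    # the start codon is conserved, as in real ortholog pairs
    q_s[1L] <- 0
    q_n[1L] <- 0
    hit_s <- which(stats::runif(length(idx)) < q_s)
    for (i in hit_s) {
      nb <- tab$syn_nb[[idx[i]]]
      if (length(nb)) idx[i] <- nb[sample.int(length(nb), 1L)]
    }
    hit_n <- which(stats::runif(length(idx)) < q_n)
    for (i in hit_n) {
      nb <- tab$nonsyn_nb[[idx[i]]]
      if (length(nb)) idx[i] <- nb[sample.int(length(nb), 1L)]
    }
    idx
  }
  a <- mutate_lineage(idx)
  b <- mutate_lineage(idx)
  list(seq_a = paste(c(tab$sense[a], last), collapse = ""),
       seq_b = paste(c(tab$sense[b], last), collapse = ""))
}

#' Simulate a tissue-expression profile with target tau and mean level
#'
#' One tissue carries the maximum `M`, the remaining tissues sit at
#' `M^(1 - tau_target)` (so the exact tau of the noise-free profile equals
#' the target), and `M` is solved numerically so the profile mean matches
#' `level_target`. Mild lognormal jitter is applied to the non-maximum
#' tissues; at 20 tissues the realized tau stays within about 0.05 of the
#' target.
#'
#' @param n_tissues Number of tissues (>= 2).
#' @param tau_target Target tau in \[0, 1\].
#' @param level_target Target mean expression (> 1).
#' @param noise_sd Lognormal jitter SD on non-maximum tissues.
#' @return Numeric vector of length `n_tissues`.
#' @export
simulate_expression <- function(n_tissues, tau_target, level_target,
                                noise_sd = 0.15) {
  if (n_tissues < 2L) stop("need at least 2 tissues", call. = FALSE)
  if (tau_target < 0 || tau_target > 1)
    stop("tau_target must be in [0, 1]", call. = FALSE)
  if (level_target <= 1)
    stop("level_target must exceed the expression floor of 1", call. = FALSE)
  n <- n_tissues
  if (tau_target < 1e-9) {
    v <- rep(level_target, n)
  } else if (tau_target > 1 - 1e-9) {
    v <- c(n * level_target - (n - 1), rep(1, n - 1))
  } else {
    f <- function(logM) {
      M <- exp(logM)
      (M + (n - 1) * M^(1 - tau_target)) / n - level_target
    }
    M <- exp(stats::uniroot(f, lower = log(level_target * (1 + 1e-9)),
                            upper = log(n * level_target), tol = 1e-9)$root)
    rest <- M^(1 - tau_target)
    if (noise_sd > 0) {
      rest <- rest * exp(stats::rnorm(n - 1, 0, noise_sd))
      rest <- pmin(pmax(rest, 1), M * 0.999)
    }
    v <- c(M, rest)
  }
  v[sample.int(n)]
}

# map a transcript-coordinate range to genomic segments given exon tables
tx_range_to_genomic <- function(lo, hi, ex_tx, ex_gen) {
  segs <- list()
  for (k in seq_len(nrow(ex_tx))) {
    a <- max(lo, ex_tx$start[k])
    b <- min(hi, ex_tx$end[k])
    if (a > b) next
    off <- ex_gen$start[k] - ex_tx$start[k]
    segs[[length(segs) + 1L]] <- c(a + off, b + off)
  }
  out <- do.call(rbind, segs)
  seg_df(out[, 1L], out[, 2L])
}

flip_segs <- function(segs, L) {
  if (!nrow(segs)) return(segs)
  out <- seg_df(L - segs$end + 1L, L - segs$start + 1L)
  out[order(out$start), , drop = FALSE]
}

#' Simulate a complete, cross-consistent analysis bundle
#'
#' Writes every file the pipeline reads: a per-gene scaffold genome FASTA
#' and matching GFF3 gene models (mixed strands, a fraction with a second,
#' shorter isoform, and a small fraction with injected CDS quality
#' failures), a CDS FASTA, an aligned ortholog-pair FASTA, an expression
#' matrix, domain/GO-slim/PO annotation tables, the gene class map and a
#' manifest recording the configuration and seed. Class differences are
#' realized in the reference directions: the secondary class has higher dN,
#' dS, dN/dS, ENc, tau and GC3, the primary class greater gene and UTR
#' length, more introns, domains, GO-slim and PO terms and higher
#' expression.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The [bundle_config()] list for `dir`, invisibly.
#' @export
simulate_study <- function(config = sim_config(), dir) {
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  genome <- list()
  models <- list()
  cds_fa <- list()
  pairs_fa <- list()
  expr_rows <- list()
  dom_gene <- list(); dom_id <- list()
  go_gene <- list(); go_id <- list()
  po_gene <- list(); po_id <- list()
  class_gene <- character(0)
  class_label <- character(0)

  go_pool <- sprintf("GO:%07d", seq_len(200))
  po_pool <- sprintf("PO:%07d", seq_len(400))
  dom_pool <- sprintf("PF%05d", seq_len(1000))
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))

  for (cl in config$classes) {
    n <- if (cl == "primary") config$n_primary else config$n_secondary
    prefix <- if (cl == "primary") "P" else "S"
    for (i in seq_len(n)) {
      gid <- sprintf("%s%04d", prefix, i)
      class_gene <- c(class_gene, gid)
      class_label <- c(class_label, cl)

      n_codons <- max(config$cds_min_codons,
                      round(stats::rlnorm(1, log(config$cds_median_codons),
                                          config$cds_sdlog)))
      n_int <- stats::rnbinom(1, mu = config$intron_mean[[cl]],
                              size = config$intron_size)
      gc3_t <- stats::rnorm(1, config$gc3_mean[[cl]] +
                              if (n_int == 0) config$gc3_intronless_shift else 0,
                            config$gc3_sd)
      gc3_t <- min(max(gc3_t, 0.15), 0.9)
      g_shape <- function(m, s) (m / s)^2
      g_rate <- function(m, s) m / s^2
      dn_i <- stats::rgamma(1, g_shape(config$dn_mean[[cl]], config$dn_sd[[cl]]),
                            g_rate(config$dn_mean[[cl]], config$dn_sd[[cl]]))
      ds_i <- stats::rgamma(1, g_shape(config$ds_mean[[cl]], config$ds_sd[[cl]]),
                            g_rate(config$ds_mean[[cl]], config$ds_sd[[cl]]))
      dn_i <- min(dn_i, 0.6)
      ds_i <- min(max(ds_i, 1e-4), 0.6)

      anc <- simulate_cds(n_codons, gc3_t, bias = config$enc_bias[[cl]])
      pair <- evolve_pair(anc, ds_i, dn_i)
      seq_a <- pair$seq_a
      seq_b <- pair$seq_b

      if (stats::runif(1) < config$qc_fail_frac) {
        kind <- sample(c("start", "stop"), 1L)
        if (kind == "start") {
          substr(seq_a, 1L, 3L) <- "CTG"
        } else {
          substr(seq_a, nchar(seq_a) - 2L, nchar(seq_a)) <- "GGG"
        }
      }

      u5 <- if (stats::runif(1) < config$utr_absent_frac) 0L else
        max(5L, round(stats::rlnorm(1, log(config$utr5_mean[[cl]]) -
                                      config$utr_sdlog^2 / 2, config$utr_sdlog)))
      u3 <- if (stats::runif(1) < config$utr_absent_frac) 0L else
        max(5L, round(stats::rlnorm(1, log(config$utr3_mean[[cl]]) -
                                      config$utr_sdlog^2 / 2, config$utr_sdlog)))
      gcu5 <- min(max(stats::rnorm(1, config$gc_utr5[[cl]], config$gc_utr_sd),
                      0.1), 0.6)
      gcu3 <- min(max(stats::rnorm(1, config$gc_utr3[[cl]], config$gc_utr_sd),
                      0.1), 0.6)
      utr5_seq <- random_seq(u5, gcu5)
      utr3_seq <- random_seq(u3, gcu3)
      tx <- paste0(utr5_seq, seq_a, utr3_seq)
      Tn <- nchar(tx)

      n_int <- min(n_int, Tn - 1L)
      cuts <- if (n_int > 0L) sort(sample.int(Tn - 1L, n_int)) else integer(0)
      ex_start_tx <- c(1L, cuts + 1L)
      ex_end_tx <- c(cuts, Tn)
      intron_len <- if (n_int > 0L)
        pmax(config$intron_len_min,
             round(stats::rlnorm(n_int, log(config$intron_len_median),
                                 config$intron_len_sdlog))) else integer(0)

      gene_start <- 101L
      ex_start_g <- integer(n_int + 1L)
      ex_end_g <- integer(n_int + 1L)
      gpos <- gene_start
      pieces <- character(0)
      for (k in seq_len(n_int + 1L)) {
        len_k <- ex_end_tx[k] - ex_start_tx[k] + 1L
        ex_start_g[k] <- gpos
        ex_end_g[k] <- gpos + len_k - 1L
        pieces <- c(pieces, substring(tx, ex_start_tx[k], ex_end_tx[k]))
        gpos <- gpos + len_k
        if (k <= n_int) {
          il <- intron_len[k]
          pieces <- c(pieces, paste0("GT", random_seq(il - 4L, config$gc_intron),
                                     "AG"))
          gpos <- gpos + il
        }
      }
      gene_end <- gpos - 1L
      scaf_len <- gene_end + 100L
      scaffold <- paste0(random_seq(100L, 0.35), paste(pieces, collapse = ""),
                         random_seq(100L, 0.35))

      ex_tx <- seg_df(ex_start_tx, ex_end_tx)
      ex_gen <- seg_df(ex_start_g, ex_end_g)
      cds_gen <- tx_range_to_genomic(u5 + 1L, u5 + nchar(seq_a), ex_tx, ex_gen)
      utr5_gen <- if (u5 > 0L) tx_range_to_genomic(1L, u5, ex_tx, ex_gen)
                  else seg_df()
      utr3_gen <- if (u3 > 0L) tx_range_to_genomic(u5 + nchar(seq_a) + 1L, Tn,
                                                   ex_tx, ex_gen) else seg_df()

      strand <- if (stats::runif(1) < config$minus_strand_frac) "-" else "+"
      if (strand == "-") {
        scaffold <- revcomp(scaffold)
        tmp <- scaf_len - gene_end + 1L
        gene_end <- scaf_len - gene_start + 1L
        gene_start <- tmp
        ex_gen <- flip_segs(ex_gen, scaf_len)
        cds_gen <- flip_segs(cds_gen, scaf_len)
        utr5_gen <- flip_segs(utr5_gen, scaf_len)
        utr3_gen <- flip_segs(utr3_gen, scaf_len)
      }

      chrom <- paste0("scaf_", gid)
      genome[[chrom]] <- scaffold
      mdl <- new_gene_model(gid, paste0(gid, ".1"), chrom, gene_start,
                            gene_end, strand, ex_gen, utr5_gen, utr3_gen,
                            cds_gen)
      models[[length(models) + 1L]] <- mdl

      if (stats::runif(1) < config$isoform_frac &&
          nchar(seq_a) >= 3L * ceiling(0.6 * n_codons) + 3L) {
        short_nt <- 3L * floor(0.6 * n_codons)
        cds2 <- tx_range_to_genomic(u5 + 1L, u5 + short_nt, ex_tx, ex_gen)
        if (strand == "-") cds2 <- flip_segs(cds2, scaf_len)
        models[[length(models) + 1L]] <- new_gene_model(
          gid, paste0(gid, ".2"), chrom, gene_start, gene_end, strand,
          ex_gen, seg_df(), seg_df(), cds2)
      }

      cds_fa[[gid]] <- c(paste0(">", gid), seq_a)
      pairs_fa[[gid]] <- c(paste0(">", gid, "|a"), seq_a,
                           paste0(">", gid, "|b"), seq_b)

      if (stats::runif(1) >= config$expr_missing_frac) {
        tau_t <- stats::rbeta(1, config$tau_mean[[cl]] * config$tau_conc,
                              (1 - config$tau_mean[[cl]]) * config$tau_conc)
        lvl <- stats::rlnorm(1, log(config$expr_mean[[cl]]) -
                               config$expr_sdlog^2 / 2, config$expr_sdlog)
        lvl <- max(lvl, 2)
        prof <- simulate_expression(config$n_tissues, tau_t, lvl,
                                    noise_sd = config$expr_noise_sd)
        expr_rows[[gid]] <- prof
      }

      nd <- stats::rpois(1, config$domain_lambda[[cl]])
      if (nd > 0) {
        dom_gene[[gid]] <- rep(gid, nd)
        dom_id[[gid]] <- sample(dom_pool, nd, replace = TRUE)
      }
      ngo <- min(stats::rpois(1, config$go_lambda[[cl]]), length(go_pool))
      if (ngo > 0) {
        go_gene[[gid]] <- rep(gid, ngo)
        go_id[[gid]] <- sample(go_pool, ngo)
      }
      npo <- min(stats::rpois(1, config$po_lambda[[cl]]), length(po_pool))
      if (npo > 0) {
        po_gene[[gid]] <- rep(gid, npo)
        po_id[[gid]] <- sample(po_pool, npo)
      }
    }
  }

  writeLines(unlist(lapply(names(genome), function(ch)
    c(paste0(">", ch), genome[[ch]]))), file.path(dir, "genome.fa"))
  write_gff3(models, file.path(dir, "genes.gff3"))
  writeLines(unlist(cds_fa, use.names = FALSE), file.path(dir, "cds.fa"))
  writeLines(unlist(pairs_fa, use.names = FALSE), file.path(dir, "pairs.fa"))

  em <- do.call(rbind, expr_rows)
  colnames(em) <- tissues
  utils::write.table(
    data.frame(gene_id = names(expr_rows), em, check.names = FALSE),
    file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = unlist(dom_gene, use.names = FALSE),
               domain_id = unlist(dom_id, use.names = FALSE)),
    file.path(dir, "domains.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = unlist(go_gene, use.names = FALSE),
               term_id = unlist(go_id, use.names = FALSE)),
    file.path(dir, "go_slim.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = unlist(po_gene, use.names = FALSE),
               term_id = unlist(po_id, use.names = FALSE)),
    file.path(dir, "po_terms.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = class_gene, class = class_label),
    file.path(dir, "class_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  scalar <- vapply(config, function(v) length(v) == 1L && !is.list(v),
                   logical(1))
  manifest <- c(
    "# synthetic bundle manifest",
    paste0("seed: ", config$seed),
    vapply(names(config)[!scalar & !vapply(config, is.list, logical(1))],
           function(k) paste0(k, ": ", paste(config[[k]], collapse = ", ")),
           character(1)),
    vapply(setdiff(names(config)[scalar], "seed"),
           function(k) paste0(k, ": ", config[[k]]), character(1)))
  writeLines(manifest, file.path(dir, "manifest.txt"))

  invisible(bundle_config(dir))
}
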