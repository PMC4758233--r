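# Small hand-written FASTA/GFF3 fixtures, built in code at test time.

write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A two-gene toy locus: g1 on the plus strand with two exons and UTRs,
# g2 on the minus strand, single exon. Coordinates are 1-based inclusive.
toy_genome <- function() {
  # chr1: 400 nt; g1 occupies 101-250 with exons 101-150 and 171-250
  set.seed(99)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  # place a clean CDS across the two exons: tx = utr5(10) + cds(102) + utr3(18)
  cds <- random_cds(34)  # 102 nt
  tx <- paste0(strrep("ACGTA", 2), cds, strrep("TTGCAA", 3))
  stopifnot(nchar(tx) == 130)
  exon1 <- substr(tx, 1, 50)
  exon2 <- substr(tx, 51, 130)
  chr1 <- paste0(substr(chr1, 1, 100), exon1, substr(chr1, 151, 170), exon2,
                 substr(chr1, 251, 400))
  # chr2: minus-strand single-exon gene at 51-152: genomic slice is the
  # reverse complement of its transcript
  cds2 <- random_cds(34)
  chr2_mid <- rateherit:::revcomp(cds2)
  set.seed(100)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  chr2 <- paste0(pad(50), chr2_mid, pad(80))
  list(chr1 = chr1, chr2 = chr2, g1_cds = cds, g2_cds = cds2)
}

toy_gff3_lines <- function() {
  c("##gff-version 3",
    "chr1\ttest\tgene\t101\t250\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t101\t250\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t101\t150\t.\t+\t.\tParent=g1.t1",
    "chr1\ttest\texon\t171\t250\t.\t+\t.\tParent=g1.t1",
    "chr1\ttest\tfive_prime_UTR\t101\t110\t.\t+\t.\tParent=g1.t1",
    "chr1\ttest\tCDS\t111\t150\t.\t+\t0\tParent=g1.t1",
    "chr1\ttest\tCDS\t171\t232\t.\t+\t2\tParent=g1.t1",
    "chr1\ttest\tthree_prime_UTR\t233\t250\t.\t+\t.\tParent=g1.t1",
    "chr2\ttest\tgene\t51\t152\t.\t-\t.\tID=g2",
    "chr2\ttest\tmRNA\t51\t152\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr2\ttest\texon\t51\t152\t.\t-\t.\tParent=g2.t1",
    "chr2\ttest\tCDS\t51\t152\t.\t-\t0\tParent=g2.t1")
}

small_bundle <- function(n_primary = 30, n_secondary = 15, seed = 7, ...) {
  dir <- file.path(tempfile("bundle"))
  cfg <- sim_config(n_primary = n_primary, n_secondary = n_secondary,
                    seed = seed, ...)
  simulate_study(cfg, dir)
}
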