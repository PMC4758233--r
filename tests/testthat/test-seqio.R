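test_that("read_fasta parses, normalizes case and converts U to T", {
  p <- write_tmp(c(">g1", "ATGAAATAG"), ".fa")
  expect_equal(read_fasta(p), c(g1 = "ATGAAATAG"))
  p2 <- write_tmp(c(">g1 description text", "atgaaauag"), ".fa")
  expect_equal(read_fasta(p2), c(g1 = "ATGAAATAG"))
})

test_that("read_fasta rejects duplicate ids and empty files", {
  p <- write_tmp(c(">g1", "ATG", ">g1", "CCC"), ".fa")
  expect_error(read_fasta(p), "g1")
  p2 <- write_tmp(character(0), ".fa")
  expect_error(read_fasta(p2))
})

test_that("validate_cds enumerates every violated rule", {
  expect_true(validate_cds("ATGAAATAG")$pass)
  expect_equal(validate_cds("ATGAAA")$reasons, "stop")
  expect_equal(validate_cds("ATGAAATAGA")$reasons, c("stop", "frame"))
  expect_setequal(validate_cds("CCCAA")$reasons, c("start", "stop", "frame"))
  expect_error(validate_cds("ATGXXXTAG"), "outside")
})

test_that("GFF3 gene models carry correct structure and sequences", {
  gen <- toy_genome()
  gff <- write_tmp(toy_gff3_lines(), ".gff3")
  models <- read_gff3(gff, genome = c(chr1 = gen$chr1, chr2 = gen$chr2))
  expect_length(models, 2L)
  g1 <- models[[which(vapply(models, `[[`, character(1), "gene_id") == "g1")]]
  # intron of length 20 between exons 101-150 and 171-250
  expect_equal(nrow(g1$exons), 2L)
  expect_equal(g1$exons$start[2] - g1$exons$end[1] - 1L, 20L)
  expect_equal(g1$cds_seq, gen$g1_cds)
  expect_equal(g1$utr5_seq, strrep("ACGTA", 2))
  expect_equal(g1$utr3_seq, strrep("TTGCAA", 3))
  # minus-strand gene: cds_seq is the reverse complement of the genomic slice
  g2 <- models[[which(vapply(models, `[[`, character(1), "gene_id") == "g2")]]
  expect_equal(g2$strand, "-")
  expect_equal(g2$cds_seq, gen$g2_cds)
  expect_equal(g2$gene_seq, gen$g2_cds)
})

test_that("GFF3 round-trips coordinates and strand through write_gff3", {
  gen <- toy_genome()
  gff <- write_tmp(toy_gff3_lines(), ".gff3")
  models <- read_gff3(gff, genome = c(chr1 = gen$chr1, chr2 = gen$chr2))
  out <- tempfile(fileext = ".gff3")
  write_gff3(models, out)
  back <- read_gff3(out, genome = c(chr1 = gen$chr1, chr2 = gen$chr2))
  key <- function(ms) {
    ms <- ms[order(vapply(ms, `[[`, character(1), "isoform_id"))]
    lapply(ms, function(m) m[c("gene_id", "isoform_id", "chrom", "start",
                               "end", "strand", "exons", "utr5_segments",
                               "utr3_segments", "cds_segments", "cds_seq")])
  }
  expect_equal(key(back), key(models))
})

test_that("GFF3 structural errors are reported with context", {
  bad <- c("##gff-version 3",
           "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
           "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=NOSUCH")
  expect_error(read_gff3(write_tmp(bad, ".gff3")), "NOSUCH")
  mal <- c("##gff-version 3",
           "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
           "chr1\ttest\tmRNA\t1\t100\t.\t+")
  expect_error(read_gff3(write_tmp(mal, ".gff3")), "line 3")
})

test_that("longest-isoform selection is by CDS length with lexicographic ties", {
  mk <- function(iso, len) {
    new_gm <- rateherit:::new_gene_model
    new_gm("g", iso, "chr", 1L, 1000L, "+",
           data.frame(start = 1L, end = 1000L),
           data.frame(start = integer(0), end = integer(0)),
           data.frame(start = integer(0), end = integer(0)),
           data.frame(start = 1L, end = len),
           cds_seq = strrep("A", len))
  }
  expect_equal(select_longest_isoform(list(mk("t1", 300L), mk("t2", 450L)))$isoform_id, "t2")
  expect_equal(select_longest_isoform(list(mk("t1", 300L)))$isoform_id, "t1")
  expect_equal(select_longest_isoform(list(mk("t2", 300L), mk("t1", 300L)))$isoform_id, "t1")
  expect_error(select_longest_isoform(list()), "empty")
})

test_that("QC partitions every gene into exactly one of pass or fail", {
  gen <- toy_genome()
  gff <- write_tmp(toy_gff3_lines(), ".gff3")
  models <- read_gff3(gff, genome = c(chr1 = gen$chr1, chr2 = gen$chr2))
  # corrupt the second model's start codon
  models[[2]]$cds_seq <- sub("^ATG", "CTG", models[[2]]$cds_seq)
  qc <- qc_gene_models(models)
  ids <- vapply(models, `[[`, character(1), "gene_id")
  pass_ids <- vapply(qc$pass, `[[`, character(1), "gene_id")
  expect_equal(qc$report$n_input, length(models))
  expect_setequal(c(pass_ids, qc$report$failed_ids), ids)
  expect_length(intersect(pass_ids, qc$report$failed_ids), 0L)
  expect_equal(qc$report$n_fail_start, 1L)
})
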