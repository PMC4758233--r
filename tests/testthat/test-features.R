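mk_model <- function(exons, utr5 = NULL, utr3 = NULL, start = NULL,
                     end = NULL, cds_seq = "ATGAAATAG") {
  ex <- data.frame(start = vapply(exons, `[`, numeric(1), 1),
                   end = vapply(exons, `[`, numeric(1), 2))
  seg <- function(x) if (is.null(x))
    data.frame(start = integer(0), end = integer(0)) else
    data.frame(start = vapply(x, `[`, numeric(1), 1),
               end = vapply(x, `[`, numeric(1), 2))
  rateherit:::new_gene_model(
    "g", "g.1", "chr", as.integer(start %||% min(ex$start)),
    as.integer(end %||% max(ex$end)), "+", ex, seg(utr5), seg(utr3),
    seg(NULL), cds_seq = cds_seq)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("architecture features match hand computations", {
  one <- architecture_features(mk_model(list(c(100, 400))))
  expect_equal(one$gene_length, 301L)
  expect_equal(one$intron_number, 0L)
  expect_true(is.na(one$mean_intron_length))

  three <- architecture_features(
    mk_model(list(c(1, 60), c(101, 160), c(201, 260))))
  expect_equal(three$intron_number, 2L)
  expect_equal(three$mean_intron_length, 40)

  utr <- architecture_features(
    mk_model(list(c(1, 100)), utr5 = list(c(1, 20), c(21, 30))))
  expect_equal(utr$utr5_length, 30L)
})

test_that("architecture is invariant to exon input order and rejects overlap", {
  a <- architecture_features(mk_model(list(c(1, 60), c(101, 160), c(201, 260))))
  b <- architecture_features(mk_model(list(c(201, 260), c(1, 60), c(101, 160))))
  expect_equal(a, b)
  m <- mk_model(list(c(1, 60), c(101, 160)))
  m$exons <- data.frame(start = c(1L, 50L), end = c(60L, 160L))
  expect_error(architecture_features(m), "overlap")
})

test_that("gc_content handles N exclusion and degenerate input", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGNNC"), 2 / 4)  # both Ns excluded
  expect_true(is.na(gc_content("")))
  expect_true(is.na(gc_content("NNN")))
})

test_that("gc3 matches hand counts and is consistent with gc_content", {
  expect_equal(gc3("ATGGCGTAA"), 1)
  expect_equal(gc3("ATGGCATAA"), 0.5)
  expect_equal(gc3("ATGGCAATTTAA"), 1 / 3)
  expect_error(gc3("ATGAAA"), "quality")
  set.seed(13)
  cds <- random_cds(200)
  cods <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  thirds <- paste(substr(cods[-length(cods)], 3, 3), collapse = "")
  expect_equal(gc3(cds), gc_content(thirds))
})

test_that("ENc hits its limits and matches the direct-formula oracle", {
  tab <- rateherit:::codon_tables()
  one_each <- paste0("ATG", paste(rep(vapply(tab$fam, function(m)
    tab$sense[m[1]], character(1)), each = 3), collapse = ""), "TAA")
  expect_equal(enc(one_each), 20)

  set.seed(17)
  unif <- paste0("ATG", paste(sample(tab$sense, 100000, replace = TRUE),
                              collapse = ""), "TAA")
  e <- enc(unif)
  expect_gte(e, 60)
  expect_lte(e, 61)

  for (s in c(2, 3)) {
    cds <- random_cds(600, seed = s)
    expect_equal(enc(cds), oracle_enc(cds), tolerance = 1e-12)
  }
})

test_that("ENc decreases monotonically with codon-usage bias", {
  set.seed(23)
  vals <- vapply(seq(0, 1, length.out = 5), function(b) {
    mean(replicate(8, enc(simulate_cds(500, 0.45, bias = b))))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("domain counting keeps duplicates, term counting collapses them", {
  dom <- data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                    domain_id = c("PF001", "PF002", "PF001", "PF001"))
  expect_equal(count_domains(dom, c("g1", "g2", "g3")),
               c(g1 = 2L, g2 = 2L, g3 = 0L))
  terms <- data.frame(gene_id = c("g1", "g1", "g1"),
                      term_id = c("PO:1", "PO:2", "PO:2"))
  expect_equal(term_count(terms, c("g1", "gX")), c(g1 = 2L, gX = 0L))
})

test_that("domain classes split 1/2/3+ and drop zero-domain proteins", {
  expect_equal(as.character(domain_class(c(1, 2, 7, 0))),
               c("single", "double", "multi", NA))
})
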