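fake_records <- function(n_p = 120, n_s = 60, seed = 55) {
  set.seed(seed)
  n <- n_p + n_s
  cls <- rep(c("primary", "secondary"), c(n_p, n_s))
  sec <- cls == "secondary"
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    class = cls,
    gene_length = round(stats::rlnorm(n, log(2500) - 0.05 * sec, 0.4)),
    utr5_length = round(stats::rlnorm(n, log(120) - 0.2 * sec, 0.5)),
    utr3_length = round(stats::rlnorm(n, log(220) - 0.2 * sec, 0.5)),
    intron_number = stats::rnbinom(n, mu = ifelse(sec, 4.3, 6.2), size = 1),
    mean_intron_length = stats::rlnorm(n, log(180), 0.5),
    gc_gene = stats::rnorm(n, 0.38, 0.03),
    gc_utr5 = stats::rnorm(n, 0.34 - 0.03 * sec, 0.05),
    gc_utr3 = stats::rnorm(n, 0.30 - 0.02 * sec, 0.05),
    gc3 = stats::rnorm(n, 0.41 + 0.01 * sec, 0.05),
    enc = stats::rnorm(n, 53 + 1.3 * sec, 2),
    domain_number = stats::rpois(n, ifelse(sec, 1.26, 1.53)),
    expression_level = stats::rlnorm(n, log(9000) - 0.7 * sec, 1),
    tau = stats::rbeta(n, 2, 6) + 0.05 * sec,
    po_count = stats::rpois(n, ifelse(sec, 22, 28)),
    goslim_count = stats::rpois(n, ifelse(sec, 11, 13)),
    dN = stats::rgamma(n, 1.5, rate = 1.5 / ifelse(sec, 0.026, 0.02)),
    dS = stats::rgamma(n, 11, rate = 11 / ifelse(sec, 0.157, 0.147)),
    stringsAsFactors = FALSE
  ) -> df
  df$omega <- df$dN / df$dS
  df
}

test_that("intron stratification uses the boundaries 0 / 1-10 / >10", {
  rec <- fake_records()
  rec$intron_number <- rep(c(0L, 5L, 10L, 11L), length.out = nrow(rec))
  st <- stratify_by_intron(rec)
  expect_setequal(unique(st$group),
                  c("intronless", "1-10 introns", ">10 introns"))
  # boundary: 10 introns belongs to the middle group, 11 to the last
  mid <- st[st$group == "1-10 introns" & st$variable == "dN", ]
  expect_equal(mid$n_primary + mid$n_secondary,
               sum(rec$intron_number %in% c(5L, 10L)))
  hi <- st[st$group == ">10 introns" & st$variable == "dN", ]
  expect_equal(hi$n_primary + hi$n_secondary, sum(rec$intron_number == 11L))
  expect_true(all(st$p[!is.na(st$p)] >= 0 & st$p[!is.na(st$p)] <= 1))
})

test_that("empty strata are reported with n and skipped tests", {
  rec <- fake_records(20, 10)
  rec$intron_number <- 2L  # nothing intronless, nothing > 10
  st <- stratify_by_intron(rec)
  no <- st[st$group == "intronless", ]
  expect_true(all(no$n_primary == 0))
  expect_true(all(is.na(no$p)))
  mid <- st[st$group == "1-10 introns" & st$variable == "dN", ]
  expect_false(is.na(mid$p))
})

test_that("domain-class proportions are exact and z is 0 for equal splits", {
  rec <- data.frame(
    class = rep(c("primary", "secondary"), each = 10),
    domain_number = c(rep(1, 6), rep(2, 2), rep(5, 2),
                      rep(1, 6), rep(2, 2), rep(5, 2)))
  dc <- domain_class_proportions(rec)
  p <- dc$proportions
  expect_equal(p$pct[p$class == "primary"], c(60, 20, 20))
  expect_equal(dc$tests$z, rep(0, 3))

  all_single <- data.frame(class = rep(c("primary", "secondary"), each = 5),
                           domain_number = 1)
  ps <- domain_class_proportions(all_single)$proportions
  expect_equal(ps$pct[ps$domain_class == "single"], c(100, 100))
})

test_that("zero-domain genes are excluded from domain-class analysis", {
  rec <- data.frame(class = rep("primary", 4), domain_number = c(0, 1, 1, 2))
  rec2 <- rbind(rec, data.frame(class = "secondary", domain_number = c(1, 2)))
  dc <- domain_class_proportions(rec2)
  expect_equal(sum(dc$proportions$n[dc$proportions$class == "primary"]), 3)
})

test_that("a GC3 shift in intronless genes is detected within each class", {
  set.seed(61)
  rec <- data.frame(
    class = rep(c("primary", "secondary"), each = 400),
    intron_number = rep(c(0L, 3L), 400),
    gc3 = stats::rnorm(800, 0.40, 0.05))
  rec$gc3[rec$intron_number == 0] <- rec$gc3[rec$intron_number == 0] + 0.1
  out <- gc3_by_intron_presence(rec)
  expect_true(all(out$p < 0.01))
  expect_true(all(out$median_gc3_intronless > out$median_gc3_with_intron))

  # null: identical distributions, missing gc3 rows dropped
  rec$gc3 <- stats::rnorm(800, 0.40, 0.05)
  rec$gc3[1:20] <- NA
  out0 <- gc3_by_intron_presence(rec)
  expect_equal(out0$n_intronless[out0$class == "primary"] +
                 out0$n_with_intron[out0$class == "primary"],
               sum(rec$class == "primary") - sum(is.na(rec$gc3[rec$class == "primary"])))
  expect_true(all(out0$p > 0.05))
})

test_that("the comparison object carries a consistent analysis surface", {
  rec <- fake_records()
  cmp <- compare_pathway_classes(rec)
  expect_s3_class(cmp, "pathway_comparison")
  expect_equal(sum(cmp$n_genes), nrow(rec))
  rs <- cmp$rate_summary
  expect_true(all(rs$cv[rs$variable == "dN"] > 0))
  expect_true(all(rs$min <= rs$max))
  # every feature row of the correlation table has rho in [-1, 1]
  co <- cmp$correlations
  expect_true(all(abs(co$rho_dN) <= 1, na.rm = TRUE))
  expect_true(all(co$p_dN >= 0 & co$p_dN <= 1, na.rm = TRUE))
  expect_equal(sum(cmp$pca$component_variance_pct), 100, tolerance = 1e-6)
  expect_output(print(cmp), "genes analyzed")
  expect_output(summary(cmp), "Spearman")
})

test_that("report TSV mirrors are written", {
  rec <- fake_records(60, 30)
  cmp <- compare_pathway_classes(rec)
  d <- tempfile("report")
  write_report(cmp, d)
  expect_true(all(file.exists(file.path(
    d, c("table1_rates.tsv", "table2_correlations.tsv", "table3_pca.tsv",
         "intron_strata.tsv", "domain_class_proportions.tsv",
         "gc3_by_intron.tsv")))))
  t1 <- utils::read.delim(file.path(d, "table1_rates.tsv"))
  expect_equal(nrow(t1), 6L)  # 3 rates x 2 classes
})

test_that("the pipeline is deterministic and accounts for every gene", {
  bc <- small_bundle(n_primary = 25, n_secondary = 12, seed = 77)
  res1 <- run_pipeline(bc)
  res2 <- run_pipeline(bc)
  expect_equal(res1$records, res2$records)
  expect_equal(res1$comparison$rate_summary, res2$comparison$rate_summary)

  class_map <- utils::read.delim(bc$class_map_tsv)
  accounted <- c(res1$records$gene_id, res1$exclusions$gene_id)
  expect_setequal(accounted, class_map$gene_id)
  expect_equal(anyDuplicated(accounted), 0L)
})

test_that("pipeline output directory contains the analysis tables", {
  bc <- small_bundle(n_primary = 20, n_secondary = 10, seed = 78)
  d <- tempfile("out")
  res <- run_pipeline(bc, out_dir = d)
  expect_true(all(file.exists(file.path(
    d, c("features.tsv", "divergence.tsv", "qc_report.tsv",
         "stage_counts.tsv", "table1_rates.tsv")))))
  feats <- utils::read.delim(file.path(d, "features.tsv"))
  expect_equal(names(feats)[1:13],
               c("gene_id", "class", "gene_length", "utr5_length",
                 "utr3_length", "intron_number", "mean_intron_length",
                 "gc_gene", "gc_utr5", "gc_utr3", "gc3", "enc",
                 "domain_number"))
})
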