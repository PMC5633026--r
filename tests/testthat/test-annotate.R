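make_dmrs <- function(chrom, start, end, log2fc, q = 1e-10) {
  n <- length(start)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             log2fc = log2fc, p_value = q, q_value = q,
             direction = ifelse(log2fc > 0, "up", "down"),
             dmr_id = sprintf("dmr_%05d", seq_len(n)),
             stringsAsFactors = FALSE)
}

two_gene_models <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(10000L, 40000L), end = c(20000L, 48000L),
                      strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gA", "gB"),
                      start = c(10000L, 15000L, 40000L),
                      end = c(12000L, 20000L, 48000L))
  cds <- data.frame(gene_id = c("gA", "gB"),
                    start = c(10500L, 40500L), end = c(19000L, 47500L))
  build_gene_models(genes, exons, cds)
}

test_that("promoter DMRs produce DMGs and appear in the promoter table", {
  gm <- two_gene_models()
  dmrs <- make_dmrs("chr1", 8500, 9500, log2fc = -1.2)  # upstream2k of gA
  ann <- annotate_dmrs(dmrs, gm)
  expect_equal(ann$dmgs$gene_id, "gA")
  expect_match(ann$dmgs$regions, "upstream2k")
  expect_equal(nrow(ann$promoter_dmrs), 1L)
  expect_equal(ann$promoter_summary$n_total, 1L)
  expect_equal(ann$promoter_summary$n_down, 1L)
  expect_equal(ann$dmr_elements[["dmr_00001"]], "upstream2k")
})

test_that("a DMR spanning two gene spans hits both genes", {
  gm <- two_gene_models()
  # gA downstream2k is [20000,22000); put a second gene's upstream nearby
  gm2 <- two_gene_models()
  gm2$genes$start[2] <- 23000L
  gm2$genes$end[2] <- 31000L
  gm2 <- build_gene_models(gm2$genes,
                           data.frame(gene_id = c("gA", "gB"),
                                      start = c(10000L, 23000L),
                                      end = c(20000L, 31000L)),
                           data.frame(gene_id = c("gA", "gB"),
                                      start = c(10500L, 23500L),
                                      end = c(19000L, 30500L)))
  dmrs <- make_dmrs("chr1", 20500, 21500, log2fc = 2)
  ann <- annotate_dmrs(dmrs, gm2)
  expect_setequal(ann$dmgs$gene_id, c("gA", "gB"))
})

test_that("intronic DMRs get the intron fine label; intergenic stay so", {
  gm <- two_gene_models()
  dmrs <- make_dmrs("chr1", c(12500, 100000), c(13500, 101000),
                    log2fc = c(-1.5, 1.5))
  ann <- annotate_dmrs(dmrs, gm)
  expect_equal(unname(ann$dmr_elements), c("intron", "intergenic"))
  expect_equal(ann$dmgs$gene_id, "gA")
  # DMG references only existing DMR ids that overlap its span
  expect_equal(ann$dmgs$dmr_ids, "dmr_00001")
})

test_that("best DMR per gene is the most significant one", {
  gm <- two_gene_models()
  dmrs <- make_dmrs("chr1", c(11000, 16000), c(11800, 17000),
                    log2fc = c(-1.1, 2.5), q = c(1e-5, 1e-30))
  ann <- annotate_dmrs(dmrs, gm)
  expect_equal(ann$dmgs$n_dmrs, 2L)
  expect_equal(ann$dmgs$best_log2fc, 2.5)
  expect_equal(ann$dmgs$best_q, 1e-30)
})

test_that("2^-ddCt follows the Livak hand arithmetic", {
  ct <- data.frame(
    sample_id = c("t1", "t2", "c1", "c2"),
    group = c("TC", "TC", "CH", "CH"),
    gene_id = "G",
    ct_target = c(22, 22, 24, 24),
    ct_reference = c(20, 20, 20, 20), stringsAsFactors = FALSE)
  res <- ddct_fold_change(ct, "G")
  expect_equal(res$ddct, -2)
  expect_equal(res$fold_change, 4)
  expect_equal(res$log2fc_expression, 2)
  # identical dCt in both groups -> fold change 1
  ct1 <- ct; ct1$ct_target <- 23
  expect_equal(ddct_fold_change(ct1, "G")$fold_change, 1)
  # TC dCt 5 vs CH dCt 4 -> fold change 0.5
  ct2 <- ct; ct2$ct_target <- c(25, 25, 24, 24)
  r2 <- ddct_fold_change(ct2, "G")
  expect_equal(r2$fold_change, 0.5)
  expect_equal(r2$log2fc_expression, -1)
})

test_that("ddCt is invariant to per-sample constant Ct shifts", {
  withr::local_seed(6)
  ct <- data.frame(sample_id = paste0("s", 1:8),
                   group = rep(c("TC", "CH"), each = 4), gene_id = "G",
                   ct_target = runif(8, 18, 30),
                   ct_reference = runif(8, 18, 24),
                   stringsAsFactors = FALSE)
  base <- ddct_fold_change(ct, "G")
  shift <- runif(8, -3, 3)  # e.g. input-amount differences
  ct2 <- ct
  ct2$ct_target <- ct2$ct_target + shift
  ct2$ct_reference <- ct2$ct_reference + shift
  expect_equal(ddct_fold_change(ct2, "G")$fold_change, base$fold_change)
})

test_that("ddCt drops broken samples and rejects empty groups", {
  ct <- data.frame(sample_id = c("t1", "t2", "c1"),
                   group = c("TC", "TC", "CH"), gene_id = "G",
                   ct_target = c(22, 22, 24),
                   ct_reference = c(20, NA, 20), stringsAsFactors = FALSE)
  expect_warning(res <- ddct_fold_change(ct, "G"), "dropping")
  expect_equal(res$n_test, 1L)
  ct_bad <- ct[ct$group == "TC", ]
  expect_error(suppressWarnings(ddct_fold_change(ct_bad, "G")),
               "calibrator")
})

test_that("concordance flags opposite-signed methylation and expression", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     log2fc_expression = c(1.2, -0.8, 2),
                     stringsAsFactors = FALSE)
  dmgs <- data.frame(gene_id = c("g1", "g2", "g4"),
                     best_log2fc = c(-1.5, -1.2, 3),
                     stringsAsFactors = FALSE)
  conc <- concordance_report(expr, dmgs)
  expect_equal(conc$gene_id, c("g1", "g2"))
  expect_equal(conc$concordant, c(TRUE, FALSE))
  expect_equal(attr(conc, "concordant_fraction"), 0.5)
})

test_that("simulated Ct tables encode expression inverse to methylation", {
  fc <- c(geneX = -2, geneY = 1.5)
  ct <- simulate_ct_table(fc, seed = 99)
  for (g in names(fc)) {
    res <- ddct_fold_change(ct, g)
    expect_equal(res$log2fc_expression, -fc[[g]], tolerance = 0.2)
  }
})
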