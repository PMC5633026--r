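test_that("chi-square statistic matches the closed form and chisq.test", {
  res <- chi_square_region_test(30, 10, 100, 100)
  # 200*(30*90 - 70*10)^2 / (100*100*40*160) = 12.5
  expect_equal(res$statistic, 12.5)
  expect_equal(res$p_value, stats::pchisq(12.5, 1, lower.tail = FALSE))
  expect_equal(res$p_value, 4.07e-4, tolerance = 1e-2)
  # independent route: stats::chisq.test on random tables
  withr::local_seed(21)
  for (i in 1:25) {
    lt <- sample(500:5000, 1); lc <- sample(500:5000, 1)
    a <- sample.int(400, 1); c_ <- sample.int(400, 1)
    mine <- chi_square_region_test(a, c_, lt, lc)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(c(a, lt - a, c_, lc - c_), 2,
                               byrow = TRUE), correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, unname(ref$p.value))
  }
})

test_that("chi-square is group-swap symmetric and scales linearly", {
  a <- chi_square_region_test(37, 12, 1000, 1200)
  b <- chi_square_region_test(12, 37, 1200, 1000)
  expect_equal(a$statistic, b$statistic)
  k <- 7
  s <- chi_square_region_test(37 * k, 12 * k, 1000 * k, 1200 * k)
  expect_equal(s$statistic, a$statistic * k)
})

test_that("degenerate tables are flagged with p = 1", {
  res <- chi_square_region_test(0, 0, 100, 100)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$flagged)
  # exactly homogeneous proportions give statistic 0, p = 1
  hom <- chi_square_region_test(30, 30, 100, 100)
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)
  expect_false(hom$flagged)
})

test_that("goodness-of-fit variant tests counts against library ratios", {
  g <- chi_square_region_test(30, 10, 100, 100, method = "goodness_of_fit")
  # expected 20/20: (30-20)^2/20 + (10-20)^2/20 = 10
  expect_equal(g$statistic, 10)
})

test_that("log2 fold change honours normalization and pseudocounts", {
  expect_equal(compute_log2fc(40, 10, 1000, 1000, pseudocount = 0), 2)
  expect_equal(compute_log2fc(10, 10, 1000, 1000, pseudocount = 0), 0)
  # library normalization: same counts, TC library twice as deep
  expect_equal(compute_log2fc(40, 40, 2000, 1000, pseudocount = 0), -1)
  # raw-ratio mode ignores library sizes
  expect_equal(compute_log2fc(40, 40, 2000, 1000, pseudocount = 0,
                              normalize = FALSE), 0)
  # pseudocount guards zero denominators
  expect_true(is.finite(compute_log2fc(40, 0, 1000, 1000)))
})

test_that("bh_fdr reproduces hand computations and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::local_seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:300, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # monotone in p-rank
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("DMR filter applies p, q and fold-change thresholds jointly", {
  tested <- data.frame(
    chrom = "chr1", start = c(0, 1000, 2000, 3000), end = c(500, 1500, 2500, 3500),
    count_tc = 0, count_ch = 0, chi2_stat = 0,
    p_value = c(1e-27, 1e-12, 0.02, 1e-90),
    q_value = c(1.44e-25, 1e-10, 0.03, 4.83e-80),
    log2fc = c(-1.166, 0.9, -3, -2.478),
    stringsAsFactors = FALSE)
  res <- call_dmrs(tested)
  # the two strong negative regions pass; |log2fc| = 0.9 and p = 0.02 fail
  expect_equal(res$summary$n_total, 2L)
  expect_equal(res$dmrs$log2fc, c(-1.166, -2.478))
  expect_equal(res$dmrs$direction, c("down", "down"))
  expect_equal(res$summary$n_up + res$summary$n_down, res$summary$n_total)
  # boundary behaviour: |log2fc| = 1 passes (>=), p = 0.01 fails (<)
  edge <- data.frame(chrom = "chr1", start = c(0, 1000),
                     end = c(500, 1500),
                     p_value = c(1e-5, 0.01), q_value = c(1e-5, 1e-5),
                     log2fc = c(1, 2), stringsAsFactors = FALSE)
  res2 <- call_dmrs(edge)
  expect_equal(res2$summary$n_total, 1L)
  expect_equal(res2$dmrs$log2fc, 1)
  expect_equal(res2$dmrs$direction, "up")
})

test_that("test_regions adjusts q-values jointly across regions", {
  regions <- data.frame(chrom = "chr1",
                        start = c(0L, 1000L, 2000L),
                        end = c(500L, 1500L, 2500L),
                        count_tc = c(100L, 50L, 55L),
                        count_ch = c(30L, 50L, 50L),
                        stringsAsFactors = FALSE)
  tested <- test_regions(regions, lib_tc = 10000L, lib_ch = 10000L)
  expect_equal(tested$q_value, bh_fdr(tested$p_value))
  expect_equal(tested$log2fc[2], compute_log2fc(50, 50, 10000, 10000))
})
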