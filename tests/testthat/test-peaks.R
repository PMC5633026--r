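test_that("a strongly enriched region is called against flat background", {
  withr::local_seed(2)
  cl <- c(chr1 = 200000L)
  # flat background ~ 10 midpoints / 200 bp window, one region at ~10x
  n_bg <- 10000
  bg_start <- sample.int(199000L, n_bg)
  hot_start <- 50000L + sample.int(2000L, 1000, replace = TRUE)
  frags <- make_fragments("chr1", c(bg_start, hot_start),
                          c(bg_start, hot_start) + 250L)
  peaks <- call_peaks_simple(frags, cl)
  expect_gte(nrow(peaks), 1L)
  # the called peak covers the hot region and little else
  hot <- gintervals("chr1", 50000, 52200)
  ov <- sum(overlap_length(peaks, hot[rep(1, nrow(peaks)), ]))
  expect_gt(ov / 2200, 0.9)
  expect_lt(sum(peaks$end - peaks$start), 4000)
  expect_true(all(peaks$read_count > 0))
})

test_that("empty fragment sets yield no peaks", {
  cl <- c(chr1 = 10000L)
  expect_equal(nrow(call_peaks_simple(make_fragments(character(0),
                                                     integer(0),
                                                     integer(0)), cl)), 0L)
})

test_that("nearby enriched windows merge into one peak", {
  withr::local_seed(4)
  cl <- c(chr1 = 100000L)
  bg <- sample.int(99000L, 5000)
  # two hot windows 200 bp apart (gap <= merge_gap)
  hot <- c(rep(20000L, 400) + sample.int(200, 400, replace = TRUE),
           rep(20400L, 400) + sample.int(200, 400, replace = TRUE))
  frags <- make_fragments("chr1", c(bg, hot), c(bg, hot) + 100L)
  peaks <- call_peaks_simple(frags, cl)
  inside <- peaks$start < 20600 & peaks$end > 20000
  expect_equal(sum(inside), 1L)
})

test_that("merge rule follows the >50%-of-shorter-peak criterion", {
  # overlap 60 > 50% of shorter (100) -> merged into the union
  m <- merge_peak_sets(gintervals("chr1", 0, 100),
                       gintervals("chr1", 40, 140))
  expect_equal(m, data.frame(chrom = "chr1", start = 0L, end = 140L,
                             source = "merged", stringsAsFactors = FALSE))
  # overlap 40 <= 50% of shorter (100) -> two unique regions
  m2 <- merge_peak_sets(gintervals("chr1", 0, 100),
                        gintervals("chr1", 60, 300))
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$source, c("TC_unique", "CH_unique"))
  # exactly 50% does not merge (strict rule)
  m3 <- merge_peak_sets(gintervals("chr1", 0, 100),
                        gintervals("chr1", 50, 150))
  expect_equal(nrow(m3), 2L)
  # no overlap anywhere -> unique
  m4 <- merge_peak_sets(gintervals("chr1", 0, 100),
                        gintervals("chr2", 0, 100))
  expect_setequal(m4$source, c("TC_unique", "CH_unique"))
})

test_that("qualifying chains collapse transitively to one region", {
  tc <- gintervals("chr1", c(0, 210), c(200, 410))
  ch <- gintervals("chr1", 90, 320)  # overlaps both TC peaks by 110 > 100
  m <- merge_peak_sets(tc, ch)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 410L)
  expect_equal(m$source, "merged")
})

test_that("merge_peak_sets agrees with the all-pairs oracle", {
  skip_if_not_installed("igraph")
  withr::local_seed(9)
  for (i in 1:40) {
    sets <- random_peak_sets(sample(5:60, 1), sample(5:60, 1))
    got <- suppressWarnings(merge_peak_sets(sets$tc, sets$ch))
    want <- oracle_merge_peak_sets(sets$tc, sets$ch)
    expect_equal(got, want, ignore_attr = TRUE)
    # coverage conservation: union of outputs == union of inputs
    inp <- .rd(rbind(sets$tc, sets$ch))
    outp <- .rd(got[, c("chrom", "start", "end")])
    expect_equal(outp, inp)
  }
})

test_that("count_reads_in_region counts >=1 bp overlaps monotonely", {
  frags <- make_fragments("chr1", c(100, 400, 900), c(300, 600, 1100))
  region <- gintervals("chr1", 100, 300)
  expect_equal(count_reads_in_region(region, frags), 1L)  # coterminous
  expect_equal(count_reads_in_region(gintervals("chr1", 300, 400), frags),
               0L)  # abutting half-open
  grown <- gintervals("chr1", 100, c(300, 500, 1000))
  counts <- count_reads_in_region(grown, frags)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts, c(1L, 2L, 3L))
})
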