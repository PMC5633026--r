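test_that("simulation is deterministic under a fixed config", {
  cfg <- tiny_sim_config()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genome$sequences, b$genome$sequences)
  expect_identical(a$methylomes$truth, b$methylomes$truth)
  expect_identical(a$frags$fragments, b$frags$fragments)
  expect_identical(a$ct_table, b$ct_table)
})

test_that("implanted CGIs satisfy all three criteria by direct recount", {
  cfg <- tiny_sim_config(n_cgis = 5L)
  g <- simulate_genome(cfg)
  truth <- g$cgi_truth
  expect_equal(nrow(truth), 5L)
  for (i in seq_len(nrow(truth))) {
    seg <- substr(g$sequences[[truth$chrom[i]]], truth$start[i] + 1,
                  truth$end[i])
    expect_gt(nchar(seg), 200)
    expect_gt(gc_fraction(seg), 0.5)
    expect_gt(as.numeric(cpg_oe(seg)), 0.6)
  }
})

test_that("background outside implants is CpG-depleted (O/E < 0.6)", {
  cfg <- tiny_sim_config(n_cgis = 4L, n_genes = 5L)
  g <- simulate_genome(cfg)
  seq1 <- g$sequences[[1]]
  # excise implanted islands, check the flanking background directly
  cg <- g$cgi_truth
  keep <- c(0L, as.vector(rbind(cg$start, cg$end)), nchar(seq1))
  background <- paste(vapply(seq(1, length(keep) - 1, by = 2), function(i)
    substr(seq1, keep[i] + 1, keep[i + 1]), ""), collapse = "")
  expect_lt(as.numeric(cpg_oe(background)), 0.6)
  # CpG depletion replaces some G with A/T, so GC sits a little below the
  # nominal background level
  expect_gt(gc_fraction(background), 0.30)
  expect_lt(gc_fraction(background), 0.45)
})

test_that("fragment lengths honour the size-selection window", {
  cfg <- tiny_sim_config()
  st <- simulate_study(cfg)
  for (fr in st$frags$fragments) {
    len <- fr$end - fr$start
    expect_true(all(len >= 220 & len <= 320))
    expect_true(all(fr$start >= 0))
    expect_true(all(fr$end <= st$genome$chrom_lengths[fr$chrom]))
  }
})

test_that("rate tracks encode the implanted fold change exactly", {
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg)
  m <- simulate_methylomes(cfg, g)
  expect_true(all(unlist(m$rate$TC) >= 0))
  expect_true(all(unlist(m$rate$CH) >= 0))
  truth <- m$truth
  for (i in seq_len(nrow(truth))) {
    ch <- truth$chrom[i]
    bins <- (truth$start[i] %/% m$bin + 1):(truth$end[i] %/% m$bin)
    ratio <- m$rate$TC[[ch]][bins] / m$rate$CH[[ch]][bins]
    expect_equal(ratio, rep(2^truth$true_log2fc[i], length(bins)))
  }
  # no implanted effect -> identical tracks
  cfg0 <- tiny_sim_config(n_true_dmrs = 0L, n_null_peaks = 3L)
  g0 <- simulate_genome(cfg0)
  m0 <- simulate_methylomes(cfg0, g0)
  expect_identical(m0$rate$TC, m0$rate$CH)
})

test_that("midpoint coverage ratio tracks the rate ratio", {
  cfg <- tiny_sim_config(library_jitter = 0, seed = 5L,
                         fragments_per_replicate = 20000L)
  st <- simulate_study(cfg)
  truth <- st$methylomes$truth
  up <- truth[truth$kind == "dmr_up", ][1, ]
  pool <- function(grp) do.call(rbind, lapply(
    st$frags$fragments[st$frags$samples$group == grp],
    function(d) d[, c("chrom", "start", "end")]))
  count_mid <- function(frags, region) {
    mid <- (frags$start + frags$end) %/% 2
    sum(frags$chrom == region$chrom & mid >= region$start &
          mid < region$end)
  }
  n_tc <- count_mid(pool("TC"), up)
  n_ch <- count_mid(pool("CH"), up)
  expect_gte(n_ch, 50)
  # binomial CI on the ratio: with rate ratio 4, tc/(tc+ch) ~ 0.8
  p_hat <- n_tc / (n_tc + n_ch)
  se <- sqrt(0.8 * 0.2 / (n_tc + n_ch))
  expect_lt(abs(p_hat - 0.8), 4 * se)
})

test_that("coverage is group-symmetric away from differential regions", {
  cfg <- tiny_sim_config(n_true_dmrs = 0L, seed = 12L)
  st <- simulate_study(cfg)
  pool <- function(grp) do.call(rbind, lapply(
    st$frags$fragments[st$frags$samples$group == grp],
    function(d) d[, c("chrom", "start", "end")]))
  cl <- st$genome$chrom_lengths
  ptc <- chromosome_profile(pool("TC"), cl, window = 2000L)
  pch <- chromosome_profile(pool("CH"), cl, window = 2000L)
  keep <- ptc$count >= 20 & pch$count >= 20
  expect_gte(sum(keep), 50)
  lr <- log(ptc$count[keep] / sum(ptc$count)) -
    log(pch$count[keep] / sum(pch$count))
  expect_lt(abs(mean(lr)), 3 * stats::sd(lr) / sqrt(sum(keep)) + 0.01)
})

test_that("written study files are complete and deterministic", {
  cfg <- tiny_sim_config(fragments_per_replicate = 2000L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, dir = d1)
  simulate_study(cfg, dir = d2)
  for (f in c("genome.fa", "genes.gtf", "truth.tsv", "cgi_truth.tsv",
              "config.json", file.path("fragments", "TC_1.bed"))) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("implanted CGIs are all recovered by the scanner", {
  cfg <- tiny_sim_config()
  g <- simulate_genome(cfg)
  isl <- scan_cgis_genome(g$sequences)
  truth <- g$cgi_truth
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(isl$chrom == truth$chrom[i] &
          overlap_length(isl, truth[rep(i, nrow(isl)), ]) > 0)
  }, TRUE)
  expect_true(all(hit))
})
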