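test_that("chromosome windows count fragment midpoints", {
  cl <- c(chr1 = 30000L, chr2 = 5000L)
  # one fragment with midpoint 15,100 -> window 2 of chr1
  frags <- make_fragments("chr1", 15000, 15200)
  prof <- chromosome_profile(frags, cl)
  chr1 <- prof[prof$chrom == "chr1", ]
  expect_equal(nrow(chr1), 3L)
  expect_equal(chr1$count, c(0L, 1L, 0L))
  expect_equal(chr1$normalized, c(0, 1e-3, 0))
  # empty chromosome: ceiling(L / window) all-zero windows
  chr2 <- prof[prof$chrom == "chr2", ]
  expect_equal(nrow(chr2), 1L)
  expect_equal(chr2$count, 0L)
})

test_that("CpG-density bins classify windows and reads correctly", {
  # chr of 2 x 1 kb windows: window 1 has 7 CpGs, window 2 none
  w1 <- paste0(strrep("CG", 7), strrep("AT", 493))
  w2 <- strrep("AT", 500)
  seqs <- c(chr1 = paste0(w1, w2))
  frags <- make_fragments("chr1", c(100, 200, 300), c(200, 300, 400))
  prof <- cpg_density_profile(frags, seqs)
  expect_equal(prof$bin, c("0", "1-4", "5-10", "11-20", ">20"))
  expect_equal(prof$n_windows, c(1L, 0L, 1L, 0L, 0L))
  expect_equal(prof$proportion[prof$bin == "5-10"], 1)
  expect_equal(sum(prof$proportion), 1)
})

test_that("element distribution uses midpoint labels with precedence", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(10000L, 13500L), end = c(12000L, 15000L),
                      strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gB"),
                      start = c(10000L, 13500L), end = c(12000L, 15000L))
  cds <- data.frame(gene_id = c("gA", "gB"),
                    start = c(10100L, 13600L), end = c(11900L, 14900L))
  gm <- build_gene_models(genes, exons, cds)
  # midpoint 14000: cds of gB AND inside upstream2k? no -- but 12600 is
  # downstream2k of gA and upstream2k of gB; 13650 is cds of gB
  frags <- make_fragments("chr1",
                          c(10950, 13550, 12550, 100),
                          c(11050, 13750, 12650, 200))
  dist <- element_distribution(frags, gm)
  expect_equal(dist$count[dist$element == "cds"], 2L)      # 11000, 13650
  expect_equal(dist$count[dist$element == "upstream2k"], 1L)  # 12600
  expect_equal(dist$count[dist$element == "intergenic"], 1L)
  expect_equal(sum(dist$proportion), 1)
  # a cds midpoint of one gene beats upstream2k of another
  lab <- label_positions("chr1", 13650L, gm)
  expect_equal(lab, "cds")
})

test_that("flat coverage yields a flat 20/40/20 metagene profile", {
  cl <- c(chr1 = 60000L)
  frags <- flat_fragments(60000L)  # exact depth 50 away from edges
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 20000L,
                      end = 24000L, strand = "+", stringsAsFactors = FALSE)
  gm <- build_gene_models(genes,
                          data.frame(gene_id = "g1", start = 20000L,
                                     end = 24000L),
                          data.frame(gene_id = "g1", start = 20100L,
                                     end = 23900L), chrom_lengths = cl)
  prof <- metagene_profile(frags, gm, cl)
  expect_equal(nrow(prof), 80L)
  expect_equal(attr(prof, "n_regions"), 1L)
  expect_true(all(prof$value > 0))
  expect_equal(max(prof$value) / min(prof$value), 1, tolerance = 1e-9)
  expect_equal(prof$value[1], 50 / 1000)
})

test_that("body enrichment doubles body windows relative to flanks", {
  cl <- c(chr1 = 60000L)
  base <- flat_fragments(60000L, every = 8L)           # depth 25
  # 25 fragments spanning exactly the body: +25 depth there, 0 elsewhere
  extra <- make_fragments("chr1", rep(20000L, 25), rep(24000L, 25))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 20000L,
                      end = 24000L, strand = "+", stringsAsFactors = FALSE)
  gm <- build_gene_models(genes,
                          data.frame(gene_id = "g1", start = 20000L,
                                     end = 24000L), NULL,
                          chrom_lengths = cl)
  prof <- metagene_profile(rbind(base, extra), gm, cl)
  body <- prof$value[prof$segment == "body"]
  flank <- prof$value[prof$segment != "body"]
  expect_equal(unique(round(body / mean(flank), 6)), 2)
})

test_that("strand flip reverses the profile exactly", {
  withr::local_seed(14)
  cl <- c(chr1 = 100000L)
  starts <- sample.int(99000L, 20000, replace = TRUE)
  frags <- make_fragments("chr1", starts, starts + sample(100:300, 20000,
                                                          replace = TRUE))
  mk <- function(strand) {
    # body lengths divisible by 40 so windows tile bases exactly
    genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                        start = c(30000L, 62000L), end = c(34000L, 70800L),
                        strand = strand, stringsAsFactors = FALSE)
    build_gene_models(genes,
                      data.frame(gene_id = c("a", "b"),
                                 start = c(30000L, 62000L),
                                 end = c(34000L, 70800L)),
                      NULL, chrom_lengths = cl)
  }
  plus <- metagene_profile(frags, mk(c("+", "+")), cl)
  minus <- metagene_profile(frags, mk(c("-", "-")), cl)
  expect_equal(minus$value, rev(plus$value))
})

test_that("regions too short for their windows are skipped and counted", {
  cl <- c(chr1 = 10000L)
  frags <- flat_fragments(10000L)
  regions <- data.frame(chrom = "chr1", start = c(3000L, 5000L),
                        end = c(3020L, 9000L), stringsAsFactors = FALSE)
  prof <- metagene_profile(frags, regions, cl)
  expect_equal(attr(prof, "n_regions"), 1L)
  expect_equal(attr(prof, "n_skipped"), 1L)
})

test_that("CGI metagene shows central enrichment on synthetic data", {
  cfg <- tiny_sim_config()
  st <- simulate_study(cfg)
  isl <- scan_cgis_genome(st$genome$sequences)
  frags <- do.call(rbind, lapply(st$frags$fragments[1:3], function(d)
    d[, c("chrom", "start", "end", "sample_id")]))
  prof <- metagene_profile(frags, isl[, c("chrom", "start", "end")],
                           st$genome$chrom_lengths)
  body <- mean(prof$value[prof$segment == "body"])
  flank <- mean(prof$value[c(1:10, 71:80)])
  expect_gt(body, 2 * flank)
})
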