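# Small fixture builders shared across test files.

make_fragments <- function(chrom, start, end, sample_id = "s1", ...) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end),
             sample_id = rep_len(sample_id, length(start)), ...,
             stringsAsFactors = FALSE)
}

# 125 bp mate strings/qualities with controlled N and low-quality counts
make_read_pair <- function(n_N1 = 0, n_lowq1 = 0, len = 125L,
                           chrom = "chr1", start = 0L) {
  seq1 <- paste(rep("A", len), collapse = "")
  if (n_N1 > 0)
    substr(seq1, 1, n_N1) <- paste(rep("N", n_N1), collapse = "")
  q_hi <- rawToChar(as.raw(rep(33L + 30L, len)))          # Phred 30
  qual1 <- q_hi
  if (n_lowq1 > 0) {
    low <- rawToChar(as.raw(rep(33L + 20L, n_lowq1)))     # Phred 20
    qual1 <- paste0(low, substr(q_hi, n_lowq1 + 1, len))
  }
  data.frame(chrom = chrom, start = start, end = start + 300L,
             sample_id = "s1", seq1 = seq1,
             seq2 = paste(rep("A", len), collapse = ""),
             qual1 = qual1, qual2 = q_hi,
             multiplicity = 1L, mismatches = 0L, stringsAsFactors = FALSE)
}

# deterministic uniform tiling of fragments giving flat coverage depth
# (length * every bp'th start) away from chromosome edges
flat_fragments <- function(chrom_len, frag_len = 200L, every = 4L,
                           chrom = "chr1") {
  starts <- seq.int(0L, chrom_len - frag_len, by = every)
  make_fragments(chrom, starts, starts + frag_len)
}

tiny_sim_config <- function(...) {
  args <- list(n_chroms = 1L, chrom_length = 200000L, n_genes = 10L,
               n_cgis = 6L, n_true_dmrs = 4L, n_null_peaks = 4L,
               fragments_per_replicate = 6000L, seed = 42L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# union (reduce) of an interval frame, for coverage-conservation checks
.rd <- function(df) {
  out <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# random two-group peak sets for merge-rule property tests
random_peak_sets <- function(n_tc, n_ch, chroms = c("chr1", "chr2"),
                             span = 100000L) {
  mk <- function(n) {
    start <- sample.int(span, n)
    len <- sample(50:2000, n, replace = TRUE)
    p <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                    start = start, end = start + len,
                    stringsAsFactors = FALSE)
    # pre-reduce within group so both routes see caller-like input
    p[order(p$chrom, p$start), ]
  }
  list(tc = mk(n_tc), ch = mk(n_ch))
}
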