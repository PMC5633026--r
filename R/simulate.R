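#' Configuration for a synthetic two-group MeDIP-seq study
#'
#' Defaults emulate the design of a two-breed chicken-embryo MeDIP-seq
#' experiment at toy scale: 2 groups (TC vs CH) x 3 biological replicates,
#' paired-end 125 bp reads from 100-500 bp sonication fragments
#' size-selected to 220-320 bp, antibody enrichment proportional to local
#' CpG density, implanted CpG islands satisfying the standard criteria
#' (length > 200 bp, GC > 50%, CpG O/E > 0.6), and implanted differential
#' regions of symmetric up/down effect.
#'
#' @param seed Integer seed; every stage derives its RNG stream from it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 1 Mb).
#' @param n_genes Number of non-overlapping genes (default 100); bodies are
#'   multiples of 40 bp so equal body windows tile them exactly.
#' @param gene_body_range Body length range in bp.
#' @param n_cgis,cgi_length_range Implanted CpG islands.
#' @param gc_background Background GC fraction (default 0.40).
#' @param cpg_keep Fraction of background CpG dinucleotides kept (CpG
#'   depletion; default 0.25 gives genome-wide O/E well below 0.6 outside
#'   implants).
#' @param n_true_dmrs Implanted differential regions, half up / half down
#'   (default 30).
#' @param n_null_peaks Enriched regions with no group difference
#'   (default 30).
#' @param dmr_length_range Differential-region length range in bp.
#' @param dmr_log2fc Absolute effect size on the TC enrichment rate
#'   (default 2).
#' @param peak_enrichment Rate multiplier of implanted enriched regions
#'   over the local baseline, both groups (default 8).
#' @param dmr_in_gene_frac Fraction of implanted regions centred inside a
#'   gene annotation span (default 0.7).
#' @param replicates_per_group Biological replicates (default 3).
#' @param fragments_per_replicate Mean library size (default 50000).
#' @param library_jitter Uniform relative jitter of per-replicate library
#'   sizes (default 0.10), so the fold-change normalization is exercised.
#' @param fragment_length_range Sonication range in bp (default 100-500).
#' @param size_selection_range Retained fragment lengths (default 220-320;
#'   must lie within the sonication range).
#' @param read_length Mate read length in bp (default 125).
#' @param frac_n_reads,frac_lowq_reads Fractions of fragments given
#'   N-contaminated mate sequences / low-quality mate qualities, to
#'   exercise read QC (defaults 0.01).
#' @param frac_multimap,frac_high_mismatch Fractions of fragments flagged
#'   multi-mapping / with > 5 mismatches (defaults 0.005, 0.002).
#' @param rate_bin Resolution of the enrichment-rate track in bp
#'   (default 100).
#' @param base_rate,cpg_rate_weight Baseline enrichment rate per track bin:
#'   `base_rate + cpg_rate_weight * CpG count in bin`.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 1e6,
                       n_genes = 100L, gene_body_range = c(2400L, 10000L),
                       n_cgis = 40L, cgi_length_range = c(400L, 800L),
                       gc_background = 0.40, cpg_keep = 0.25,
                       n_true_dmrs = 30L, n_null_peaks = 30L,
                       dmr_length_range = c(1000L, 2000L),
                       dmr_log2fc = 2, peak_enrichment = 8,
                       dmr_in_gene_frac = 0.7,
                       replicates_per_group = 3L,
                       fragments_per_replicate = 50000L,
                       library_jitter = 0.10,
                       fragment_length_range = c(100L, 500L),
                       size_selection_range = c(220L, 320L),
                       read_length = 125L,
                       frac_n_reads = 0.01, frac_lowq_reads = 0.01,
                       frac_multimap = 0.005, frac_high_mismatch = 0.002,
                       rate_bin = 100L, base_rate = 0.1,
                       cpg_rate_weight = 0.5) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_body_range = as.integer(gene_body_range),
              n_cgis = as.integer(n_cgis),
              cgi_length_range = as.integer(cgi_length_range),
              gc_background = gc_background, cpg_keep = cpg_keep,
              n_true_dmrs = as.integer(n_true_dmrs),
              n_null_peaks = as.integer(n_null_peaks),
              dmr_length_range = as.integer(dmr_length_range),
              dmr_log2fc = dmr_log2fc, peak_enrichment = peak_enrichment,
              dmr_in_gene_frac = dmr_in_gene_frac,
              replicates_per_group = as.integer(replicates_per_group),
              fragments_per_replicate = as.integer(fragments_per_replicate),
              library_jitter = library_jitter,
              fragment_length_range = as.integer(fragment_length_range),
              size_selection_range = as.integer(size_selection_range),
              read_length = as.integer(read_length),
              frac_n_reads = frac_n_reads,
              frac_lowq_reads = frac_lowq_reads,
              frac_multimap = frac_multimap,
              frac_high_mismatch = frac_high_mismatch,
              rate_bin = as.integer(rate_bin), base_rate = base_rate,
              cpg_rate_weight = cpg_rate_weight)
  with(cfg, {
    stopifnot(n_chroms > 0, chrom_length > 0, n_genes >= 0, n_cgis >= 0,
              n_true_dmrs >= 0, n_null_peaks >= 0,
              replicates_per_group > 0, fragments_per_replicate > 0,
              gc_background > 0, gc_background < 1,
              cpg_keep >= 0, cpg_keep <= 1,
              dmr_log2fc >= 0, peak_enrichment > 0,
              library_jitter >= 0, library_jitter < 1,
              read_length > 0, rate_bin > 0, base_rate > 0,
              size_selection_range[1L] >= fragment_length_range[1L],
              size_selection_range[2L] <= fragment_length_range[2L],
              size_selection_range[1L] <= size_selection_range[2L],
              read_length <= size_selection_range[1L])
  })
  structure(cfg, class = "sim_config")
}

## derived per-stage seeds (kept well below 2^31)
.stage_seed <- function(cfg, stage) (cfg$seed %% 100000000L) * 10L + stage

.BASES <- c("A", "C", "G", "T")

## random background sequence (char vector) with CpG depletion
.background_chrom <- function(len, gc, cpg_keep) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  x <- sample(.BASES, len, replace = TRUE, prob = p)
  is_cg <- which(x[-len] == "C" & x[-1L] == "G")
  drop <- is_cg[stats::runif(length(is_cg)) > cpg_keep]
  if (length(drop))
    x[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
  x
}

## CpG-island-like sequence of >= len bases: token process emitting "CG"
## with prob 0.2, otherwise a GC-rich single base
.cgi_sequence <- function(len) {
  repeat {
    ntok <- ceiling(len / 1.2) + 20L
    toks <- ifelse(stats::runif(ntok) < 0.2, "CG",
                   sample(.BASES, ntok, replace = TRUE,
                          prob = c(0.2, 0.3, 0.3, 0.2)))
    s <- substr(paste(toks, collapse = ""), 1L, len)
    if (nchar(s) < len) next
    if (gc_fraction(s) > 0.55 && as.numeric(cpg_oe(s)) > 0.8) return(s)
  }
}

## sample n non-overlapping placements of given lengths, avoiding `occupied`
## (interval df) with `margin` bp padding; error when they do not fit
.place_features <- function(lengths, chrom_names, chrom_len, occupied,
                            margin, label, max_tries = 10000L) {
  placed <- occupied
  out <- data.frame(chrom = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE)
  for (L in lengths) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place all ", label,
             " features in the genome; enlarge it or request fewer")
      ch <- sample(chrom_names, 1L)
      s <- sample.int(chrom_len - L - 2L * margin, 1L) + margin
      cand <- data.frame(chrom = ch, start = s, end = s + L,
                         stringsAsFactors = FALSE)
      pad <- data.frame(chrom = ch, start = max(0L, s - margin),
                        end = s + L + margin, stringsAsFactors = FALSE)
      busy <- placed[placed$chrom == ch, , drop = FALSE]
      if (nrow(busy) == 0L ||
          all(overlap_length(pad[rep(1L, nrow(busy)), ], busy) == 0L)) {
        placed <- rbind(placed, cand)
        out <- rbind(out, cand)
        break
      }
    }
  }
  out
}

#' Simulate a genome with genes and implanted CpG islands
#'
#' Background sequence is sampled at `gc_background` with CpG depletion
#' (`cpg_keep`), giving genome-wide CpG O/E well below the island criterion
#' outside implants. CpG-island segments verifying all three defining
#' criteria are implanted at non-overlapping positions; non-overlapping
#' coding gene structures (1-4 exons, CDS flanked by UTRs, body length a
#' multiple of 40) are laid out away from chromosome edges.
#'
#' @param config A [sim_config()] object.
#' @return List `sequences` (named character), `chrom_lengths`,
#'   `gene_models` ([gene_models()]), `cgi_truth` (interval df with
#'   `kind = "cgi"`, `gc_fraction`, `cpg_oe` of the implanted segment).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 1L))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- lapply(chroms, function(ch)
    .background_chrom(config$chrom_length, config$gc_background,
                      config$cpg_keep))
  names(seqs) <- chroms
  occupied <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  ## genes first (they need flank margins), then CGIs anywhere else
  gene_bodies <- 40L * sample(
    seq.int(config$gene_body_range[1L] %/% 40L,
            config$gene_body_range[2L] %/% 40L),
    config$n_genes, replace = TRUE)
  genes_pos <- .place_features(gene_bodies, chroms, config$chrom_length,
                               occupied, margin = 2200L, label = "gene")
  occupied <- rbind(occupied, genes_pos)
  cgi_len <- sample(seq.int(config$cgi_length_range[1L],
                            config$cgi_length_range[2L]),
                    config$n_cgis, replace = TRUE)
  cgi_pos <- .place_features(cgi_len, chroms, config$chrom_length,
                             occupied, margin = 300L, label = "CGI")
  ## implant CGI sequences
  cgi_stats <- data.frame(gc_fraction = numeric(), cpg_oe = numeric())
  for (i in seq_len(nrow(cgi_pos))) {
    ch <- cgi_pos$chrom[i]
    s <- cgi_pos$start[i]; e <- cgi_pos$end[i]
    isl <- .cgi_sequence(e - s)
    seqs[[ch]][(s + 1L):e] <- strsplit(isl, "")[[1L]]
    cgi_stats <- rbind(cgi_stats,
                       data.frame(gc_fraction = gc_fraction(isl),
                                  cpg_oe = as.numeric(cpg_oe(isl))))
  }
  sequences <- vapply(seqs, paste, "", collapse = "")
  cl <- chrom_lengths(sequences)
  ## gene structures on the placed bodies
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(nrow(genes_pos))),
                      chrom = genes_pos$chrom, start = genes_pos$start,
                      end = genes_pos$end,
                      strand = sample(c("+", "-"), nrow(genes_pos),
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  exons <- list(); cds <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    L <- g$end - g$start
    n_ex <- sample.int(4L, 1L)
    nseg <- 2L * n_ex - 1L
    if (nseg == 1L) {
      widths <- L
    } else {
      base <- 150L
      extra <- as.vector(stats::rmultinom(1L, L - base * nseg,
                                          rep(1, nseg)))
      widths <- base + extra
    }
    bounds <- g$start + c(0L, cumsum(widths))
    ex_idx <- seq(1L, nseg, by = 2L)
    ex <- data.frame(gene_id = g$gene_id, start = bounds[ex_idx],
                     end = bounds[ex_idx + 1L], stringsAsFactors = FALSE)
    exons[[i]] <- ex
    ## contiguous genomic CDS span leaving UTR room in the terminal exons
    first <- ex[1L, ]; last <- ex[nrow(ex), ]
    utr_left <- sample.int(min(100L, first$end - first$start - 2L), 1L)
    utr_right <- sample.int(min(100L, last$end - last$start - 2L), 1L)
    cds_span <- data.frame(gene_id = g$gene_id,
                           start = first$start + utr_left,
                           end = last$end - utr_right,
                           stringsAsFactors = FALSE)
    ## CDS = span intersected with exons
    pieces <- .ir_intersect(
      data.frame(chrom = g$chrom, start = ex$start, end = ex$end),
      data.frame(chrom = g$chrom, start = cds_span$start,
                 end = cds_span$end))
    cds[[i]] <- data.frame(gene_id = g$gene_id, start = pieces$start,
                           end = pieces$end, stringsAsFactors = FALSE)
  }
  models <- build_gene_models(genes, do.call(rbind, exons),
                              do.call(rbind, cds), chrom_lengths = cl)
  cgi_truth <- cbind(cgi_pos, kind = rep("cgi", nrow(cgi_pos)), cgi_stats,
                     stringsAsFactors = FALSE)
  names(cgi_truth)[4] <- "kind"
  cgi_truth <- cgi_truth[order(cgi_truth$chrom, cgi_truth$start), ,
                         drop = FALSE]
  rownames(cgi_truth) <- NULL
  list(sequences = sequences, chrom_lengths = cl, gene_models = models,
       cgi_truth = cgi_truth)
}

## CpG count per rate bin for one chromosome sequence
.cpg_per_bin <- function(sequence, bin) {
  b <- charToRaw(sequence)
  L <- length(b)
  cg_pos <- which(b[-L] == as.raw(67L) & b[-1L] == as.raw(71L))
  tabulate(cg_pos %/% bin + 1L, nbins = as.integer(ceiling(L / bin)))
}

#' Simulate per-group enrichment-rate tracks with implanted DMRs
#'
#' The baseline enrichment rate per track bin is
#' `base_rate + cpg_rate_weight * CpG count`, identical in both groups.
#' Implanted regions (bin-aligned) multiply both groups' baseline by
#' `peak_enrichment`; in true differential regions the TC rate is further
#' multiplied by `2^(+/- dmr_log2fc)`, so the TC/CH rate ratio equals the
#' intended fold change exactly on the track.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome()].
#' @return List `rate` (`$TC`, `$CH`: per-chromosome numeric bin vectors),
#'   `truth` (data frame `chrom`, `start`, `end`, `kind`
#'   (`dmr_up`/`dmr_down`/`null_peak`), `true_log2fc`), `bin`.
#' @export
simulate_methylomes <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 2L))
  bin <- config$rate_bin
  base <- lapply(genome$sequences, function(s)
    config$base_rate + config$cpg_rate_weight * .cpg_per_bin(s, bin))
  n_up <- config$n_true_dmrs %/% 2L
  n_down <- config$n_true_dmrs - n_up
  n_feat <- config$n_true_dmrs + config$n_null_peaks
  truth <- data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character(),
                      true_log2fc = numeric(), stringsAsFactors = FALSE)
  rate_tc <- base
  rate_ch <- base
  if (n_feat > 0L) {
    lens <- sample(seq.int(config$dmr_length_range[1L],
                           config$dmr_length_range[2L]),
                   n_feat, replace = TRUE)
    lens <- pmax(bin, (lens %/% bin) * bin)  # bin-aligned lengths
    kinds <- c(rep("dmr_up", n_up), rep("dmr_down", n_down),
               rep("null_peak", config$n_null_peaks))
    genes <- genome$gene_models$genes
    occupied <- data.frame(chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
    rows <- list()
    for (i in seq_len(n_feat)) {
      L <- lens[i]
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 10000L)
          stop("could not place all differential/null regions")
        in_gene <- nrow(genes) > 0L &&
          stats::runif(1L) < config$dmr_in_gene_frac
        if (in_gene) {
          g <- genes[sample.int(nrow(genes), 1L), ]
          lo <- max(2000L, g$start - 2000L)
          hi <- min(config$chrom_length - 2000L - L, g$end + 2000L - L)
          if (hi <= lo) next
          ch <- g$chrom
          s <- lo + sample.int(hi - lo, 1L)
        } else {
          ch <- sample(names(genome$sequences), 1L)
          s <- 2000L + sample.int(config$chrom_length - 4000L - L, 1L)
        }
        s <- (s %/% bin) * bin  # bin-aligned start
        cand <- data.frame(chrom = ch, start = s, end = s + L,
                           stringsAsFactors = FALSE)
        pad <- data.frame(chrom = ch, start = max(0L, s - 1000L),
                          end = s + L + 1000L, stringsAsFactors = FALSE)
        busy <- occupied[occupied$chrom == ch, , drop = FALSE]
        if (nrow(busy) == 0L ||
            all(overlap_length(pad[rep(1L, nrow(busy)), ], busy) == 0L)) {
          occupied <- rbind(occupied, cand)
          fc <- switch(kinds[i], dmr_up = config$dmr_log2fc,
                       dmr_down = -config$dmr_log2fc, null_peak = 0)
          rows[[i]] <- cbind(cand, kind = kinds[i], true_log2fc = fc,
                             stringsAsFactors = FALSE)
          break
        }
      }
    }
    truth <- do.call(rbind, rows)
    for (i in seq_len(nrow(truth))) {
      ch <- truth$chrom[i]
      bi <- (truth$start[i] %/% bin + 1L):(truth$end[i] %/% bin)
      rate_tc[[ch]][bi] <- rate_tc[[ch]][bi] * config$peak_enrichment *
        2^truth$true_log2fc[i]
      rate_ch[[ch]][bi] <- rate_ch[[ch]][bi] * config$peak_enrichment
    }
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(rate = list(TC = rate_tc, CH = rate_ch), truth = truth, bin = bin)
}

## batch of random quality strings, Phred 30-40
.quality_pool <- function(n, len) {
  vapply(seq_len(n), function(i)
    rawToChar(as.raw(33L + sample.int(11L, len, replace = TRUE) + 29L)),
    "")
}

## low-quality string: about 55% of bases at Phred <= 20
.lowq_quality <- function(n, len) {
  vapply(seq_len(n), function(i) {
    q <- ifelse(stats::runif(len) < 0.55,
                sample.int(19L, len, replace = TRUE) + 1L,  # Phred 2-20
                sample.int(11L, len, replace = TRUE) + 29L)
    rawToChar(as.raw(33L + q))
  }, "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate aligned MeDIP fragments for every replicate
#'
#' Per replicate, a library size is drawn around
#' `fragments_per_replicate` (uniform `library_jitter`); candidate
#' fragments get a uniform start, a uniform sonication length, are rejected
#' unless within the size-selection range, and are retained with
#' probability proportional to the group's enrichment rate at the fragment
#' midpoint. Paired 125 bp mates are cut from the fragment ends (mate 2
#' reverse-complemented); configurable fractions of fragments receive
#' N-contaminated sequences, low-quality strings, multi-mapping flags, or
#' excess mismatches to exercise read QC.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome()].
#' @param methylomes Output of [simulate_methylomes()].
#' @return List `fragments` (named list of per-sample fragment data
#'   frames), `samples` (data frame `sample_id`, `group`, `n_fragments`).
#' @export
simulate_fragments <- function(config, genome, methylomes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 3L))
  chroms <- names(genome$sequences)
  cl <- genome$chrom_lengths
  bin <- methylomes$bin
  if (max(vapply(c(methylomes$rate$TC, methylomes$rate$CH), max, 0)) <= 0)
    stop("enrichment rate is zero genome-wide")
  groups <- c("TC", "CH")
  samples <- data.frame(
    sample_id = unlist(lapply(groups, function(g)
      paste0(g, "_", seq_len(config$replicates_per_group)))),
    group = rep(groups, each = config$replicates_per_group),
    stringsAsFactors = FALSE)
  frag_lists <- vector("list", nrow(samples))
  names(frag_lists) <- samples$sample_id
  rl <- config$read_length
  ## flatten the per-chromosome rate tracks to one global bin table so a
  ## fragment midpoint can be drawn proportional to the enrichment rate
  nbins <- vapply(chroms, function(ch)
    length(methylomes$rate$TC[[ch]]), 0L)
  bin_chrom <- rep(chroms, nbins)
  bin_off <- unlist(lapply(chroms, function(ch)
    (seq_len(nbins[[ch]]) - 1L) * bin), use.names = FALSE)
  weights <- lapply(c(TC = "TC", CH = "CH"), function(g)
    unlist(methylomes$rate[[g]][chroms], use.names = FALSE))
  for (si in seq_len(nrow(samples))) {
    grp <- samples$group[si]
    w <- weights[[grp]]
    jit <- config$library_jitter
    lib_n <- round(config$fragments_per_replicate *
                     stats::runif(1L, 1 - jit, 1 + jit))
    got <- list(); n_got <- 0L
    while (n_got < lib_n) {
      m <- max(5000L, as.integer((lib_n - n_got) * 4.5))
      ## sonication length, then size selection
      len <- sample.int(config$fragment_length_range[2L] -
                          config$fragment_length_range[1L] + 1L,
                        m, replace = TRUE) +
        config$fragment_length_range[1L] - 1L
      keep <- len >= config$size_selection_range[1L] &
        len <= config$size_selection_range[2L]
      len <- len[keep]
      m2 <- length(len)
      if (m2 == 0L) next
      ## midpoint bin ~ rate, midpoint uniform within the bin
      bi <- sample.int(length(w), m2, replace = TRUE, prob = w)
      mid <- bin_off[bi] + sample.int(bin, m2, replace = TRUE) - 1L
      ch <- bin_chrom[bi]
      start <- mid - len %/% 2L
      ok <- start >= 0L & start + len <= cl[ch] & mid < cl[ch]
      if (any(ok)) {
        got[[length(got) + 1L]] <- data.frame(
          chrom = ch[ok], start = start[ok], end = start[ok] + len[ok],
          stringsAsFactors = FALSE)
        n_got <- n_got + sum(ok)
      }
    }
    fr <- do.call(rbind, got)[seq_len(lib_n), , drop = FALSE]
    fr <- fr[order(fr$chrom, fr$start), , drop = FALSE]
    rownames(fr) <- NULL
    fr$sample_id <- samples$sample_id[si]
    ## mate sequences from the fragment ends
    seq1 <- substring(genome$sequences[fr$chrom], fr$start + 1L,
                      fr$start + rl)
    seq2 <- .revcomp(substring(genome$sequences[fr$chrom],
                               fr$end - rl + 1L, fr$end))
    pool <- .quality_pool(200L, rl)
    fr$seq1 <- unname(seq1)
    fr$seq2 <- unname(seq2)
    fr$qual1 <- sample(pool, nrow(fr), replace = TRUE)
    fr$qual2 <- sample(pool, nrow(fr), replace = TRUE)
    fr$multiplicity <- 1L
    fr$mismatches <- sample.int(4L, nrow(fr), replace = TRUE) - 1L
    n <- nrow(fr)
    pick <- function(frac) which(stats::runif(n) < frac)
    ni <- pick(config$frac_n_reads)
    if (length(ni)) {
      ## 14/125 = 11.2% N in mate 1: over the 10% threshold
      n_n <- ceiling(0.112 * rl)
      fr$seq1[ni] <- vapply(fr$seq1[ni], function(s) {
        pos <- sample.int(nchar(s), min(n_n, nchar(s)))
        v <- strsplit(s, "")[[1L]]
        v[pos] <- "N"
        paste(v, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    qi <- pick(config$frac_lowq_reads)
    if (length(qi)) fr$qual1[qi] <- .lowq_quality(length(qi), rl)
    mi <- pick(config$frac_multimap)
    if (length(mi)) fr$multiplicity[mi] <- 2L
    xi <- pick(config$frac_high_mismatch)
    if (length(xi)) fr$mismatches[xi] <- 6L
    frag_lists[[si]] <- fr
  }
  samples$n_fragments <- vapply(frag_lists, nrow, 0L)
  list(fragments = frag_lists, samples = samples)
}

#' Simulate a qPCR Ct table with expression inverse to methylation
#'
#' Builds per-sample Ct values for target genes and a reference gene such
#' that the expected expression log2 fold change (TC over CH) equals minus
#' the supplied methylation log2 fold change, the repressive relationship
#' the concordance report looks for.
#'
#' @param gene_log2fc Named numeric vector: per-gene methylation log2 fold
#'   change (TC/CH).
#' @param n_per_group Samples per group (default 8).
#' @param reference_gene Reference gene id (default `"HPRT"`).
#' @param noise_sd Per-sample Ct noise (default 0.15 cycles).
#' @param seed Integer seed.
#' @return Ct data frame `sample_id`, `group`, `gene_id`, `ct_target`,
#'   `ct_reference`.
#' @export
simulate_ct_table <- function(gene_log2fc, n_per_group = 8L,
                              reference_gene = "HPRT", noise_sd = 0.15,
                              seed = 1L) {
  set.seed(seed %% 2000000000L)
  rows <- list()
  for (g in names(gene_log2fc)) {
    dct_ch <- stats::runif(1L, 3, 7)
    ## ddct = dct_tc - dct_ch = meth fc, so expression log2fc = -meth fc
    dct_tc <- dct_ch + gene_log2fc[[g]]
    for (grp in c("TC", "CH")) {
      dct <- if (grp == "TC") dct_tc else dct_ch
      for (i in seq_len(n_per_group)) {
        ref <- stats::rnorm(1L, 20, 0.3)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(grp, "_s", i), group = grp, gene_id = g,
          ct_target = ref + dct + stats::rnorm(1L, 0, noise_sd),
          ct_reference = ref, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic MeDIP-seq study
#'
#' Chains [simulate_genome()], [simulate_methylomes()] and
#' [simulate_fragments()], and derives a qPCR Ct table for up to five genes
#' overlapping true differential regions (expression inverse to
#' methylation). With `dir` set, writes `genome.fa`, `genes.gtf`,
#' `truth.tsv`, `cgi_truth.tsv`, per-sample `fragments/<sample>.bed`,
#' `ct_table.tsv` and `config.json`. Identical config (including seed)
#' reproduces identical outputs.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional output directory.
#' @return List `config`, `genome`, `methylomes`, `frags` (see
#'   [simulate_fragments()]), `ct_table` (possibly zero rows).
#' @export
simulate_study <- function(config, dir = NULL) {
  genome <- simulate_genome(config)
  methylomes <- simulate_methylomes(config, genome)
  frags <- simulate_fragments(config, genome, methylomes)
  ## qPCR targets: genes whose annotation span overlaps a true DMR
  ct <- data.frame(sample_id = character(), group = character(),
                   gene_id = character(), ct_target = numeric(),
                   ct_reference = numeric(), stringsAsFactors = FALSE)
  truth <- methylomes$truth
  tru_dmr <- truth[truth$kind %in% c("dmr_up", "dmr_down"), , drop = FALSE]
  if (nrow(tru_dmr) > 0L && nrow(genome$gene_models$genes) > 0L) {
    genes <- genome$gene_models$genes
    span <- data.frame(chrom = genes$chrom,
                       start = pmax(0L, genes$start - 2000L),
                       end = genes$end + 2000L, stringsAsFactors = FALSE)
    fc <- stats::setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
    for (i in seq_len(nrow(tru_dmr))) {
      ov <- overlap_length(span, tru_dmr[rep(i, nrow(span)), ]) > 0L
      fc[ov & is.na(fc)] <- tru_dmr$true_log2fc[i]
    }
    targets <- utils::head(names(fc)[!is.na(fc)], 5L)
    if (length(targets))
      ct <- simulate_ct_table(fc[targets], seed = .stage_seed(config, 4L))
  }
  out <- list(config = config, genome = genome, methylomes = methylomes,
              frags = frags, ct_table = ct)
  if (!is.null(dir)) write_study(out, dir)
  out
}

#' Write a simulated study to disk
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fragments"), showWarnings = FALSE)
  write_fasta(study$genome$sequences, file.path(dir, "genome.fa"))
  write_gtf(study$genome$gene_models, file.path(dir, "genes.gtf"))
  utils::write.table(study$methylomes$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$genome$cgi_truth,
                     file.path(dir, "cgi_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sid in names(study$frags$fragments)) {
    fr <- study$frags$fragments[[sid]]
    write_intervals(fr[, c("chrom", "start", "end")],
                    file.path(dir, "fragments", paste0(sid, ".bed")), "bed")
  }
  if (nrow(study$ct_table))
    utils::write.table(study$ct_table, file.path(dir, "ct_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(study$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
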