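## Fragment midpoint (0-based position).
.frag_mid <- function(frags) (frags$start + frags$end) %/% 2L

#' Per-chromosome windowed read counts
#'
#' Counts fragment midpoints per consecutive fixed-width window along every
#' chromosome; the normalized column divides the count by 1,000, the display
#' convention used for windowed MeDIP-seq read counts.
#'
#' @param fragments Fragment data frame (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window width in bp (default 10000).
#' @return Data frame `chrom`, `window`, `start`, `end`, `count`,
#'   `normalized`.
#' @export
chromosome_profile <- function(fragments, chrom_lengths, window = 10000L) {
  mids <- .frag_mid(fragments)
  parts <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    nwin <- as.integer(ceiling(len / window))
    m <- mids[fragments$chrom == ch]
    counts <- tabulate(m %/% window + 1L, nbins = nwin)
    starts <- (seq_len(nwin) - 1L) * as.integer(window)
    data.frame(chrom = ch, window = seq_len(nwin), start = starts,
               end = pmin(starts + as.integer(window), as.integer(len)),
               count = counts, normalized = counts / 1000,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Read distribution across CpG-density classes
#'
#' Splits every chromosome into fixed windows (default 1 kb), counts CpG
#' dinucleotides per window (a CpG belongs to the window of its first base),
#' bins windows by CpG count, and reports the proportion of fragment
#' midpoints falling into each bin.
#'
#' @param fragments Fragment data frame.
#' @param sequences Named character vector of chromosome sequences.
#' @param window Window width in bp (default 1000).
#' @param breaks Lower edges of the CpG-count bins
#'   (default `c(0, 1, 5, 11, 21)`, i.e. 0, 1-4, 5-10, 11-20, >20).
#' @return Data frame `bin`, `n_windows`, `n_fragments`, `proportion`
#'   (proportions sum to 1 when any fragments are given).
#' @export
cpg_density_profile <- function(fragments, sequences, window = 1000L,
                                breaks = c(0L, 1L, 5L, 11L, 21L)) {
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks))
  labels <- c(vapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- breaks[i]; hi <- breaks[i + 1L] - 1L
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }, ""), paste0(">", breaks[length(breaks)] - 1L))
  bin_of <- function(n) findInterval(n, breaks)  # 0 below first edge
  win_counts <- integer(0)
  frag_bin <- integer(0)
  n_windows <- integer(length(labels))
  n_frag_bin <- integer(length(labels))
  mids <- .frag_mid(fragments)
  for (ch in names(sequences)) {
    b <- charToRaw(chartr("acgt", "ACGT", sequences[[ch]]))
    L <- length(b)
    cg_pos <- which(b[-L] == as.raw(67L) & b[-1L] == as.raw(71L))
    nwin <- as.integer(ceiling(L / window))
    cpg_per_win <- tabulate((cg_pos - 1L) %/% window + 1L, nbins = nwin)
    wb <- bin_of(cpg_per_win)
    wb[wb == 0L] <- 1L
    n_windows <- n_windows + tabulate(wb, nbins = length(labels))
    m <- mids[fragments$chrom == ch]
    if (length(m)) {
      fb <- wb[m %/% window + 1L]
      n_frag_bin <- n_frag_bin + tabulate(fb, nbins = length(labels))
    }
  }
  total <- sum(n_frag_bin)
  data.frame(bin = labels, n_windows = n_windows, n_fragments = n_frag_bin,
             proportion = if (total > 0) n_frag_bin / total else
               rep(0, length(labels)),
             stringsAsFactors = FALSE)
}

#' Read distribution across gene elements
#'
#' Labels each fragment midpoint with the highest-precedence gene element
#' covering it ([element_precedence]; `intergenic` when none) and reports
#' per-element counts and proportions. Proportions over all labels,
#' including `intergenic`, sum to 1.
#'
#' @param fragments Fragment data frame.
#' @param models A [gene_models()] object.
#' @return Data frame `element`, `count`, `proportion`.
#' @export
element_distribution <- function(fragments, models) {
  labels <- c(element_precedence, "intergenic")
  lab <- label_positions(fragments$chrom, .frag_mid(fragments), models)
  counts <- vapply(labels, function(l) sum(lab == l), 0L)
  total <- sum(counts)
  data.frame(element = labels, count = unname(counts),
             proportion = if (total > 0) unname(counts) / total else
               rep(0, length(labels)),
             stringsAsFactors = FALSE)
}

## base-to-window assignment: offset o in [0, L) -> floor(o * n / L)
.window_index <- function(L, n) {
  o <- seq_len(L) - 1L
  as.integer((o * as.numeric(n)) %/% L) + 1L
}

## coverage Rle list from fragments, one per chromosome
.coverage_by_chrom <- function(fragments, chrom_lengths) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    d <- fragments[fragments$chrom == ch, , drop = FALSE]
    out[[ch]] <- IRanges::coverage(.as_iranges(d),
                                   width = as.integer(chrom_lengths[[ch]]))
  }
  out
}

#' Windowed metagene / meta-region coverage profile
#'
#' For each region the 5' flank, body and 3' flank are split into
#' `n_flank_windows` / `n_body_windows` / `n_flank_windows` equal windows
#' (bases assigned to window `floor(offset * n / length)`), per-window mean
#' base-level alignment depth is computed, per-window values are averaged
#' across regions, and the result is divided by 1,000 (set
#' `normalize = "per_million"` to scale by library size instead). Regions
#' are [gene_models()] (strand-aware: window 1 is always 5'-most; minus
#' strand profiles are reversed) or an interval data frame (unstranded).
#' Flanks are clipped at chromosome bounds; regions with any segment
#' shorter than its window count are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param fragments Fragment data frame.
#' @param regions A [gene_models()] object or interval data frame.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_flank_windows,n_body_windows Window counts (default 20/40).
#' @param flank Flank width in bp (default 2000).
#' @param normalize `"thousand"` (divide by 1,000; default) or
#'   `"per_million"` (divide by library size in millions).
#' @return Data frame `segment` (`up`/`body`/`down`), `window` (1-based
#'   overall index), `label` (`up01`...`down20`), `value`; attributes
#'   `n_regions` (used) and `n_skipped`.
#' @export
metagene_profile <- function(fragments, regions, chrom_lengths,
                             n_flank_windows = 20L, n_body_windows = 40L,
                             flank = 2000L,
                             normalize = c("thousand", "per_million")) {
  normalize <- match.arg(normalize)
  if (inherits(regions, "gene_models")) {
    reg <- regions$genes[, c("chrom", "start", "end", "strand")]
  } else {
    reg <- regions[, c("chrom", "start", "end")]
    reg$strand <- "+"
  }
  covs <- .coverage_by_chrom(fragments, chrom_lengths)
  n_tot <- 2L * n_flank_windows + n_body_windows
  acc <- matrix(0, nrow = 0L, ncol = n_tot)
  n_skipped <- 0L
  for (i in seq_len(nrow(reg))) {
    ch <- reg$chrom[i]
    if (!ch %in% names(covs)) { n_skipped <- n_skipped + 1L; next }
    len <- as.integer(chrom_lengths[[ch]])
    s <- reg$start[i]; e <- reg$end[i]
    left <- c(max(0L, s - flank), s)     # genomic left flank
    right <- c(e, min(len, e + flank))   # genomic right flank
    seg_len <- c(left[2L] - left[1L], e - s, right[2L] - right[1L])
    nwin <- c(n_flank_windows, n_body_windows, n_flank_windows)
    if (any(seg_len < nwin)) { n_skipped <- n_skipped + 1L; next }
    cov <- covs[[ch]]
    means <- function(a, z, n) {  # 0-based half-open segment -> window means
      v <- as.numeric(S4Vectors::window(cov, start = a + 1L, end = z))
      idx <- .window_index(z - a, n)
      as.numeric(rowsum(v, idx)) / tabulate(idx, nbins = n)
    }
    row <- c(means(left[1L], left[2L], n_flank_windows),
             means(s, e, n_body_windows),
             means(right[1L], right[2L], n_flank_windows))
    if (identical(reg$strand[i], "-")) row <- rev(row)
    acc <- rbind(acc, row)
  }
  if (nrow(acc) == 0L) {
    prof <- rep(0, n_tot)
  } else {
    prof <- colMeans(acc)
  }
  div <- if (normalize == "thousand") 1000 else max(1, nrow(fragments)) / 1e6
  prof <- prof / div
  seg <- rep(c("up", "body", "down"),
             times = c(n_flank_windows, n_body_windows, n_flank_windows))
  within <- c(seq_len(n_flank_windows), seq_len(n_body_windows),
              seq_len(n_flank_windows))
  out <- data.frame(segment = seg, window = seq_len(n_tot),
                    label = sprintf("%s%02d", seg, within), value = prof,
                    stringsAsFactors = FALSE)
  attr(out, "n_regions") <- nrow(acc)
  attr(out, "n_skipped") <- n_skipped
  out
}
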