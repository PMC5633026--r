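#' Simple window-based enrichment peak caller
#'
#' A deliberately plain stand-in for a model-based peak caller: fragment
#' midpoints are counted in fixed windows; a window is enriched when its
#' count both exceeds the upper `p_cutoff` tail of a Poisson background
#' (rate = genome-wide mean count per window) and reaches `min_fold` times
#' that mean; enriched windows separated by at most `merge_gap` bp are
#' merged into peaks. Replicates should be pooled per group before calling.
#'
#' @param fragments Pooled fragment data frame for one group.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window width in bp (default 200).
#' @param min_fold Minimum fold over the background mean (default 4).
#' @param p_cutoff Poisson tail probability cutoff (default 1e-4).
#' @param merge_gap Maximum gap in bp between enriched windows merged into
#'   one peak (default 200).
#' @return Peak data frame `chrom`, `start`, `end`, `read_count` (fragments
#'   overlapping the peak by >= 1 bp), `summit_score` (max window count over
#'   background mean).
#' @export
call_peaks_simple <- function(fragments, chrom_lengths, window = 200L,
                              min_fold = 4, p_cutoff = 1e-4,
                              merge_gap = 200L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), read_count = integer(),
                      summit_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(fragments) == 0L) return(empty)
  mids <- .frag_mid(fragments)
  nwin <- vapply(chrom_lengths, function(l) as.integer(ceiling(l / window)),
                 0L)
  lambda <- nrow(fragments) / sum(nwin)
  thr <- stats::qpois(1 - p_cutoff, lambda)
  gap_windows <- merge_gap %/% window
  parts <- list()
  for (ch in names(chrom_lengths)) {
    m <- mids[fragments$chrom == ch]
    counts <- tabulate(m %/% window + 1L, nbins = nwin[[ch]])
    hot <- which(counts > thr & counts >= min_fold * lambda)
    if (!length(hot)) next
    grp <- cumsum(c(1L, diff(hot) > gap_windows + 1L))
    for (g in split(hot, grp)) {
      s <- (min(g) - 1L) * as.integer(window)
      e <- min(max(g) * as.integer(window),
               as.integer(chrom_lengths[[ch]]))
      parts[[length(parts) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        summit_score = max(counts[g]) / lambda,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(parts)) return(empty)
  peaks <- do.call(rbind, parts)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$read_count <- count_reads_in_region(peaks, fragments)
  peaks[, c("chrom", "start", "end", "read_count", "summit_score")]
}

#' Count fragments overlapping regions
#'
#' Number of fragments whose interval overlaps each region by at least 1 bp
#' (half-open touching does not count); counts are monotone non-decreasing
#' as a region grows.
#'
#' @param regions Interval data frame.
#' @param fragments Fragment data frame.
#' @return Integer vector aligned with `regions` rows.
#' @export
count_reads_in_region <- function(regions, fragments) {
  out <- integer(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    fi <- fragments$chrom == ch
    if (!any(fi)) next
    out[ri] <- IRanges::countOverlaps(.as_iranges(regions[ri, , drop = FALSE]),
                                      .as_iranges(fragments[fi, , drop = FALSE]),
                                      minoverlap = 1L)
  }
  out
}

## union-find with path halving
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Merge two groups' peak sets by the 50%-of-shorter-peak rule
#'
#' A pair of peaks from the two groups is merged when their overlap exceeds
#' 50% (strictly, `min_overlap_frac`) of the shorter peak's length; merged
#' pairs chain transitively, and each connected set collapses to the union
#' span of its members (`source = "merged"`). Peaks qualifying with no
#' cross-group partner become unique regions (`TC_unique` / `CH_unique`).
#' Overlapping peaks within one group (which a well-formed caller should
#' not emit) are unioned first with a warning.
#'
#' @param tc_peaks,ch_peaks Peak data frames for the two groups.
#' @param min_overlap_frac Overlap fraction of the shorter peak that must be
#'   exceeded to merge (default 0.5).
#' @return Region data frame `chrom`, `start`, `end`, `source`
#'   (`TC_unique`, `CH_unique`, `merged`), sorted by coordinates.
#' @export
merge_peak_sets <- function(tc_peaks, ch_peaks, min_overlap_frac = 0.5) {
  pre <- function(p, who) {
    if (nrow(p) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    r <- .per_chrom_reduce(p[, c("chrom", "start", "end")])
    if (nrow(r) < nrow(p))
      warning("overlapping ", who, " peaks were unioned within group (",
              nrow(p), " -> ", nrow(r), ")")
    r
  }
  tc <- pre(tc_peaks, "TC")
  ch <- pre(ch_peaks, "CH")
  n1 <- nrow(tc); n2 <- nrow(ch)
  all <- rbind(cbind(tc, group = "TC", stringsAsFactors = FALSE),
               cbind(ch, group = "CH", stringsAsFactors = FALSE))
  n <- nrow(all)
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), source = character(),
                      stringsAsFactors = FALSE))
  parent <- seq_len(n)
  if (n1 > 0L && n2 > 0L) {
    for (chm in intersect(unique(tc$chrom), unique(ch$chrom))) {
      ti <- which(tc$chrom == chm)
      ci <- which(ch$chrom == chm)
      hits <- IRanges::findOverlaps(.as_iranges(tc[ti, , drop = FALSE]),
                                    .as_iranges(ch[ci, , drop = FALSE]),
                                    minoverlap = 1L)
      if (!length(hits)) next
      qi <- ti[S4Vectors::queryHits(hits)]
      si <- ci[S4Vectors::subjectHits(hits)]
      ov <- pmin(tc$end[qi], ch$end[si]) - pmax(tc$start[qi], ch$start[si])
      shorter <- pmin(tc$end[qi] - tc$start[qi], ch$end[si] - ch$start[si])
      ok <- ov > min_overlap_frac * shorter
      for (k in which(ok)) {
        a <- .uf_find(parent, qi[k])
        b <- .uf_find(parent, n1 + si[k])
        if (a != b) parent[b] <- a
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), 0L)
  parts <- lapply(split(seq_len(n), root), function(idx) {
    grp <- unique(all$group[idx])
    data.frame(chrom = all$chrom[idx[1L]],
               start = min(all$start[idx]),
               end = max(all$end[idx]),
               source = if (length(grp) == 2L) "merged"
                        else paste0(grp, "_unique"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
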