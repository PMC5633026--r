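#' CpG observed/expected ratio
#'
#' Gardiner-Garden & Frommer ratio over a sequence:
#' `(n_CpG * L) / (n_C * n_G)`, where `n_CpG` counts `CG` dinucleotides.
#' Defined as 0 (with attribute `undefined = TRUE`) when the sequence has no
#' C or no G.
#'
#' @param sequence Single character string over `A,C,G,T,N` (case
#'   insensitive).
#' @return Numeric ratio with logical attribute `undefined`.
#' @examples
#' cpg_oe("CGCGCG")  # 2
#' @export
cpg_oe <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  b <- charToRaw(chartr("acgt", "ACGT", sequence))
  L <- length(b)
  cc <- b == as.raw(67L)  # C
  gg <- b == as.raw(71L)  # G
  n_c <- sum(cc); n_g <- sum(gg)
  n_cg <- if (L >= 2L) sum(cc[-L] & gg[-1L]) else 0L
  if (n_c == 0L || n_g == 0L)
    return(structure(0, undefined = TRUE))
  structure((n_cg * L) / (n_c * n_g), undefined = FALSE)
}

#' GC fraction of a sequence
#'
#' @param sequence Single character string.
#' @return Fraction of bases that are G or C (N counts in the denominator).
#' @export
gc_fraction <- function(sequence) {
  b <- charToRaw(chartr("acgt", "ACGT", sequence))
  if (length(b) == 0L) return(0)
  sum(b == as.raw(67L) | b == as.raw(71L)) / length(b)
}

## rolling sum over c(0, cumsum(v)) between index ranges [lo, hi]
.range_sum <- function(cs, lo, hi) cs[hi + 1L] - cs[lo]

#' Scan a sequence for CpG islands
#'
#' Sliding-window island detection in the style of EMBOSS cpgplot: windows
#' of `window` bp stepped by `step` are scored for GC fraction and CpG
#' observed/expected ratio; a position qualifies when the averages over all
#' windows covering it exceed `min_gc` and `min_oe`; maximal runs of
#' qualifying positions longer than `min_length` bp are reported, and the
#' defining criteria (`length > min_length`, GC `> min_gc`,
#' O/E `> min_oe`) are re-checked on the final island extent. Windows
#' containing `N` never qualify.
#'
#' @param sequence Single character string.
#' @param window Window width in bp (default 100).
#' @param step Window step in bp (default 1).
#' @param min_length Minimum island length in bp, exclusive (default 200).
#' @param min_gc Minimum GC fraction, exclusive (default 0.5).
#' @param min_oe Minimum CpG O/E, exclusive (default 0.6).
#' @return Data frame `start`, `end` (0-based half-open), `length`,
#'   `gc_fraction`, `cpg_oe` recomputed on the reported extent. Sequences
#'   shorter than `window` yield zero rows.
#' @export
scan_cgis <- function(sequence, window = 100L, step = 1L,
                      min_length = 200L, min_gc = 0.5, min_oe = 0.6) {
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      gc_fraction = numeric(), cpg_oe = numeric(),
                      stringsAsFactors = FALSE)
  b <- charToRaw(chartr("acgt", "ACGT", sequence))
  L <- length(b)
  w <- as.integer(window)
  if (L < w) return(empty)
  cc <- b == as.raw(67L)
  gg <- b == as.raw(71L)
  nn <- !(cc | gg | b == as.raw(65L) | b == as.raw(84L))
  cg <- c(cc[-L] & gg[-1L], FALSE)  # CG dinucleotide starting at each pos
  cs_c <- c(0L, cumsum(cc)); cs_g <- c(0L, cumsum(gg))
  cs_n <- c(0L, cumsum(nn)); cs_cg <- c(0L, cumsum(cg))
  wstarts <- seq.int(1L, L - w + 1L, by = step)
  nw <- length(wstarts)
  wc <- .range_sum(cs_c, wstarts, wstarts + w - 1L)
  wg <- .range_sum(cs_g, wstarts, wstarts + w - 1L)
  wn <- .range_sum(cs_n, wstarts, wstarts + w - 1L)
  wcg <- .range_sum(cs_cg, wstarts, wstarts + w - 2L)  # dinucs inside window
  w_gc <- (wc + wg) / w
  w_oe <- ifelse(wc * wg > 0, (wcg * w) / (wc * wg), 0)
  w_gc[wn > 0L] <- 0
  w_oe[wn > 0L] <- 0
  ## per-position average of the window values over covering windows
  p <- seq_len(L)
  i_lo <- pmax(1L, as.integer(ceiling((p - w) / step)) + 1L)
  i_hi <- pmin(nw, (p - 1L) %/% as.integer(step) + 1L)
  covered <- i_lo <= i_hi
  ncov <- pmax(1L, i_hi - i_lo + 1L)
  cs_wgc <- c(0, cumsum(w_gc)); cs_woe <- c(0, cumsum(w_oe))
  avg_gc <- .range_sum(cs_wgc, pmin(i_lo, nw), i_hi) / ncov
  avg_oe <- .range_sum(cs_woe, pmin(i_lo, nw), i_hi) / ncov
  ok <- covered & avg_gc > min_gc & avg_oe > min_oe
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths > min_length)
  if (!length(cand)) return(empty)
  out <- lapply(cand, function(k) {
    a <- starts[k]; z <- ends[k]
    len <- z - a + 1L
    isl_c <- .range_sum(cs_c, a, z)
    isl_g <- .range_sum(cs_g, a, z)
    isl_cg <- if (z > a) .range_sum(cs_cg, a, z - 1L) else 0L
    gcf <- (isl_c + isl_g) / len
    oe <- if (isl_c > 0L && isl_g > 0L) (isl_cg * len) / (isl_c * isl_g) else 0
    if (gcf <= min_gc || oe <= min_oe) return(NULL)
    data.frame(start = a - 1L, end = z, length = len,
               gc_fraction = gcf, cpg_oe = oe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Scan all chromosomes of a genome for CpG islands
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param ... Passed to [scan_cgis()].
#' @return Data frame with a `chrom` column prepended.
#' @export
scan_cgis_genome <- function(sequences, ...) {
  parts <- lapply(names(sequences), function(ch) {
    isl <- scan_cgis(sequences[[ch]], ...)
    if (nrow(isl)) cbind(chrom = ch, isl, stringsAsFactors = FALSE)
    else cbind(data.frame(chrom = character()), isl)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
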