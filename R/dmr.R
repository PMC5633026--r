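#' Chi-square test of read counts between two groups
#'
#' Pearson chi-square (df = 1, no continuity correction by default) on the
#' 2x2 homogeneity table
#' `[[count_tc, lib_tc - count_tc], [count_ch, lib_ch - count_ch]]`,
#' comparing the in-region read proportion between groups. With
#' `method = "goodness_of_fit"` the in-region counts are instead tested
#' against expectations proportional to the library sizes. Tables with a
#' zero margin (e.g. both counts zero) get `statistic = 0`, `p_value = 1`,
#' and `flagged = TRUE`. All arguments are vectorized.
#'
#' @param count_tc,count_ch In-region fragment counts per group.
#' @param lib_tc,lib_ch Total mapped fragments per group (library sizes).
#' @param method `"two_by_two"` (default) or `"goodness_of_fit"`.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return Data frame `statistic`, `p_value`, `flagged`.
#' @examples
#' chi_square_region_test(30, 10, 100, 100)  # statistic 12.5
#' @export
chi_square_region_test <- function(count_tc, count_ch, lib_tc, lib_ch,
                                   method = c("two_by_two",
                                              "goodness_of_fit"),
                                   correct = FALSE) {
  method <- match.arg(method)
  stopifnot(all(lib_tc > 0), all(lib_ch > 0),
            all(count_tc <= lib_tc), all(count_ch <= lib_ch),
            all(count_tc >= 0), all(count_ch >= 0))
  n <- max(length(count_tc), length(count_ch))
  a <- rep_len(as.numeric(count_tc), n)
  c_ <- rep_len(as.numeric(count_ch), n)
  lt <- rep_len(as.numeric(lib_tc), n)
  lc <- rep_len(as.numeric(lib_ch), n)
  b <- lt - a
  d <- lc - c_
  if (method == "two_by_two") {
    N <- lt + lc
    flagged <- (a + c_) == 0 | (b + d) == 0 | lt == 0 | lc == 0
    det <- abs(a * d - b * c_)
    if (correct) det <- pmax(0, det - N / 2)
    denom <- lt * lc * (a + c_) * (b + d)
    stat <- ifelse(flagged, 0, N * det^2 / ifelse(denom == 0, 1, denom))
  } else {
    tot <- a + c_
    e1 <- tot * lt / (lt + lc)
    e2 <- tot * lc / (lt + lc)
    flagged <- tot == 0
    stat <- ifelse(flagged, 0, (a - e1)^2 / ifelse(e1 == 0, 1, e1) +
                     (c_ - e2)^2 / ifelse(e2 == 0, 1, e2))
  }
  p <- ifelse(flagged, 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  data.frame(statistic = stat, p_value = p, flagged = flagged)
}

#' Log2 fold change of in-region read counts (TC over CH)
#'
#' `log2(((count_tc + pseudocount) / lib_tc) /
#'       ((count_ch + pseudocount) / lib_ch))` by default; with
#' `normalize = FALSE` the raw count ratio
#' `log2((count_tc + pseudocount) / (count_ch + pseudocount))` is used.
#' The pseudocount (default 0.5) guards zero counts; set it to 0 for exact
#' ratios of strictly positive counts.
#'
#' @inheritParams chi_square_region_test
#' @param pseudocount Added to both counts (default 0.5).
#' @param normalize Divide counts by library sizes first (default TRUE).
#' @return Numeric vector of log2 fold changes.
#' @export
compute_log2fc <- function(count_tc, count_ch, lib_tc, lib_ch,
                           pseudocount = 0.5, normalize = TRUE) {
  a <- count_tc + pseudocount
  c_ <- count_ch + pseudocount
  if (normalize) log2((a / lib_tc) / (c_ / lib_ch)) else log2(a / c_)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic BH q-values: order the m p-values increasingly, form
#' `p_(i) * m / i`, enforce monotonicity from the largest rank down, and cap
#' at 1. Output order matches input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  o <- order(p_values, decreasing = TRUE)
  q <- pmin(1, cummin(p_values[o] * m / seq.int(m, 1L)))
  q[order(o)]
}

#' Test merged regions for differential methylation
#'
#' Attaches the chi-square statistic, p-value, BH q-value (adjusted jointly
#' across all supplied regions, after a stable coordinate sort) and the
#' library-normalized log2 fold change to a merged-region table.
#'
#' @param regions Region data frame (`chrom`, `start`, `end`, optionally
#'   `source`) with columns `count_tc` and `count_ch`, or those counts given
#'   separately.
#' @param count_tc,count_ch Optional count vectors overriding region
#'   columns.
#' @param lib_tc,lib_ch Library sizes (total kept fragments per group).
#' @param pseudocount,normalize Passed to [compute_log2fc()].
#' @param method,correct Passed to [chi_square_region_test()].
#' @return `regions` sorted by coordinates with columns `count_tc`,
#'   `count_ch`, `chi2_stat`, `p_value`, `q_value`, `log2fc`.
#' @export
test_regions <- function(regions, lib_tc, lib_ch,
                         count_tc = regions$count_tc,
                         count_ch = regions$count_ch,
                         pseudocount = 0.5, normalize = TRUE,
                         method = "two_by_two", correct = FALSE) {
  stopifnot(!is.null(count_tc), !is.null(count_ch))
  regions$count_tc <- count_tc
  regions$count_ch <- count_ch
  regions <- regions[order(regions$chrom, regions$start, regions$end), ,
                     drop = FALSE]
  rownames(regions) <- NULL
  ct <- chi_square_region_test(regions$count_tc, regions$count_ch,
                               lib_tc, lib_ch, method = method,
                               correct = correct)
  regions$chi2_stat <- ct$statistic
  regions$p_value <- ct$p_value
  regions$q_value <- bh_fdr(ct$p_value)
  regions$log2fc <- compute_log2fc(regions$count_tc, regions$count_ch,
                                   lib_tc, lib_ch,
                                   pseudocount = pseudocount,
                                   normalize = normalize)
  regions
}

#' Call differentially methylated regions
#'
#' Filters tested regions by the standard three-part rule:
#' `p_value < p_cutoff`, `q_value < q_cutoff`, and
#' `|log2fc| >= min_abs_log2fc`; direction is `up` for positive and `down`
#' for negative fold change (TC relative to CH).
#'
#' @param tested Output of [test_regions()].
#' @param p_cutoff,q_cutoff Significance cutoffs (default 0.01, exclusive).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1,
#'   inclusive).
#' @return List with `dmrs` (passing rows plus `dmr_id` and `direction`)
#'   and `summary` (`n_tested`, `n_total`, `n_up`, `n_down`;
#'   `n_up + n_down == n_total`).
#' @export
call_dmrs <- function(tested, p_cutoff = 0.01, q_cutoff = 0.01,
                      min_abs_log2fc = 1) {
  pass <- tested$p_value < p_cutoff & tested$q_value < q_cutoff &
    abs(tested$log2fc) >= min_abs_log2fc
  dmrs <- tested[pass, , drop = FALSE]
  rownames(dmrs) <- NULL
  dmrs$direction <- ifelse(dmrs$log2fc > 0, "up", "down")
  dmrs$dmr_id <- sprintf("dmr_%05d", seq_len(nrow(dmrs)))
  list(dmrs = dmrs,
       summary = list(n_tested = nrow(tested),
                      n_total = nrow(dmrs),
                      n_up = sum(dmrs$direction == "up"),
                      n_down = sum(dmrs$direction == "down")))
}

#' Full two-group DMR analysis from fragments
#'
#' Convenience wrapper chaining per-group peak calling (unless peak sets
#' are supplied), cross-group merging, in-region counting, chi-square
#' testing with BH correction, and DMR filtering.
#'
#' @param tc_fragments,ch_fragments Pooled, QC-passed fragment data frames.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param tc_peaks,ch_peaks Optional externally produced peak sets
#'   (bypassing [call_peaks_simple()]).
#' @param peak_params List of arguments for [call_peaks_simple()].
#' @param dmr_params List of arguments for [call_dmrs()].
#' @param ... Passed to [test_regions()].
#' @return List `peaks_tc`, `peaks_ch`, `regions` (tested), `dmrs`,
#'   `summary`, `lib_tc`, `lib_ch`.
#' @export
dmr_analysis <- function(tc_fragments, ch_fragments, chrom_lengths,
                         tc_peaks = NULL, ch_peaks = NULL,
                         peak_params = list(), dmr_params = list(), ...) {
  if (is.null(tc_peaks))
    tc_peaks <- do.call(call_peaks_simple,
                        c(list(tc_fragments, chrom_lengths), peak_params))
  if (is.null(ch_peaks))
    ch_peaks <- do.call(call_peaks_simple,
                        c(list(ch_fragments, chrom_lengths), peak_params))
  regions <- merge_peak_sets(tc_peaks, ch_peaks)
  lib_tc <- nrow(tc_fragments)
  lib_ch <- nrow(ch_fragments)
  if (nrow(regions) > 0L) {
    regions$count_tc <- count_reads_in_region(regions, tc_fragments)
    regions$count_ch <- count_reads_in_region(regions, ch_fragments)
    tested <- test_regions(regions, lib_tc, lib_ch, ...)
  } else {
    tested <- cbind(regions,
                    data.frame(count_tc = integer(), count_ch = integer(),
                               chi2_stat = numeric(), p_value = numeric(),
                               q_value = numeric(), log2fc = numeric()))
  }
  called <- do.call(call_dmrs, c(list(tested), dmr_params))
  list(peaks_tc = tc_peaks, peaks_ch = ch_peaks, regions = tested,
       dmrs = called$dmrs, summary = called$summary,
       lib_tc = lib_tc, lib_ch = lib_ch)
}
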