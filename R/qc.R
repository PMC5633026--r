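#' Read quality-control parameters
#'
#' Defaults follow the standard MeDIP-seq cleaning rule: discard a fragment
#' if either mate has more than 10% undetermined bases (N) or more than 40%
#' low-quality bases (Phred <= 20), or if it aligned with more than five
#' mismatches or to more than one location.
#'
#' @param max_n_fraction Maximum tolerated N fraction per mate (default 0.10).
#' @param max_lowq_fraction Maximum tolerated fraction of bases at or below
#'   `lowq_threshold` (default 0.40).
#' @param lowq_threshold Phred score at or below which a base counts as
#'   low quality (default 20).
#' @param max_mismatches Maximum alignment mismatches (default 5).
#' @param require_unique Drop multi-mapping fragments (default TRUE).
#' @return A list of class `read_qc_params`.
#' @export
read_qc_params <- function(max_n_fraction = 0.10, max_lowq_fraction = 0.40,
                           lowq_threshold = 20L, max_mismatches = 5L,
                           require_unique = TRUE) {
  stopifnot(max_n_fraction >= 0, max_n_fraction <= 1,
            max_lowq_fraction >= 0, max_lowq_fraction <= 1,
            lowq_threshold >= 0, max_mismatches >= 0)
  structure(list(max_n_fraction = max_n_fraction,
                 max_lowq_fraction = max_lowq_fraction,
                 lowq_threshold = as.integer(lowq_threshold),
                 max_mismatches = as.integer(max_mismatches),
                 require_unique = isTRUE(require_unique)),
            class = "read_qc_params")
}

## count characters in each string whose raw byte is <= cutoff (Phred+33)
.count_le <- function(strings, cutoff_byte) {
  pattern <- sprintf("[^\\x21-\\x%02x]", cutoff_byte)
  nchar(gsub(pattern, "", strings, perl = TRUE))
}

.count_char <- function(strings, char) {
  nchar(strings) - nchar(gsub(char, "", strings, fixed = TRUE))
}

#' Filter aligned fragments by read quality and mapping criteria
#'
#' A fragment is kept iff, for both mates, the N fraction and the
#' low-quality-base fraction are within bounds, and (when the columns are
#' present) `mismatches <= max_mismatches` and `multiplicity == 1`.
#' Qualities are Phred+33 encoded strings in columns `qual1`/`qual2`;
#' sequences in `seq1`/`seq2`. Each rejected fragment is tallied under the
#' first failing reason, in the order N content, low quality, mismatches,
#' multi-mapping.
#'
#' @param fragments Fragment data frame; sequence/quality/mapping columns
#'   optional.
#' @param params A [read_qc_params()] object.
#' @param strict If `TRUE` (default), missing sequence or quality columns
#'   raise an error; if `FALSE`, the corresponding checks are skipped with a
#'   message.
#' @return List with `kept` (fragment data frame) and `tally` (named integer
#'   vector: `input`, `kept`, `n_content`, `low_quality`, `mismatches`,
#'   `multi_mapped`).
#' @export
filter_reads <- function(fragments, params = read_qc_params(),
                         strict = TRUE) {
  n <- nrow(fragments)
  has_seq <- all(c("seq1", "seq2") %in% names(fragments))
  has_qual <- all(c("qual1", "qual2") %in% names(fragments))
  if (strict && (!has_seq || !has_qual))
    stop("fragments lack sequence/quality columns; ",
         "use strict = FALSE to skip the quality checks")
  if (!has_seq || !has_qual)
    message("quality columns absent: N/low-quality checks skipped")
  fail_n <- rep(FALSE, n)
  fail_q <- rep(FALSE, n)
  if (has_seq) {
    for (cc in c("seq1", "seq2")) {
      len <- nchar(fragments[[cc]])
      fail_n <- fail_n | .count_char(fragments[[cc]], "N") >
        params$max_n_fraction * len
    }
  }
  if (has_qual) {
    cutoff <- params$lowq_threshold + 33L
    for (cc in c("qual1", "qual2")) {
      len <- nchar(fragments[[cc]])
      fail_q <- fail_q | .count_le(fragments[[cc]], cutoff) >
        params$max_lowq_fraction * len
    }
  }
  fail_mm <- if ("mismatches" %in% names(fragments))
    fragments$mismatches > params$max_mismatches else rep(FALSE, n)
  fail_mult <- if (params$require_unique &&
                   "multiplicity" %in% names(fragments))
    fragments$multiplicity != 1L else rep(FALSE, n)
  reason <- rep(0L, n)
  reason[fail_mult] <- 4L
  reason[fail_mm] <- 3L
  reason[fail_q] <- 2L
  reason[fail_n] <- 1L
  kept <- fragments[reason == 0L, , drop = FALSE]
  rownames(kept) <- NULL
  tally <- c(input = n, kept = nrow(kept),
             n_content = sum(reason == 1L),
             low_quality = sum(reason == 2L),
             mismatches = sum(reason == 3L),
             multi_mapped = sum(reason == 4L))
  list(kept = kept, tally = tally)
}
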