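#' Genomic interval data frames
#'
#' Throughout medipdiff a set of genomic intervals is a plain `data.frame`
#' with at least the columns `chrom` (character), `start` and `end`
#' (integer-valued, 0-based half-open, BED convention). `gintervals()`
#' builds and validates such a frame; `validate_intervals()` checks an
#' existing one.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors of 0-based half-open coordinates
#'   (`0 <= start < end`).
#' @param ... Further equal-length columns to carry along (e.g. `score`).
#' @return A validated interval `data.frame`.
#' @examples
#' gintervals("chr1", 0, 100)
#' @export
gintervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
}

#' @rdname gintervals
#' @param x An interval `data.frame`.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(x)
  if (anyNA(x$start) || anyNA(x$end) || anyNA(x$chrom))
    stop("intervals contain missing values")
  if (any(x$start < 0))
    stop("interval start < 0")
  if (any(x$start >= x$end))
    stop("interval start >= end")
  x
}

#' Overlap length of two intervals
#'
#' Number of bases shared by intervals `a` and `b` (row-wise if both have
#' several rows, recycling a single row). Intervals on different chromosomes
#' share 0 bp; half-open touching intervals share 0 bp. This is the primitive
#' underlying the ">50% of the shorter peak" merge rule.
#'
#' @param a,b Interval data frames (`chrom`, `start`, `end`).
#' @return Integer vector of overlap widths in bp.
#' @examples
#' overlap_length(gintervals("chr1", 0, 100), gintervals("chr1", 50, 150))
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[idx_a], b$end[idx_b]) - pmax(a$start[idx_a], b$start[idx_b])
  as.integer(pmax(0L, ov) * (a$chrom[idx_a] == b$chrom[idx_b]))
}

## IRanges bridge: medipdiff coordinates are 0-based half-open, IRanges is
## 1-based closed; the +1 happens only here.
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.from_iranges <- function(ir, chrom) {
  data.frame(chrom = rep_len(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

## Union of overlapping intervals per chromosome (touching intervals are
## kept separate: half-open [a,b) + [b,c) do not overlap).
.per_chrom_reduce <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  parts <- lapply(split(df, df$chrom), function(d)
    .from_iranges(IRanges::reduce(.as_iranges(d), min.gapwidth = 0L),
                  d$chrom[1L]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning upper-cased
#' plain character sequences keyed by record id (first whitespace-delimited
#' token of the header).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Chromosome lengths of a sequence set
#'
#' @param sequences Named character vector as returned by [read_fasta()].
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(sequences) {
  stats::setNames(nchar(sequences), names(sequences))
}

#' Read genomic intervals from BED or narrowPeak files
#'
#' BED coordinates (0-based half-open) are kept as-is. For `narrowPeak` the
#' signal/p/q/summit columns are retained. Lines with `start >= end` or a
#' negative start raise an error.
#'
#' @param path Input path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return Interval `data.frame`; extra columns (`name`, `score`, `strand`,
#'   and for narrowPeak `signal`, `pvalue`, `qvalue`, `peak`) when present.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "",
                           colClasses = "character",
                           blank.lines.skip = TRUE)
  if (format == "bed") {
    cols <- c("chrom", "start", "end", "name", "score", "strand")
  } else {
    cols <- c("chrom", "start", "end", "name", "score", "strand",
              "signal", "pvalue", "qvalue", "peak")
    if (ncol(raw) < 10L)
      stop("narrowPeak requires 10 columns, found ", ncol(raw))
  }
  names(raw) <- cols[seq_len(min(ncol(raw), length(cols)))]
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  num_cols <- intersect(c("score", "signal", "pvalue", "qvalue", "peak"),
                        names(raw))
  for (cc in num_cols) raw[[cc]] <- as.numeric(raw[[cc]])
  validate_intervals(raw)
}

#' Write genomic intervals to BED or narrowPeak
#'
#' Inverse of [read_intervals()]: a read-write-read round trip preserves
#' coordinates and retained columns.
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  validate_intervals(x)
  if (format == "bed") {
    ## BED columns are positional: emit the shortest prefix covering all
    ## present optional columns, filling gaps with "." / 0
    want <- c("chrom", "start", "end", "name", "score", "strand")
    keep <- want[seq_len(max(which(want %in% names(x))))]
    out <- data.frame(chrom = x$chrom, stringsAsFactors = FALSE)
    for (cc in keep[-1L]) {
      out[[cc]] <- if (cc %in% names(x)) x[[cc]]
                   else if (cc == "score") 0 else "."
    }
  } else {
    want <- c("chrom", "start", "end", "name", "score", "strand",
              "signal", "pvalue", "qvalue", "peak")
    out <- x
    for (cc in setdiff(want, names(x)))
      out[[cc]] <- if (cc %in% c("name", "strand")) "." else -1
    out <- out[, want, drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write called DMRs as BED6
#'
#' Encodes each differentially methylated region as a BED line with
#' `name = direction` and `score = min(1000, -10 * log10(q))`, the usual
#' capped Phred-style display score.
#'
#' @param dmrs DMR data frame from [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$q_value, 1e-300)), 1))
  out <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = dmrs$direction, score = score, strand = ".",
                    stringsAsFactors = FALSE)
  write_intervals(out, path, "bed")
}

#' Read aligned fragments from a BED file
#'
#' Fragment BED input carries no sequences or qualities, so downstream read
#' QC must run in lenient mode ([filter_reads()] with `strict = FALSE`).
#'
#' @param path Path to a BED3+ file of fragment intervals.
#' @param sample_id Sample identifier attached to every fragment.
#' @return A fragment data frame (`chrom`, `start`, `end`, `sample_id`).
#' @export
read_fragments_bed <- function(path, sample_id) {
  x <- read_intervals(path, "bed")
  data.frame(chrom = x$chrom, start = x$start, end = x$end,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Read aligned fragments from a SAM file
#'
#' Minimal SAM ingestion for paired-end MeDIP fragments: mates are paired by
#' query name, the fragment interval spans the leftmost mate start to the
#' rightmost mate end, and per-mate sequence/quality strings plus the `NM`
#' (mismatches) and `NH` (number of hits, mapping multiplicity) tags are
#' retained for read QC. Unmapped records and unpaired names are dropped.
#'
#' @param path Path to a SAM (text) file.
#' @param sample_id Sample identifier attached to every fragment.
#' @return Fragment data frame with columns `chrom`, `start`, `end`,
#'   `sample_id`, `seq1`, `seq2`, `qual1`, `qual2`, `multiplicity`,
#'   `mismatches`.
#' @export
read_fragments_sam <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sample_id = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  seq <- vapply(fields, `[[`, "", 10L)
  qual <- vapply(fields, `[[`, "", 11L)
  tagval <- function(f, tag) {
    hit <- grep(paste0("^", tag, ":i:"), f[-(1:11)], value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1L])) else NA_integer_
  }
  nm <- vapply(fields, tagval, 1L, tag = "NM")
  nh <- vapply(fields, tagval, 1L, tag = "NH")
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  keep <- mapped
  qname <- qname[keep]; rname <- rname[keep]; pos <- pos[keep]
  seq <- seq[keep]; qual <- qual[keep]; nm <- nm[keep]; nh <- nh[keep]
  first <- bitwAnd(flag[keep], 64L) != 0L
  ends <- pos + nchar(seq) - 1L  # M-only CIGARs assumed for fragment input
  out <- lapply(split(seq_along(qname), qname), function(i) {
    if (length(i) != 2L) return(NULL)
    i <- i[order(!first[i])]  # mate1 first
    if (rname[i[1L]] != rname[i[2L]]) return(NULL)
    data.frame(chrom = rname[i[1L]],
               start = min(pos[i]) - 1L,
               end = max(ends[i]),
               sample_id = sample_id,
               seq1 = seq[i[1L]], seq2 = seq[i[2L]],
               qual1 = qual[i[1L]], qual2 = qual[i[2L]],
               multiplicity = max(1L, nh[i], na.rm = TRUE),
               mismatches = sum(pmax(0L, nm[i]), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
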