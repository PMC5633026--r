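#' Gene element labels in profiling precedence order
#'
#' When one base falls in elements of several genes (or several elements),
#' profiling assigns the single highest-precedence label:
#' `five_utr > cds > three_utr > intron > upstream2k > downstream2k`.
#' `noncoding_exon` (exonic bases of a gene with no annotated CDS) ranks with
#' `cds`.
#'
#' @format Character vector.
#' @export
element_precedence <- c("five_utr", "cds", "noncoding_exon", "three_utr",
                        "intron", "upstream2k", "downstream2k")

#' Construct a gene-model set
#'
#' A `gene_models` object bundles two data frames: `genes` with one row per
#' gene (`gene_id`, `chrom`, `start`, `end`, `strand`; the interval is the
#' gene body, TSS to TTS, 0-based half-open) and `elements` with one row per
#' element sub-interval (`gene_id`, `element`, `chrom`, `start`, `end`).
#' Element labels are `upstream2k`, `five_utr`, `cds`, `intron`,
#' `three_utr`, `downstream2k` (plus `noncoding_exon` for genes without CDS).
#' The 2 kb flanks are strand-oriented and clipped at chromosome bounds.
#'
#' @param genes,elements Data frames as described above.
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, elements) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)),
            all(c("gene_id", "element", "chrom", "start", "end") %in%
                  names(elements)),
            all(genes$strand %in% c("+", "-")))
  validate_intervals(genes)
  if (nrow(elements)) validate_intervals(elements)
  structure(list(genes = genes, elements = elements), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      nrow(x$elements), "element intervals\n")
  invisible(x)
}

## interval difference / intersection helpers on 0-based half-open frames
.ir_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(a[, c("chrom", "start", "end")])
  chrom <- a$chrom[1L]
  res <- IRanges::setdiff(.as_iranges(a), .as_iranges(b))
  .from_iranges(res, chrom)
}

.ir_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  chrom <- a$chrom[1L]
  res <- IRanges::intersect(.as_iranges(a), .as_iranges(b))
  .from_iranges(res, chrom)
}

#' Build gene models from gene, exon and CDS tables
#'
#' Derives the per-gene element map: exons are unioned across transcripts
#' (multi-transcript genes collapse to one model), introns are the gene body
#' minus exons, UTRs are exonic non-CDS bases partitioned by strand (5' of
#' the CDS start is `five_utr`), and 2 kb strand-oriented flanks are clipped
#' at chromosome bounds. Genes without CDS get `noncoding_exon` instead of
#' CDS/UTR labels.
#'
#' @param genes Data frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param exons Data frame `gene_id`, `start`, `end`.
#' @param cds Data frame `gene_id`, `start`, `end` (may be empty).
#' @param chrom_lengths Optional named vector; flanks are clipped to
#'   `[0, length)` when given, at 0 otherwise.
#' @param flank Flank width in bp (default 2000).
#' @return A [gene_models()] object.
#' @export
build_gene_models <- function(genes, exons, cds = NULL,
                              chrom_lengths = NULL, flank = 2000L) {
  stopifnot(nrow(genes) > 0L)
  if (is.null(cds))
    cds <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  exn_by <- split(exons, exons$gene_id)
  cds_by <- split(cds, cds$gene_id)
  el <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    body <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                       stringsAsFactors = FALSE)
    ex <- exn_by[[g$gene_id]]
    if (is.null(ex) || nrow(ex) == 0L) ex <- body
    ex$chrom <- g$chrom
    ex <- .ir_intersect(.per_chrom_reduce(ex), body)
    introns <- .ir_setdiff(body, ex)
    cd <- cds_by[[g$gene_id]]
    rows <- list()
    add <- function(lbl, df) {
      if (nrow(df)) {
        df$gene_id <- g$gene_id
        df$element <- lbl
        rows[[length(rows) + 1L]] <<- df
      }
    }
    if (!is.null(cd) && nrow(cd) > 0L) {
      cd$chrom <- g$chrom
      cd <- .ir_intersect(.per_chrom_reduce(cd), ex)
      cds_lo <- min(cd$start); cds_hi <- max(cd$end)
      left <- .ir_intersect(ex, data.frame(chrom = g$chrom, start = g$start,
                                           end = cds_lo))
      right <- .ir_intersect(ex, data.frame(chrom = g$chrom, start = cds_hi,
                                            end = g$end))
      if (identical(g$strand, "+")) {
        add("five_utr", left); add("three_utr", right)
      } else {
        add("five_utr", right); add("three_utr", left)
      }
      add("cds", cd)
      ## exonic bases inside the CDS span but not CDS (atypical): intronic
      mid <- .ir_setdiff(.ir_intersect(ex, data.frame(chrom = g$chrom,
                                                      start = cds_lo,
                                                      end = cds_hi)), cd)
      add("intron", mid)
    } else {
      add("noncoding_exon", ex)
    }
    add("intron", introns)
    cl <- if (!is.null(chrom_lengths)) unname(chrom_lengths[g$chrom]) else NA
    if (identical(g$strand, "+")) {
      up <- c(max(0L, g$start - flank), g$start)
      dn <- c(g$end, if (is.na(cl)) g$end + flank else min(cl, g$end + flank))
    } else {
      up <- c(g$end, if (is.na(cl)) g$end + flank else min(cl, g$end + flank))
      dn <- c(max(0L, g$start - flank), g$start)
    }
    if (up[2L] > up[1L])
      add("upstream2k", data.frame(chrom = g$chrom, start = up[1L],
                                   end = up[2L]))
    if (dn[2L] > dn[1L])
      add("downstream2k", data.frame(chrom = g$chrom, start = dn[1L],
                                     end = dn[2L]))
    add("gene_body", body)
    el[[i]] <- do.call(rbind, rows)
  }
  elements <- do.call(rbind, el)
  elements <- elements[, c("gene_id", "element", "chrom", "start", "end")]
  rownames(elements) <- NULL
  gene_models(genes, elements)
}

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF via [rtracklayer::import()], collapses
#' transcripts per gene (union of exons, union of CDS), converts the 1-based
#' inclusive GTF coordinates to 0-based half-open, and derives the element
#' map via [build_gene_models()]. Records with unknown strand, or whose CDS
#' falls outside the gene extent, are rejected with a warning.
#'
#' @param path Path to a GTF file with gene/exon/CDS features.
#' @param chrom_lengths Optional named vector used to clip 2 kb flanks.
#' @return A [gene_models()] object.
#' @export
read_gtf_genes <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  if (is.null(df$gene_id)) stop("GTF lacks gene_id attributes")
  df <- df[df$type %in% c("gene", "transcript", "exon", "CDS"), ]
  ## 1-based inclusive -> 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  bad_strand <- unique(df$gene_id[!(df$strand %in% c("+", "-"))])
  if (length(bad_strand)) {
    warning("rejecting ", length(bad_strand), " gene(s) with unknown strand: ",
            paste(utils::head(bad_strand, 5L), collapse = ", "))
    df <- df[!(df$gene_id %in% bad_strand), ]
  }
  if (nrow(df) == 0L) stop("no usable gene records in ", path)
  span <- function(d) {
    data.frame(gene_id = d$gene_id[1L], chrom = d$seqnames[1L],
               start = min(d$start0), end = max(d$end0),
               strand = d$strand[1L], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, lapply(split(df, df$gene_id), span))
  ex <- df[df$type == "exon", c("gene_id", "start0", "end0")]
  if (nrow(ex) == 0L)  # fall back to gene extent as a single exon
    ex <- genes[, c("gene_id", "start", "end")]
  names(ex) <- c("gene_id", "start", "end")
  cd <- df[df$type == "CDS", c("gene_id", "start0", "end0")]
  names(cd) <- c("gene_id", "start", "end")
  ## reject genes whose CDS lies outside the gene extent
  if (nrow(cd)) {
    gidx <- match(cd$gene_id, genes$gene_id)
    outside <- cd$start < genes$start[gidx] | cd$end > genes$end[gidx]
    bad_cds <- unique(cd$gene_id[outside])
    if (length(bad_cds)) {
      warning("rejecting ", length(bad_cds),
              " gene(s) with CDS outside the gene extent: ",
              paste(utils::head(bad_cds, 5L), collapse = ", "))
      genes <- genes[!(genes$gene_id %in% bad_cds), ]
      ex <- ex[!(ex$gene_id %in% bad_cds), ]
      cd <- cd[!(cd$gene_id %in% bad_cds), ]
    }
  }
  if (nrow(genes) == 0L) stop("no usable gene records in ", path)
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  build_gene_models(genes, ex, cd, chrom_lengths = chrom_lengths)
}

#' Write gene models to GTF
#'
#' Emits gene/transcript/exon/CDS lines (one synthetic transcript per gene)
#' in Ensembl attribute dialect, converting back to 1-based inclusive
#' coordinates. Round-trips with [read_gtf_genes()].
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                      g$gene_id, g$gene_id)
    mk <- function(type, s, e, att)
      sprintf("%s\tmedipdiff\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s + 1L, e, g$strand, att)
    lines <- c(lines, mk("gene", g$start, g$end, attr_g),
               mk("transcript", g$start, g$end, attr_t))
    el <- models$elements
    el <- el[el$gene_id == g$gene_id, ]
    for (lbl in c("cds", "noncoding_exon", "five_utr", "three_utr")) {
      ## exons = all exonic element intervals; CDS written separately
      sel <- el[el$element == lbl, ]
      if (nrow(sel) == 0L) next
      type <- if (lbl == "cds") "CDS" else "exon"
      for (j in seq_len(nrow(sel)))
        lines <- c(lines, mk(type, sel$start[j], sel$end[j], attr_t))
    }
    ## CDS intervals are also exonic: emit matching exon lines
    sel <- el[el$element == "cds", ]
    for (j in seq_len(nrow(sel)))
      lines <- c(lines, mk("exon", sel$start[j], sel$end[j], attr_t))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Label genomic positions by gene element
#'
#' Assigns each position the highest-precedence element label across all
#' genes ([element_precedence]); positions in no element are `intergenic`.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based positions.
#' @param models A [gene_models()] object.
#' @return Character vector of labels.
#' @export
label_positions <- function(chrom, pos, models) {
  out <- rep("intergenic", length(pos))
  el <- models$elements
  if (nrow(el) == 0L || length(pos) == 0L) return(out)
  unresolved <- rep(TRUE, length(pos))
  for (lbl in element_precedence) {
    sel <- el[el$element == lbl, ]
    if (nrow(sel) == 0L) next
    for (ch in unique(sel$chrom)) {
      idx <- which(unresolved & chrom == ch)
      if (!length(idx)) next
      q <- IRanges::IRanges(start = pos[idx] + 1L, width = 1L)
      s <- .as_iranges(sel[sel$chrom == ch, ])
      hit <- IRanges::overlapsAny(q, s)
      out[idx[hit]] <- lbl
      unresolved[idx[hit]] <- FALSE
    }
  }
  out
}
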