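# Independent reference implementations used to validate the package's
# optimized code paths. These deliberately use different primitives
# (stats::filter moving sums, all-pairs scans, per-base loops) than the
# implementations they check.

# --- CpG island scanning -------------------------------------------------

# Moving-sum island scanner: same definition as scan_cgis (100 bp windows
# stepped 1 bp, per-position average over covering windows, maximal runs,
# criteria re-checked on the final extent) computed via stats::filter
# convolutions instead of cumulative sums.
oracle_scan_cgis <- function(sequence, window = 100L, min_length = 200L,
                             min_gc = 0.5, min_oe = 0.6) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  L <- length(ch)
  if (L < window) return(data.frame(start = integer(), end = integer()))
  is_c <- as.numeric(ch == "C")
  is_g <- as.numeric(ch == "G")
  is_n <- as.numeric(!(ch %in% c("A", "C", "G", "T")))
  is_cg <- c(as.numeric(ch[-L] == "C" & ch[-1] == "G"), 0)
  movsum <- function(v, k) {
    f <- stats::filter(v, rep(1, k), sides = 1)
    as.numeric(f[k:length(v)])
  }
  wc <- movsum(is_c, window)
  wg <- movsum(is_g, window)
  wn <- movsum(is_n, window)
  wcg <- movsum(is_cg, window)
  # CG dinucleotides fully inside window [i, i+w-1]: exclude one starting
  # at the last base
  wcg <- wcg - is_cg[seq(window, L)]
  gc <- (wc + wg) / window
  oe <- ifelse(wc * wg > 0, wcg * window / (wc * wg), 0)
  gc[wn > 0] <- 0
  oe[wn > 0] <- 0
  nw <- length(gc)
  # position p (1-based) is covered by windows starting p-window+1 .. p
  lo <- pmax(1, seq_len(L) - window + 1)
  hi <- pmin(nw, seq_len(L))
  cum_gc <- c(0, cumsum(gc)); cum_oe <- c(0, cumsum(oe))
  avg_gc <- (cum_gc[hi + 1] - cum_gc[lo]) / (hi - lo + 1)
  avg_oe <- (cum_oe[hi + 1] - cum_oe[lo]) / (hi - lo + 1)
  ok <- (lo <= hi) & avg_gc > min_gc & avg_oe > min_oe
  r <- rle(ok)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1
  out <- list()
  for (k in which(r$values & r$lengths > min_length)) {
    seg <- ch[s[k]:e[k]]
    len <- length(seg)
    ngc <- sum(seg %in% c("C", "G"))
    nc <- sum(seg == "C"); ng <- sum(seg == "G")
    ncg <- sum(seg[-len] == "C" & seg[-1] == "G")
    gcf <- ngc / len
    oef <- if (nc > 0 && ng > 0) ncg * len / (nc * ng) else 0
    if (gcf > min_gc && oef > min_oe)
      out[[length(out) + 1]] <- data.frame(start = s[k] - 1L, end = e[k])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(), end = integer())
}

# Direct dinucleotide count by substring inspection.
oracle_cpg_oe <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  ncg <- 0L
  if (L >= 2) for (i in 1:(L - 1))
    if (substr(s, i, i + 1) == "CG") ncg <- ncg + 1L
  nc <- 0L; ng <- 0L
  for (i in 1:L) {
    b <- substr(s, i, i)
    if (b == "C") nc <- nc + 1L
    if (b == "G") ng <- ng + 1L
  }
  if (nc == 0L || ng == 0L) return(0)
  ncg * L / (nc * ng)
}

# --- peak merging --------------------------------------------------------

# All-pairs implementation of the >50%-of-shorter-peak rule with igraph
# connected components.
oracle_merge_peak_sets <- function(tc, ch, frac = 0.5) {
  reduce_df <- function(p) {
    if (nrow(p) == 0) return(p[, c("chrom", "start", "end")])
    out <- list()
    for (cc in unique(p$chrom)) {
      d <- p[p$chrom == cc, ]
      d <- d[order(d$start, d$end), ]
      cs <- d$start[1]; ce <- d$end[1]
      for (i in seq_len(nrow(d))[-1]) {
        if (d$start[i] < ce) ce <- max(ce, d$end[i])
        else { out[[length(out) + 1]] <- data.frame(chrom = cc, start = cs,
                                                    end = ce); cs <- d$start[i]; ce <- d$end[i] }
      }
      out[[length(out) + 1]] <- data.frame(chrom = cc, start = cs, end = ce)
    }
    do.call(rbind, out)
  }
  tc <- reduce_df(tc); ch <- reduce_df(ch)
  n1 <- nrow(tc); n2 <- nrow(ch)
  all <- rbind(cbind(tc, group = "TC"), cbind(ch, group = "CH"))
  n <- nrow(all)
  if (n == 0) return(data.frame(chrom = character(), start = integer(),
                                end = integer(), source = character()))
  edges <- integer(0)
  if (n1 > 0 && n2 > 0) {
    # all pairs, no sorting/index structure: outer comparisons
    same <- outer(tc$chrom, ch$chrom, "==")
    ov <- outer(tc$end, ch$end, pmin) - outer(tc$start, ch$start, pmax)
    shorter <- outer(tc$end - tc$start, ch$end - ch$start, pmin)
    qual <- which(same & ov > frac * shorter, arr.ind = TRUE)
    if (nrow(qual))
      edges <- as.vector(rbind(qual[, 1], n1 + qual[, 2]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    grp <- unique(all$group[idx])
    data.frame(chrom = all$chrom[idx[1]], start = min(all$start[idx]),
               end = max(all$end[idx]),
               source = if (length(grp) == 2) "merged"
                        else paste0(grp, "_unique"))
  }))
  out <- out[order(out$chrom, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# --- gene element labelling ----------------------------------------------

# Per-base labeller working directly from exon/CDS structure, not from the
# derived element intervals.
oracle_label_base <- function(pos, gene, exons, cds) {
  # gene: one row (chrom, start, end, strand); exons/cds: interval dfs
  inside <- function(df) any(df$start <= pos & pos < df$end)
  if (gene$start <= pos && pos < gene$end) {
    if (!inside(exons)) return("intron")
    if (nrow(cds) && inside(cds)) return("cds")
    if (!nrow(cds)) return("noncoding_exon")
    lo <- min(cds$start); hi <- max(cds$end)
    if (pos < lo) return(if (gene$strand == "+") "five_utr" else "three_utr")
    if (pos >= hi) return(if (gene$strand == "+") "three_utr" else "five_utr")
    return("intron")  # exonic inside CDS span but not CDS: atypical
  }
  if (gene$strand == "+") {
    if (pos >= gene$start - 2000 && pos < gene$start) return("upstream2k")
    if (pos >= gene$end && pos < gene$end + 2000) return("downstream2k")
  } else {
    if (pos >= gene$end && pos < gene$end + 2000) return("upstream2k")
    if (pos >= gene$start - 2000 && pos < gene$start) return("downstream2k")
  }
  "outside"
}

# --- misc ----------------------------------------------------------------

# Random DNA string with given GC content.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
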