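## finest element label given a set of hit labels
.finest_label <- function(labels) {
  hit <- element_precedence[element_precedence %in% labels]
  if (length(hit)) hit[1L] else "intergenic"
}

#' Annotate DMRs with genes and genomic elements
#'
#' A gene is differentially methylated (DMG) when at least one DMR overlaps
#' (by >= 1 bp) its annotation span: gene body, 2 kb upstream, or 2 kb
#' downstream. Each DMR is labelled with every gene hit and with the hit
#' elements (finest label chosen by [element_precedence] for the per-DMR
#' summary); DMRs hitting no gene span are `intergenic`. DMRs overlapping
#' any `upstream2k` interval form the promoter-DMR table.
#'
#' @param dmrs DMR data frame from [call_dmrs()] (needs `dmr_id`, `chrom`,
#'   `start`, `end`, `log2fc`, `q_value`, `direction`).
#' @param models A [gene_models()] object.
#' @return List:
#'   * `dmgs`: per-gene table (`gene_id`, `n_dmrs`, `dmr_ids`, `regions`
#'     (coarse labels hit), `elements` (fine labels hit), `best_log2fc`,
#'     `best_q` of the most significant DMR);
#'   * `dmr_gene_hits`: one row per (DMR, gene) pair with hit labels;
#'   * `dmr_elements`: per-DMR finest element label (named by `dmr_id`);
#'   * `promoter_dmrs`: DMRs overlapping a promoter (2 kb upstream), with
#'     the promoter's gene;
#'   * `promoter_summary`: list `n_total`, `n_up`, `n_down`.
#' @export
annotate_dmrs <- function(dmrs, models) {
  el <- models$elements
  genes <- models$genes
  if (is.null(dmrs$dmr_id))
    dmrs$dmr_id <- sprintf("dmr_%05d", seq_len(nrow(dmrs)))
  hits <- list()
  if (nrow(dmrs) > 0L && nrow(el) > 0L) {
    for (ch in intersect(unique(dmrs$chrom), unique(el$chrom))) {
      di <- which(dmrs$chrom == ch)
      ei <- which(el$chrom == ch)
      h <- IRanges::findOverlaps(.as_iranges(dmrs[di, , drop = FALSE]),
                                 .as_iranges(el[ei, , drop = FALSE]),
                                 minoverlap = 1L)
      if (!length(h)) next
      hits[[length(hits) + 1L]] <- data.frame(
        dmr_id = dmrs$dmr_id[di[S4Vectors::queryHits(h)]],
        gene_id = el$gene_id[ei[S4Vectors::subjectHits(h)]],
        element = el$element[ei[S4Vectors::subjectHits(h)]],
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(dmr_id = character(), gene_id = character(),
               element = character(), stringsAsFactors = FALSE)
  ## coarse span labels come directly: upstream2k / gene_body / downstream2k
  coarse <- hits[hits$element %in% c("upstream2k", "gene_body",
                                     "downstream2k"), ]
  fine <- hits[!(hits$element %in% "gene_body"), ]
  dmr_idx <- match(hits$dmr_id, dmrs$dmr_id)
  ## per-DMR finest label across all genes
  dmr_elements <- stats::setNames(rep("intergenic", nrow(dmrs)), dmrs$dmr_id)
  if (nrow(fine)) {
    by_dmr <- split(fine$element, fine$dmr_id)
    dmr_elements[names(by_dmr)] <- vapply(by_dmr, .finest_label, "")
  }
  ## DMG table: any overlap with the annotation span
  dmgs <- data.frame(gene_id = character(), n_dmrs = integer(),
                     dmr_ids = character(), regions = character(),
                     elements = character(), best_log2fc = numeric(),
                     best_q = numeric(), stringsAsFactors = FALSE)
  if (nrow(coarse)) {
    dmgs <- do.call(rbind, lapply(split(coarse, coarse$gene_id), function(d) {
      g_fine <- fine[fine$gene_id == d$gene_id[1L], ]
      ids <- unique(d$dmr_id)
      ridx <- match(ids, dmrs$dmr_id)
      best <- ridx[which.min(dmrs$q_value[ridx])]
      data.frame(gene_id = d$gene_id[1L],
                 n_dmrs = length(ids),
                 dmr_ids = paste(sort(ids), collapse = ","),
                 regions = paste(sort(unique(d$element)), collapse = ","),
                 elements = paste(sort(unique(g_fine$element)),
                                  collapse = ","),
                 best_log2fc = dmrs$log2fc[best],
                 best_q = dmrs$q_value[best],
                 stringsAsFactors = FALSE)
    }))
    dmgs <- dmgs[order(dmgs$gene_id), , drop = FALSE]
    rownames(dmgs) <- NULL
  }
  ## promoter table
  prom_hits <- hits[hits$element == "upstream2k", ]
  prom_ids <- unique(prom_hits$dmr_id)
  promoter_dmrs <- dmrs[dmrs$dmr_id %in% prom_ids, , drop = FALSE]
  if (nrow(promoter_dmrs)) {
    gene_by_dmr <- vapply(split(prom_hits$gene_id, prom_hits$dmr_id),
                          function(g) paste(sort(unique(g)), collapse = ","),
                          "")
    promoter_dmrs$promoter_genes <- gene_by_dmr[promoter_dmrs$dmr_id]
  } else {
    promoter_dmrs$promoter_genes <- character(0)
  }
  rownames(promoter_dmrs) <- NULL
  list(dmgs = dmgs,
       dmr_gene_hits = hits,
       dmr_elements = dmr_elements,
       promoter_dmrs = promoter_dmrs,
       promoter_summary = list(
         n_total = nrow(promoter_dmrs),
         n_up = sum(promoter_dmrs$direction == "up"),
         n_down = sum(promoter_dmrs$direction == "down")))
}

#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification: per sample, `dCt = Ct_target -
#' Ct_reference`; `ddCt = mean dCt(test group) - mean dCt(calibrator
#' group)`; fold change `2^-ddCt`, so `log2fc_expression = -ddCt`. Samples
#' missing either Ct are dropped with a warning; a group left without
#' samples is an error.
#'
#' @param ct_table Data frame with columns `sample_id`, `group`, `gene_id`,
#'   `ct_target`, `ct_reference`.
#' @param target_gene Gene to quantify (rows with this `gene_id`).
#' @param test_group,calibrator_group Group labels (defaults `"TC"` vs
#'   calibrator `"CH"`).
#' @return One-row data frame: `gene_id`, `n_test`, `n_calibrator`,
#'   `mean_dct_test`, `mean_dct_calibrator`, `sd_dct_test`,
#'   `sd_dct_calibrator`, `ddct`, `fold_change`, `log2fc_expression`.
#' @examples
#' ct <- data.frame(sample_id = c("t1", "c1"), group = c("TC", "CH"),
#'                  gene_id = "G", ct_target = c(22, 24),
#'                  ct_reference = c(20, 20))
#' ddct_fold_change(ct, "G")  # fold change 4
#' @export
ddct_fold_change <- function(ct_table, target_gene,
                             test_group = "TC", calibrator_group = "CH") {
  rows <- ct_table[ct_table$gene_id == target_gene, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no Ct rows for gene ", target_gene)
  bad <- !is.finite(rows$ct_target) | !is.finite(rows$ct_reference) |
    rows$ct_target <= 0 | rows$ct_reference <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " sample(s) of ", target_gene,
            " with missing or non-positive Ct")
    rows <- rows[!bad, , drop = FALSE]
  }
  dct <- rows$ct_target - rows$ct_reference
  tt <- rows$group == test_group
  cc <- rows$group == calibrator_group
  if (!any(tt)) stop("no usable samples in test group ", test_group)
  if (!any(cc)) stop("no usable samples in calibrator group ",
                     calibrator_group)
  ddct <- mean(dct[tt]) - mean(dct[cc])
  data.frame(gene_id = target_gene,
             n_test = sum(tt), n_calibrator = sum(cc),
             mean_dct_test = mean(dct[tt]),
             mean_dct_calibrator = mean(dct[cc]),
             sd_dct_test = stats::sd(dct[tt]),
             sd_dct_calibrator = stats::sd(dct[cc]),
             ddct = ddct,
             fold_change = 2^(-ddct),
             log2fc_expression = -ddct,
             stringsAsFactors = FALSE)
}

#' Methylation-expression sign concordance
#'
#' Joins expression fold changes with per-gene methylation fold changes and
#' flags genes where the signs oppose (lower methylation with higher
#' expression, or vice versa), the pattern expected when promoter/gene
#' methylation represses transcription.
#'
#' @param expression_results Data frame with `gene_id` and
#'   `log2fc_expression` (e.g. rows from [ddct_fold_change()]).
#' @param dmg_records Data frame with `gene_id` and `best_log2fc`
#'   (methylation), e.g. `dmgs` from [annotate_dmrs()].
#' @return Data frame `gene_id`, `log2fc_methylation`, `log2fc_expression`,
#'   `concordant`; attribute `concordant_fraction`.
#' @export
concordance_report <- function(expression_results, dmg_records) {
  m <- merge(expression_results[, c("gene_id", "log2fc_expression")],
             data.frame(gene_id = dmg_records$gene_id,
                        log2fc_methylation = dmg_records$best_log2fc,
                        stringsAsFactors = FALSE),
             by = "gene_id")
  m$concordant <- m$log2fc_expression * m$log2fc_methylation < 0
  m <- m[order(m$gene_id),
         c("gene_id", "log2fc_methylation", "log2fc_expression",
           "concordant")]
  rownames(m) <- NULL
  attr(m, "concordant_fraction") <-
    if (nrow(m)) mean(m$concordant) else NA_real_
  m
}
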