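#' Build a pipeline run configuration
#'
#' Either `simulate` is given (a [sim_config()] or a list of its arguments)
#' and the study is generated in-run, or `inputs` points at existing data:
#' `genome_fasta`, `gtf`, and `fragments` (data frame or list with `path`,
#' `sample_id`, `group` per sample; BED or SAM). Optional `ct_table` (TSV
#' path or data frame) enables the qPCR concordance stage.
#'
#' @param seed Integer seed recorded in the manifest and used for every
#'   source of randomness.
#' @param simulate `NULL`, a [sim_config()], or a list of [sim_config()]
#'   arguments (its `seed` is forced to `seed`).
#' @param inputs List of input paths (see above) when not simulating.
#' @param qc List of [read_qc_params()] arguments.
#' @param peaks List of [call_peaks_simple()] arguments.
#' @param dmr List with `p_cutoff`, `q_cutoff`, `min_abs_log2fc`,
#'   `pseudocount`, `normalize`, `method`, `correct`.
#' @param profiles Logical: compute coverage profiles (default TRUE).
#' @param ct_table Optional Ct table path or data frame (overrides a
#'   simulated one).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, simulate = list(), inputs = NULL,
                       qc = list(), peaks = list(), dmr = list(),
                       profiles = TRUE, ct_table = NULL) {
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    simulate$seed <- seed
    simulate <- do.call(sim_config, simulate)
  }
  if (is.null(simulate) && is.null(inputs))
    stop("either 'simulate' or 'inputs' must be given")
  if (!is.null(inputs)) {
    for (f in c("genome_fasta", "gtf"))
      if (!is.null(inputs[[f]]) && !file.exists(inputs[[f]]))
        stop("input file does not exist: ", inputs[[f]])
  }
  structure(list(seed = as.integer(seed), simulate = simulate,
                 inputs = inputs, qc = qc, peaks = peaks, dmr = dmr,
                 profiles = isTRUE(profiles), ct_table = ct_table),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the [run_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full differential-methylation pipeline
#'
#' Stages: obtain data (simulate or read) -> read QC -> pooling per group
#' -> coverage profiles (optional) -> per-group peak calling -> cross-group
#' merging -> chi-square testing with BH correction -> DMR filtering ->
#' gene annotation -> qPCR concordance (when a Ct table is available).
#' All outputs are written under `outdir`; the JSON manifest records the
#' seed, parameters and per-stage record counts. Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param config A [run_config()] object (or YAML path).
#' @param outdir Output directory.
#' @return The manifest list, invisibly. Side effects: files under
#'   `outdir` (`peaks_TC.bed`, `peaks_CH.bed`, `merged_regions.tsv`,
#'   `dmrs.tsv`, `dmrs.bed`, `dmgs.tsv`, `promoter_dmrs.tsv`,
#'   `profiles/*.tsv`, `concordance.tsv`, `manifest.json`, and the
#'   simulated study under `sim/` when simulating).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "medipdiff",
                   version = as.character(utils::packageVersion("medipdiff")),
                   seed = config$seed)
  ## --- stage: data ---------------------------------------------------
  ct_table <- NULL
  if (!is.null(config$simulate)) {
    study <- simulate_study(config$simulate, dir = file.path(outdir, "sim"))
    sequences <- study$genome$sequences
    models <- study$genome$gene_models
    cl <- study$genome$chrom_lengths
    frag_list <- study$frags$fragments
    samples <- study$frags$samples
    if (nrow(study$ct_table)) ct_table <- study$ct_table
    manifest$simulated <- TRUE
    manifest$sim_truth <- list(
      n_true_dmrs = sum(study$methylomes$truth$kind %in%
                          c("dmr_up", "dmr_down")),
      n_null_peaks = sum(study$methylomes$truth$kind == "null_peak"),
      n_cgis = nrow(study$genome$cgi_truth))
  } else {
    inp <- config$inputs
    sequences <- if (!is.null(inp$genome_fasta))
      read_fasta(inp$genome_fasta) else NULL
    cl <- if (!is.null(sequences)) chrom_lengths(sequences)
      else stats::setNames(as.integer(inp$chrom_lengths),
                           names(inp$chrom_lengths))
    models <- if (!is.null(inp$gtf))
      read_gtf_genes(inp$gtf, chrom_lengths = cl) else NULL
    ft <- inp$fragments
    if (is.data.frame(ft)) ft <- split(ft, seq_len(nrow(ft)))
    frag_list <- list()
    samples <- data.frame(sample_id = character(), group = character(),
                          stringsAsFactors = FALSE)
    for (f in ft) {
      fr <- if (grepl("\\.sam$", f$path))
        read_fragments_sam(f$path, f$sample_id)
      else read_fragments_bed(f$path, f$sample_id)
      frag_list[[f$sample_id]] <- fr
      samples <- rbind(samples,
                       data.frame(sample_id = f$sample_id, group = f$group,
                                  stringsAsFactors = FALSE))
    }
    manifest$simulated <- FALSE
  }
  if (!is.null(config$ct_table)) {
    ct_table <- if (is.character(config$ct_table))
      utils::read.table(config$ct_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else config$ct_table
  }
  ## --- stage: read QC ------------------------------------------------
  qc_params <- do.call(read_qc_params, config$qc)
  qc_tallies <- list()
  for (sid in names(frag_list)) {
    has_qual <- all(c("seq1", "qual1") %in% names(frag_list[[sid]]))
    res <- filter_reads(frag_list[[sid]], qc_params, strict = has_qual)
    frag_list[[sid]] <- res$kept
    qc_tallies[[sid]] <- as.list(res$tally)
  }
  manifest$qc <- qc_tallies
  ## --- stage: pool replicates per group -------------------------------
  core_cols <- c("chrom", "start", "end", "sample_id")
  pool <- function(grp) {
    ids <- samples$sample_id[samples$group == grp]
    out <- do.call(rbind, lapply(frag_list[ids], function(d)
      d[, core_cols, drop = FALSE]))
    rownames(out) <- NULL
    out
  }
  frags_tc <- pool("TC")
  frags_ch <- pool("CH")
  manifest$pooled <- list(TC = nrow(frags_tc), CH = nrow(frags_ch))
  ## --- stage: profiles ------------------------------------------------
  if (config$profiles && !is.null(sequences)) {
    pdir <- file.path(outdir, "profiles")
    dir.create(pdir, showWarnings = FALSE)
    cgis <- scan_cgis_genome(sequences)
    both <- list(TC = frags_tc, CH = frags_ch)
    prof <- function(fn, file, ...) {
      out <- do.call(rbind, lapply(names(both), function(g)
        cbind(group = g, fn(both[[g]], ...), stringsAsFactors = FALSE)))
      .write_tsv(out, file.path(pdir, file))
    }
    prof(chromosome_profile, "chromosome_windows.tsv", cl)
    prof(cpg_density_profile, "cpg_density.tsv", sequences)
    if (!is.null(models)) {
      prof(element_distribution, "element_distribution.tsv", models)
      prof(metagene_profile, "metagene_genes.tsv", models, cl)
    }
    if (nrow(cgis))
      prof(metagene_profile, "metagene_cgis.tsv",
           cgis[, c("chrom", "start", "end")], cl)
    manifest$profiles <- list(n_cgis_detected = nrow(cgis))
  }
  ## --- stage: peaks, merge, test, call --------------------------------
  res <- dmr_analysis(frags_tc, frags_ch, cl,
                      peak_params = config$peaks,
                      dmr_params = config$dmr[intersect(
                        names(config$dmr),
                        c("p_cutoff", "q_cutoff", "min_abs_log2fc"))],
                      pseudocount = config$dmr$pseudocount %||% 0.5,
                      normalize = config$dmr$normalize %||% TRUE,
                      method = config$dmr$method %||% "two_by_two",
                      correct = config$dmr$correct %||% FALSE)
  write_intervals(res$peaks_tc, file.path(outdir, "peaks_TC.bed"), "bed")
  write_intervals(res$peaks_ch, file.path(outdir, "peaks_CH.bed"), "bed")
  .write_tsv(res$regions, file.path(outdir, "merged_regions.tsv"))
  manifest$peaks <- list(TC = nrow(res$peaks_tc), CH = nrow(res$peaks_ch))
  manifest$regions <- list(
    n_total = nrow(res$regions),
    n_merged = sum(res$regions$source == "merged"),
    n_tc_unique = sum(res$regions$source == "TC_unique"),
    n_ch_unique = sum(res$regions$source == "CH_unique"))
  manifest$libraries <- list(TC = res$lib_tc, CH = res$lib_ch)
  ## --- stage: annotate -------------------------------------------------
  dmrs <- res$dmrs
  if (!is.null(models)) {
    ann <- annotate_dmrs(dmrs, models)
    dmrs$element_label <- unname(ann$dmr_elements[dmrs$dmr_id])
    .write_tsv(ann$dmgs, file.path(outdir, "dmgs.tsv"))
    .write_tsv(ann$promoter_dmrs, file.path(outdir, "promoter_dmrs.tsv"))
    manifest$annotation <- list(n_dmgs = nrow(ann$dmgs),
                                promoter = ann$promoter_summary)
  }
  .write_tsv(dmrs, file.path(outdir, "dmrs.tsv"))
  if (nrow(dmrs)) write_dmr_bed(dmrs, file.path(outdir, "dmrs.bed"))
  else writeLines(character(0), file.path(outdir, "dmrs.bed"))
  manifest$dmrs <- res$summary
  ## --- stage: qPCR concordance ----------------------------------------
  if (!is.null(ct_table) && !is.null(models) && nrow(ct_table)) {
    targets <- setdiff(unique(ct_table$gene_id), character(0))
    expr <- do.call(rbind, lapply(targets, function(g)
      ddct_fold_change(ct_table, g)))
    if (exists("ann") && nrow(ann$dmgs)) {
      conc <- concordance_report(expr, ann$dmgs)
      .write_tsv(conc, file.path(outdir, "concordance.tsv"))
      manifest$qpcr <- list(
        n_genes_tested = nrow(expr),
        n_genes_matched = nrow(conc),
        concordant_fraction = attr(conc, "concordant_fraction"))
    }
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
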