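#' Run the full DMR pipeline from files on disk
#'
#' Executes every stage in order — load counts, estimate spike-in
#' non-conversion, per-site RMS permutation tests, FDR cutoff selection,
#' DMR assembly and filtering, gene/TE/expression annotation, and (when a
#' recovery group is present) persistence classification and sample
#' clustering — and writes each stage's output plus a structured log and a
#' machine-readable summary into `out_dir`.  A rerun with the same inputs
#' and seed is byte-identical.
#'
#' @param input_dir Directory holding `samples.tsv` (with `allc_path`),
#'   `genes.gff3` (or `.gff`), `tes.bed`, and optionally `de.tsv` — the
#'   layout written by [write_simulation()].
#' @param out_dir Output directory (created).
#' @param config [dmr_config()] bundle; profiles set the FDR/filter
#'   thresholds.
#' @param spike_in_chrom Spike-in chromosome name, or `NA` for none.
#' @return Invisibly, a list with `dmrs`, `annotated`, `persistence`,
#'   `summary`.
#' @export
run_pipeline <- function(input_dir, out_dir, config = dmr_config(),
                         spike_in_chrom = "lambda") {
  t0 <- Sys.time()
  sheet_path <- file.path(input_dir, "samples.tsv")
  if (!file.exists(sheet_path))
    stop("config error: sample sheet not found at ", sheet_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)

  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"),
             file.path(out_dir, "config.json"))
  cfg_hash <- unname(tools::md5sum(file.path(out_dir, "config.json")))
  logf("config", "profile=%s hash=%s", config$profile, cfg_hash)

  sheet <- read_sample_sheet(sheet_path)
  ms <- methylome_set(sheet, spike_in_chrom = spike_in_chrom)
  groups <- design_groups(ms$samples)
  logf("load", "sites=%d samples=%d", nrow(ms$sites), ncol(ms$mc))

  gene_path <- Filter(file.exists,
                      file.path(input_dir, c("genes.gff3", "genes.gff",
                                             "genes.bed")))[1]
  te_path <- Filter(file.exists,
                    file.path(input_dir, c("tes.bed", "tes.gff3")))[1]
  if (is.na(gene_path) || is.na(te_path))
    stop("config error: gene/TE annotation not found in ", input_dir)
  genes <- read_features(gene_path, "gene")
  tes <- read_features(te_path, "te")
  de <- if (file.exists(file.path(input_dir, "de.tsv")))
    read_de_table(file.path(input_dir, "de.tsv")) else NULL
  logf("annotation", "genes=%d tes=%d de_genes=%d", nrow(genes), nrow(tes),
       if (is.null(de)) 0L else nrow(de))

  disc_groups <- groups[c("control", "stress")]
  dmrs <- call_dmrs(ms, disc_groups, config)
  cal <- attr(dmrs, "calibration")
  site_res <- attr(dmrs, "site_results")
  logf("site_test", "tested=%d cutoff=%.6g n_significant=%d",
       sum(site_res$tested), cal$pvalue_cutoff, cal$n_significant)
  logf("dmr", "n_dmrs=%d hyper=%d hypo=%d", nrow(dmrs),
       sum(dmrs$direction == "hyper"), sum(dmrs$direction == "hypo"))
  utils::write.table(site_res, file.path(out_dir, "site_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_dmrs(dmrs, file.path(out_dir, "dmrs.tsv"))

  ann <- if (nrow(dmrs))
    annotate_dmrs(dmrs, genes, tes, de, alpha = 0.05) else as.data.frame(dmrs)
  if (nrow(ann))
    utils::write.table(ann, file.path(out_dir, "dmrs_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  logf("annotate", "te_overlap=%d/%d", sum(ann$te_overlap %||% logical()),
       nrow(ann))

  persistence <- NULL
  lev <- attr(dmrs, "sample_levels")
  if (!is.null(groups$recovery) && nrow(dmrs)) {
    persistence <- classify_persistence(lev, groups,
                                        alpha = config$alpha_persistence)
    utils::write.table(persistence, file.path(out_dir, "persistence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("temporal", "persistent=%d transient=%d ambiguous=%d",
         sum(persistence$call == "persistent"),
         sum(persistence$call == "transient"),
         sum(persistence$call == "ambiguous"))
  }
  if (nrow(dmrs) >= 1L && ncol(lev) >= 2L && any(stats::complete.cases(lev)))
    cluster_samples(lev, newick_path = file.path(out_dir, "sample_tree.nwk"))

  summary <- list(config_hash = cfg_hash, profile = config$profile,
                  n_sites = nrow(ms$sites), n_samples = ncol(ms$mc),
                  n_sites_tested = sum(site_res$tested),
                  pvalue_cutoff = cal$pvalue_cutoff,
                  n_significant_sites = cal$n_significant,
                  n_dmrs = nrow(dmrs),
                  n_hyper = sum(dmrs$direction == "hyper"),
                  n_hypo = sum(dmrs$direction == "hypo"),
                  prop_te_overlap = if (nrow(ann)) mean(ann$te_overlap) else NA,
                  n_persistent = if (is.null(persistence)) NA else
                    sum(persistence$call == "persistent"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  logf("done", "elapsed=%.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(dmrs = dmrs, annotated = ann, persistence = persistence,
                 summary = summary))
}
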