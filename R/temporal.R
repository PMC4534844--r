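#' Two-sample t-test on per-sample region levels
#'
#' Welch's unequal-variance t-test by default (Student's pooled-variance
#' variant via `var_equal = TRUE`).  Degenerate inputs — fewer than two
#' non-missing values in a group, or zero variance in both groups — are
#' untestable and return `NA` statistics rather than an error, so callers
#' can mark the region untestable.
#'
#' @param levels_a,levels_b Numeric level vectors (NA = missing sample).
#' @param var_equal Use the pooled-variance t-test (default FALSE = Welch).
#' @return List with `t_stat`, `pvalue`, `mean_a`, `mean_b`, `testable`.
#' @export
group_ttest <- function(levels_a, levels_b, var_equal = FALSE) {
  a <- levels_a[!is.na(levels_a)]
  b <- levels_b[!is.na(levels_b)]
  out <- list(t_stat = NA_real_, pvalue = NA_real_,
              mean_a = mean(a), mean_b = mean(b), testable = FALSE)
  if (length(a) < 2L || length(b) < 2L) return(out)
  if (stats::var(a) == 0 && stats::var(b) == 0) return(out)
  tt <- stats::t.test(a, b, var.equal = var_equal)
  out$t_stat <- unname(tt$statistic)
  out$pvalue <- tt$p.value
  out$testable <- TRUE
  out
}

#' t-test one group pair across all regions of a level matrix
#'
#' Runs [group_ttest()] per region and applies Benjamini-Hochberg
#' adjustment across the regions of this comparison family (untestable
#' regions are excluded from the family size).
#'
#' @param level_matrix Regions x samples matrix of corrected levels.
#' @param samples_a,samples_b Column names (sample ids) of the two groups.
#' @param var_equal Passed to [group_ttest()].
#' @return data.frame: dmr_id, mean_a, mean_b, t_stat, pvalue, qvalue,
#'   testable.
#' @export
compare_groups <- function(level_matrix, samples_a, samples_b,
                           var_equal = FALSE) {
  res <- lapply(seq_len(nrow(level_matrix)), function(i)
    group_ttest(level_matrix[i, samples_a], level_matrix[i, samples_b],
                var_equal))
  out <- data.frame(dmr_id = rownames(level_matrix) %||%
                      paste0("region_", seq_len(nrow(level_matrix))),
                    mean_a = vapply(res, `[[`, numeric(1), "mean_a"),
                    mean_b = vapply(res, `[[`, numeric(1), "mean_b"),
                    t_stat = vapply(res, `[[`, numeric(1), "t_stat"),
                    pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
                    testable = vapply(res, `[[`, logical(1), "testable"),
                    stringsAsFactors = FALSE)
  out$qvalue <- NA_real_
  out$qvalue[out$testable] <- bh_adjust(out$pvalue[out$testable])
  out
}

#' Classify DMR persistence across control / stress / recovery groups
#'
#' A region's methylation difference is `persistent` when it is significant
#' between control and stress, still significant between recovery and
#' control, and not significant between stress and recovery (the recovered
#' tissue retains the stressed state).  It is `transient` when the
#' control-stress difference is significant but recovery has returned to
#' the control state (recovery-vs-control not significant).  Anything else
#' — including regions where the stress effect itself is not significant —
#' is `ambiguous`.  Significance is BH-adjusted within each comparison
#' family; note that calling "not significant" accepts a null, so the
#' evidence q-values are retained alongside the call.
#'
#' @param level_matrix Regions x samples matrix of corrected CNN levels.
#' @param groups Named list with `control`, `stress` and `recovery`
#'   sample-id vectors (>= 2 replicates each).
#' @param alpha Significance threshold on the q-values (default 0.05; the
#'   panicle-style profile uses 0.1).
#' @param var_equal Passed to [group_ttest()].
#' @return data.frame per region: dmr_id, call, q_control_stress,
#'   q_recovery_control, q_stress_recovery, and the three group means.
#' @export
classify_persistence <- function(level_matrix, groups, alpha = 0.05,
                                 var_equal = FALSE) {
  need <- c("control", "stress", "recovery")
  if (!all(need %in% names(groups)))
    stop("groups must name control, stress and recovery samples")
  if (any(vapply(groups[need], length, integer(1)) < 2L))
    stop("each group needs >= 2 replicates")
  cs <- compare_groups(level_matrix, groups$control, groups$stress, var_equal)
  rc <- compare_groups(level_matrix, groups$recovery, groups$control, var_equal)
  sr <- compare_groups(level_matrix, groups$stress, groups$recovery, var_equal)
  call <- ifelse(!cs$testable | is.na(cs$qvalue), "ambiguous",
          ifelse(cs$qvalue < alpha &
                   !is.na(rc$qvalue) & rc$qvalue < alpha &
                   (is.na(sr$qvalue) | sr$qvalue >= alpha), "persistent",
          ifelse(cs$qvalue < alpha &
                   !is.na(rc$qvalue) & rc$qvalue >= alpha, "transient",
                 "ambiguous")))
  data.frame(dmr_id = cs$dmr_id,
             call = factor(call, levels = c("persistent", "transient",
                                            "ambiguous")),
             q_control_stress = cs$qvalue,
             q_recovery_control = rc$qvalue,
             q_stress_recovery = sr$qvalue,
             mean_control = cs$mean_a, mean_stress = cs$mean_b,
             mean_recovery = rc$mean_a,
             alpha = alpha, stringsAsFactors = FALSE)
}

#' Onset ordering of transcriptional vs methylation changes
#'
#' For each timepoint, computes the fraction of DMR-associated genes that
#' are significantly differentially expressed (DE q-value < alpha) and the
#' fraction of DMRs significantly differentially methylated vs the control
#' group at that timepoint (t-test + BH).  Plotting the two fractions over
#' time shows which molecular layer responds first.
#'
#' @param annotated_dmrs Annotated DMR data.frame with `dmr_id` and
#'   `nearest_gene`.
#' @param level_matrices Named list (one per timepoint) of regions x
#'   samples level matrices.
#' @param group_pairs Named list (same names) of lists with `control` and
#'   `stress` sample ids valid for the matching matrix.
#' @param de_tables Named list (same names) of DE tables.
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame per timepoint: timepoint, frac_genes_de,
#'   frac_dmrs_dm.
#' @export
onset_summary <- function(annotated_dmrs, level_matrices, group_pairs,
                          de_tables, alpha = 0.05) {
  tps <- names(level_matrices)
  if (!identical(tps, names(de_tables)) || !identical(tps, names(group_pairs)))
    stop("timepoint names must match across inputs")
  genes <- unique(annotated_dmrs$nearest_gene)
  genes <- genes[!is.na(genes)]
  out <- lapply(tps, function(tp) {
    de <- de_tables[[tp]]
    q <- de$qvalue[match(genes, de$gene_id)]
    frac_de <- mean(!is.na(q) & q < alpha)
    cmp <- compare_groups(level_matrices[[tp]],
                          group_pairs[[tp]]$control, group_pairs[[tp]]$stress)
    frac_dm <- mean(cmp$testable & !is.na(cmp$qvalue) & cmp$qvalue < alpha)
    data.frame(timepoint = tp, frac_genes_de = frac_de,
               frac_dmrs_dm = frac_dm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hierarchically cluster samples by their DMR methylation levels
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' columns of a regions x samples level matrix; `hclust`'s deterministic
#' tie handling preserves input order.  Regions with any missing sample are
#' dropped before computing distances.
#'
#' @param level_matrix Regions x samples matrix.
#' @param newick_path Optional path; when given the dendrogram is also
#'   written as a Newick tree (via \pkg{ape}).
#' @return The `hclust` object, with the leaf order in `$order`.
#' @export
cluster_samples <- function(level_matrix, newick_path = NULL) {
  if (ncol(level_matrix) < 2L) stop("need >= 2 samples to cluster")
  keep <- stats::complete.cases(level_matrix)
  if (!any(keep)) stop("no region has complete coverage across samples")
  hc <- stats::hclust(stats::dist(t(level_matrix[keep, , drop = FALSE]),
                                  method = "euclidean"),
                      method = "average")
  if (!is.null(newick_path))
    ape::write.tree(ape::as.phylo(hc), file = newick_path)
  hc
}
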