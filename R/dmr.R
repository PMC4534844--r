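#' DMR-calling configuration profiles
#'
#' Preset threshold bundles mirroring the analysis variants of the study
#' design this package emulates: `rice_root` (9v9 pooled-timepoint design,
#' FDR 0.01, blocks with fewer than 8 significant sites discarded,
#' consistency 7-of-9), `rice_shoot` and `panicle` (triplicates, FDR 0.05,
#' consistency 3-of-3; panicle persistence tested at alpha 0.1),
#' `arabidopsis` (FDR 0.2, minimum 5 sites, consistency 2-of-3), and
#' `custom` (all values from the arguments).
#'
#' @param profile Profile name.
#' @param ... Individual overrides of any config field: `target_fdr`,
#'   `fdr_method`, `max_perms`, `stop_exceedances`, `max_gap`, `min_sites`,
#'   `k_required`, `min_reads_per_group`, `pool_replicates`,
#'   `consistency_margin`, `alpha_persistence`, `correction_method`,
#'   `master_seed`.
#' @return Named list of configuration values.
#' @export
dmr_config <- function(profile = c("rice_root", "rice_shoot", "panicle",
                                   "arabidopsis", "custom"), ...) {
  profile <- match.arg(profile)
  base <- list(target_fdr = 0.01, fdr_method = "bh",
               max_perms = 10000L, stop_exceedances = 100L,
               max_gap = 200L, min_sites = 8L, k_required = 7L,
               min_reads_per_group = 1L, pool_replicates = FALSE,
               consistency_margin = 0, alpha_persistence = 0.05,
               correction_method = "subtract", master_seed = 1L)
  preset <- switch(profile,
    rice_root   = list(),
    rice_shoot  = list(target_fdr = 0.05, k_required = 3L),
    panicle     = list(target_fdr = 0.05, k_required = 3L,
                       alpha_persistence = 0.1),
    arabidopsis = list(target_fdr = 0.2, min_sites = 5L, k_required = 2L),
    custom      = list())
  cfg <- utils::modifyList(base, preset)
  cfg <- utils::modifyList(cfg, list(...))
  cfg$profile <- profile
  cfg
}

#' Merge significant cytosines into candidate DMRs
#'
#' Greedy left-to-right chaining: a site joins the open block iff it is on
#' the same chromosome, has the same direction, and lies within `max_gap`
#' bases of the previous member.  Blocks with fewer than `min_sites`
#' members are flagged `passed_min_sites = FALSE` (and discarded downstream
#' by default).  Block boundaries are the first and last member positions,
#' not padded.
#'
#' @param sig_sites data.frame with `chrom`, `pos` and `direction`
#'   (`"hyper"`/`"hypo"`) columns, e.g. the significant rows of
#'   [test_sites()] output.
#' @param max_gap Maximum within-block gap in bp (default 200).
#' @param min_sites Minimum member sites for a block to pass (default 8).
#' @return data.frame of blocks: dmr_id, chrom, start, end, n_sites,
#'   direction, passed_min_sites.
#' @export
merge_sites <- function(sig_sites, max_gap = 200L, min_sites = 8L) {
  none <- sig_sites$direction == "none" | is.na(sig_sites$direction)
  if (any(none)) {
    warning(sum(none), " site(s) with direction 'none' excluded from merging")
    sig_sites <- sig_sites[!none, , drop = FALSE]
  }
  empty <- data.frame(dmr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), direction = character(),
                      passed_min_sites = logical(), stringsAsFactors = FALSE)
  if (!nrow(sig_sites)) return(empty)
  sig_sites <- sig_sites[order(sig_sites$chrom, sig_sites$pos), , drop = FALSE]
  new_block <- c(TRUE, sig_sites$chrom[-1] != sig_sites$chrom[-nrow(sig_sites)] |
                   sig_sites$direction[-1] != sig_sites$direction[-nrow(sig_sites)] |
                   diff(sig_sites$pos) > max_gap)
  bid <- cumsum(new_block)
  out <- data.frame(
    chrom = tapply(sig_sites$chrom, bid, `[`, 1),
    start = as.integer(tapply(sig_sites$pos, bid, min)),
    end = as.integer(tapply(sig_sites$pos, bid, max)),
    n_sites = as.integer(tabulate(bid)),
    direction = tapply(sig_sites$direction, bid, `[`, 1),
    stringsAsFactors = FALSE)
  out$passed_min_sites <- out$n_sites >= min_sites
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$dmr_id <- sprintf("dmr_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("dmr_id", "chrom", "start", "end", "n_sites", "direction",
          "passed_min_sites")]
}

#' Replicate-consistency filter for a DMR
#'
#' Operationalizes "k of n replicates differentially methylated" through
#' level separation: with `m` the midpoint between the two group means of
#' the region's corrected CNN levels, a sample is consistent iff its level
#' lies strictly on its own group's side of `m` in the DMR's direction (an
#' optional margin widens the required separation).  The filter passes iff
#' at least `k_required` samples are consistent in each group; tolerance for
#' swapped samples (e.g. 7-of-9 allows up to 2) falls out of `k_required`.
#'
#' @param levels_control,levels_stress Per-sample corrected region levels
#'   for the two groups (`NA` = no coverage).
#' @param direction `"hyper"` (stress above control) or `"hypo"`.
#' @param k_required Required consistent samples per group.
#' @param margin Optional minimum distance from the midpoint (default 0).
#' @return List with `pass`, `n_consistent_control`, `n_consistent_stress`,
#'   `midpoint`, `reason`.
#' @export
consistency_filter <- function(levels_control, levels_stress, direction,
                               k_required, margin = 0) {
  lc <- levels_control[!is.na(levels_control)]
  ls <- levels_stress[!is.na(levels_stress)]
  if (length(lc) < k_required || length(ls) < k_required)
    return(list(pass = FALSE, n_consistent_control = NA_integer_,
                n_consistent_stress = NA_integer_, midpoint = NA_real_,
                reason = "insufficient coverage"))
  mid <- (mean(lc) + mean(ls)) / 2
  if (direction == "hyper") {
    okc <- lc < mid - margin
    oks <- ls > mid + margin
  } else if (direction == "hypo") {
    okc <- lc > mid + margin
    oks <- ls < mid - margin
  } else {
    return(list(pass = FALSE, n_consistent_control = NA_integer_,
                n_consistent_stress = NA_integer_, midpoint = mid,
                reason = "no direction"))
  }
  pass <- sum(okc) >= k_required && sum(oks) >= k_required
  list(pass = pass,
       n_consistent_control = sum(okc),
       n_consistent_stress = sum(oks),
       midpoint = mid,
       reason = if (pass) "ok" else "separation")
}

#' Call differentially methylated regions
#'
#' Full discovery pipeline on a methylome set: per-cytosine RMS permutation
#' tests in the pooled CNN scope, largest-cutoff FDR calibration, merging of
#' significant same-direction sites within `max_gap`, minimum-site and
#' replicate-consistency filtering, and attachment of per-sample corrected
#' levels plus per-context group means.  Deterministic given
#' `config$master_seed`.
#'
#' @param ms A [methylome_set()].
#' @param groups Named list of two sample-id vectors; the first is the
#'   control group, the second the stress group.
#' @param config Configuration from [dmr_config()].
#' @param keep_failed Keep blocks failing the filters in the output
#'   (flagged) rather than dropping them (default FALSE).
#' @return Object of class `dmr_set`: data.frame of passing DMRs with
#'   attributes `sample_levels` (regions x samples matrix),
#'   `context_levels` (per-context group means), `site_results` (the full
#'   [test_sites()] table), `calibration`, `nc_rates`, `config`, `groups`.
#' @export
call_dmrs <- function(ms, groups, config = dmr_config(), keep_failed = FALSE) {
  if (!inherits(ms, "methylome_set")) stop("ms must be a methylome_set")
  if (nrow(ms$sites) == 0L) stop("empty methylome_set")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 samples")

  nc_rates <- if (!is.na(ms$spike_in_chrom)) estimate_nonconversion(ms)
              else setNames(rep(0, ncol(ms$mc)), colnames(ms$mc))

  site_res <- test_sites(ms, groups,
                         max_perms = config$max_perms,
                         stop_exceedances = config$stop_exceedances,
                         min_reads_per_group = config$min_reads_per_group,
                         pool_replicates = config$pool_replicates,
                         master_seed = config$master_seed)
  cal <- select_fdr_cutoff(site_res$pvalue, config$target_fdr,
                           method = config$fdr_method)
  sig <- site_res$tested & !is.na(site_res$pvalue) &
    site_res$pvalue <= cal$pvalue_cutoff & cal$pvalue_cutoff > 0 &
    site_res$direction != "none"
  blocks <- merge_sites(site_res[sig, , drop = FALSE],
                        max_gap = config$max_gap,
                        min_sites = config$min_sites)
  if (!keep_failed) blocks <- blocks[blocks$passed_min_sites, , drop = FALSE]

  blocks$passed_consistency <- logical(nrow(blocks))
  lev <- dmr_level_matrix(ms, blocks, scope = "CNN", nc_rates = nc_rates,
                          method = config$correction_method)
  gi <- resolve_groups(ms, groups)
  ctrl_cols <- gi[[1]]; str_cols <- gi[[2]]
  for (i in seq_len(nrow(blocks))) {
    cf <- consistency_filter(lev[i, ctrl_cols], lev[i, str_cols],
                             blocks$direction[i], config$k_required,
                             config$consistency_margin)
    blocks$passed_consistency[i] <- cf$pass
  }
  if (!keep_failed) {
    keep <- blocks$passed_consistency
    blocks <- blocks[keep, , drop = FALSE]
    lev <- lev[keep, , drop = FALSE]
  }
  rownames(blocks) <- NULL

  ctx_lev <- context_group_levels(ms, blocks, groups, nc_rates,
                                  config$correction_method)
  structure(blocks, class = c("dmr_set", "data.frame"),
            sample_levels = lev, context_levels = ctx_lev,
            site_results = site_res, calibration = cal,
            nc_rates = nc_rates, config = config, groups = groups)
}

#' Per-context group-mean levels for each DMR
#' @keywords internal
context_group_levels <- function(ms, blocks, groups, nc_rates, method) {
  gi <- resolve_groups(ms, groups)
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    row <- list()
    for (ctx in c("CNN", CONTEXTS)) {
      l <- suppressWarnings(
        region_levels(ms, blocks$chrom[i], blocks$start[i], blocks$end[i],
                      scope = ctx, nc_rates = nc_rates, method = method))
      for (g in names(groups))
        row[[paste(ctx, g, sep = "_")]] <-
          mean(l[gi[[g]]], na.rm = TRUE)
    }
    out[[i]] <- as.data.frame(row)
  }
  if (!length(out)) return(data.frame())
  cbind(dmr_id = blocks$dmr_id, do.call(rbind, out))
}

#' @export
print.dmr_set <- function(x, ...) {
  cal <- attr(x, "calibration")
  cat(sprintf("dmr_set: %d DMRs (%d hyper, %d hypo)\n", nrow(x),
              sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  if (!is.null(cal))
    cat(sprintf("  p-value cutoff %.4g at target FDR %.3g (%s); %d significant sites\n",
                cal$pvalue_cutoff, cal$target_fdr, cal$method,
                cal$n_significant))
  NextMethod()
}

#' Write a DMR set as a BED-like TSV plus a level matrix TSV
#'
#' The main table uses BED-style half-open 0-based `start0`; the level
#' matrix is written long (dmr_id, sample_id, level).
#'
#' @param dmrs A `dmr_set` (or plain data.frame with the same columns).
#' @param path Output TSV path; the level matrix goes to
#'   `<path>.levels.tsv` when sample levels are attached.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  df <- as.data.frame(dmrs)
  df$start0 <- df$start - 1L
  cols <- c("chrom", "start0", "end", "dmr_id", "direction", "n_sites",
            "passed_min_sites", "passed_consistency")
  utils::write.table(df[, intersect(cols, names(df))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lev <- attr(dmrs, "sample_levels")
  if (!is.null(lev) && nrow(df)) {
    long <- data.frame(dmr_id = rep(rownames(lev), ncol(lev)),
                       sample_id = rep(colnames(lev), each = nrow(lev)),
                       level = as.vector(lev))
    utils::write.table(long, paste0(path, ".levels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
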