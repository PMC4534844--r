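#' Weighted methylation level over a set of cytosines
#'
#' The weighted level is the fraction of all basecalls at cytosine reference
#' positions that were read as cytosine (i.e. bisulfite-protected,
#' methylated): `sum(mc_reads) / sum(total_reads)` pooled over the scope.
#' This is a fraction of basecalls, not a mean of per-site fractions, so
#' deeply covered sites carry proportionally more weight.
#'
#' @param records allc-style data.frame with `mc_reads`, `total_reads` and
#'   `context` columns.
#' @param scope Context scope: one of `"CG"`, `"CHG"`, `"CHH"` or `"CNN"`
#'   (all three pooled).
#' @return List with `raw_level`, `n_cytosines`, `n_basecalls`,
#'   `context_scope`.
#' @export
weighted_level <- function(records, scope = "CNN") {
  scope <- match.arg(scope, c("CNN", CONTEXTS))
  if (scope != "CNN")
    records <- records[records$context == scope, , drop = FALSE]
  n_bc <- sum(records$total_reads)
  if (nrow(records) == 0L || n_bc == 0)
    stop("undefined level: zero total basecalls in scope ", scope)
  list(raw_level = sum(records$mc_reads) / n_bc,
       n_cytosines = nrow(records),
       n_basecalls = n_bc,
       context_scope = scope)
}

#' Estimate the bisulfite non-conversion rate from the spike-in control
#'
#' The frequency of cytosine basecalls at reference cytosine positions in
#' the unmethylated control chromosome, normalized by the total number of
#' basecalls there.  Since the control carries no methylation, any apparent
#' methylation is conversion failure.
#'
#' @param spike_records allc-style data.frame restricted to the spike-in
#'   chromosome, or a `methylome_set` (per-sample rates are then returned).
#' @param sanity_threshold Rates at or above this trigger a warning
#'   (default 0.05); bisulfite conversion that poor usually indicates a
#'   failed library.
#' @return For a data.frame: list with `rate`, `n_basecalls`,
#'   `source_chrom`.  For a `methylome_set`: named numeric vector of
#'   per-sample rates.
#' @export
estimate_nonconversion <- function(spike_records, sanity_threshold = 0.05) {
  if (inherits(spike_records, "methylome_set")) {
    ms <- spike_records
    if (is.na(ms$spike_in_chrom))
      stop("methylome_set has no spike-in chromosome")
    idx <- ms$sites$chrom == ms$spike_in_chrom
    if (!any(idx)) stop("no spike-in coverage: chromosome '",
                        ms$spike_in_chrom, "' has no sites")
    tot <- colSums(ms$cov[idx, , drop = FALSE])
    if (any(tot == 0)) stop("no spike-in coverage for sample(s): ",
                            paste(names(tot)[tot == 0], collapse = ", "))
    rate <- colSums(ms$mc[idx, , drop = FALSE]) / tot
    if (any(rate >= sanity_threshold))
      warning("non-conversion rate >= ", sanity_threshold,
              " for sample(s): ",
              paste(names(rate)[rate >= sanity_threshold], collapse = ", "))
    return(rate)
  }
  n_bc <- sum(spike_records$total_reads)
  if (nrow(spike_records) == 0L || n_bc == 0)
    stop("no spike-in coverage")
  rate <- sum(spike_records$mc_reads) / n_bc
  if (rate >= sanity_threshold)
    warning("non-conversion rate ", signif(rate, 3), " >= sanity threshold ",
            sanity_threshold)
  list(rate = rate, n_basecalls = n_bc,
       source_chrom = if (length(unique(spike_records$chrom)) == 1L)
         spike_records$chrom[1] else NA_character_)
}

#' Correct a raw methylation level for non-conversion
#'
#' The default subtracts the non-conversion rate and clamps at zero.  The
#' alternative `"rescale"` method treats the observed proportion as
#' `p + (1 - p) * nc` and inverts it: `(raw - nc) / (1 - nc)`, clamped to
#' `[0, 1]`.
#'
#' @param raw Raw weighted level(s) in `[0, 1]`.
#' @param nc_rate Non-conversion rate(s) in `[0, 1]` (a number or the `rate`
#'   element of [estimate_nonconversion()]).
#' @param method `"subtract"` (default) or `"rescale"`.
#' @return Corrected level(s) in `[0, 1]`.
#' @export
correct_level <- function(raw, nc_rate, method = c("subtract", "rescale")) {
  method <- match.arg(method)
  if (is.list(nc_rate)) nc_rate <- nc_rate$rate
  stopifnot(all(raw >= 0 & raw <= 1, na.rm = TRUE),
            all(nc_rate >= 0 & nc_rate <= 1))
  out <- switch(method,
                subtract = raw - nc_rate,
                rescale  = (raw - nc_rate) / (1 - nc_rate))
  pmin(pmax(out, 0), 1)
}

#' Per-sample methylation levels over a genomic region
#'
#' Pools counts over all cytosines of the region (in the requested context
#' scope) separately for each sample and applies non-conversion correction.
#' Samples with zero coverage in the region are returned as `NA` (missing),
#' never imputed.
#'
#' @param ms A [methylome_set()].
#' @param chrom,start,end Region (1-based inclusive).
#' @param scope Context scope (`"CNN"`, `"CG"`, `"CHG"`, `"CHH"`).
#' @param nc_rates Named per-sample non-conversion rates (as from
#'   [estimate_nonconversion()] on the set), a single rate recycled to all
#'   samples, or `NULL` for no correction.
#' @param method Correction method passed to [correct_level()].
#' @return Named numeric vector of corrected levels, one per sample.
#' @export
region_levels <- function(ms, chrom, start, end, scope = "CNN",
                          nc_rates = NULL, method = "subtract") {
  idx <- which(ms$sites$chrom == chrom & ms$sites$pos >= start &
                 ms$sites$pos <= end &
                 (scope == "CNN" | ms$sites$context == scope))
  if (!length(idx)) {
    warning(sprintf("no cytosines in %s:%d-%d (scope %s)",
                    chrom, start, end, scope))
    return(setNames(rep(NA_real_, ncol(ms$mc)), colnames(ms$mc)))
  }
  site_level_matrix(ms, idx, nc_rates, method)[1, ]
}

#' Pooled per-sample levels for arbitrary site index groups
#' @keywords internal
site_level_matrix <- function(ms, idx, nc_rates = NULL, method = "subtract",
                              group_id = NULL) {
  if (is.null(group_id)) group_id <- rep(1L, length(idx))
  gid <- factor(group_id)
  mc <- rowsum(ms$mc[idx, , drop = FALSE], gid)
  cov <- rowsum(ms$cov[idx, , drop = FALSE], gid)
  lev <- mc / cov                     # NaN where cov == 0
  lev[cov == 0] <- NA_real_
  if (!is.null(nc_rates)) {
    if (length(nc_rates) == 1L)
      nc_rates <- setNames(rep(nc_rates, ncol(lev)), colnames(lev))
    nc <- nc_rates[colnames(lev)]
    lev <- sweep_correct(lev, nc, method)
  }
  rownames(lev) <- levels(gid)
  lev
}

sweep_correct <- function(lev, nc, method) {
  for (j in seq_len(ncol(lev)))
    lev[, j] <- ifelse(is.na(lev[, j]), NA_real_,
                       correct_level(lev[, j], nc[j], method))
  lev
}

#' Per-DMR, per-sample level matrix
#'
#' Builds the regions-by-samples matrix of corrected weighted levels used by
#' the consistency filter, hierarchical clustering and persistence tests.
#'
#' @param ms A [methylome_set()].
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `dmr_id` columns.
#' @inheritParams region_levels
#' @return Numeric matrix (regions x samples); `NA` marks zero-coverage
#'   entries.
#' @export
dmr_level_matrix <- function(ms, regions, scope = "CNN", nc_rates = NULL,
                             method = "subtract") {
  ids <- regions$dmr_id %||% paste0("region_", seq_len(nrow(regions)))
  out <- matrix(NA_real_, nrow(regions), ncol(ms$mc),
                dimnames = list(ids, colnames(ms$mc)))
  for (i in seq_len(nrow(regions)))
    out[i, ] <- suppressWarnings(
      region_levels(ms, regions$chrom[i], regions$start[i], regions$end[i],
                    scope, nc_rates, method))
  out
}
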