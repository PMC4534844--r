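#' Build the per-cytosine contingency table
#'
#' For one cytosine, rows are the covered samples and the two columns count
#' reads supporting a methylated vs an unmethylated cytosine.  Samples with
#' zero coverage at the site are omitted; if fewer than two samples remain,
#' or either group loses all its samples, the site is untestable and `NULL`
#' is returned (the caller skips it).
#'
#' @param ms A [methylome_set()].
#' @param site_index Row index into `ms$sites`.
#' @param groups Named list of two sample-id vectors (see [call_dmrs()]).
#' @return List with `counts` (r x 2 integer matrix, columns mc/un) and
#'   `group` (group label per row), or `NULL` for an untestable site.
#' @export
build_contingency <- function(ms, site_index, groups) {
  gidx <- resolve_groups(ms, groups)
  cols <- unlist(gidx, use.names = FALSE)
  lab <- rep(names(groups), lengths(gidx))
  mc <- ms$mc[site_index, cols]
  cov <- ms$cov[site_index, cols]
  keep <- cov > 0
  if (sum(keep) < 2L || length(unique(lab[keep])) < length(groups))
    return(NULL)
  counts <- cbind(mc = mc[keep], un = cov[keep] - mc[keep])
  rownames(counts) <- colnames(ms$mc)[cols][keep]
  list(counts = counts, group = lab[keep])
}

#' Root-mean-square statistic of a contingency table
#'
#' With observed cell frequencies `f_ij = counts_ij / n` and independence
#' expectations `e_ij = row_i * col_j / n^2`, the statistic is
#' `sqrt(mean((f - e)^2))` over all `r * c` cells.  It is zero exactly when
#' the table matches its independence expectation, and invariant to row
#' reordering and to swapping the columns across all rows.
#'
#' @param counts Non-negative integer matrix (r x c, r >= 2).
#' @return Non-negative scalar.
#' @export
rms_statistic <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("contingency table needs >= 2 rows")
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n == 0) stop("empty contingency table (n = 0)")
  f <- counts / n
  e <- outer(rowSums(counts), colSums(counts)) / n^2
  sqrt(mean((f - e)^2))
}

#' Multinomial permutation p-value for the RMS statistic
#'
#' Simulates the null by drawing, for each permutation, all `n` reads
#' multinomially over the `r x 2` cells with probabilities equal to the
#' product of the observed row and column marginals divided by `n^2`.  Each
#' permuted table is scored with [rms_statistic()] (recomputing its own
#' marginals); an exceedance is a permuted statistic greater than or equal
#' to the observed one.  Sampling stops early once `stop_exceedances`
#' exceedances accumulate, or at `max_perms`.  The p-value uses the add-one
#' estimator `(exceedances + 1) / (permutations + 1)`, which is never zero
#' and remains valid under early stopping.
#'
#' @param counts r x 2 contingency table.
#' @param max_perms Maximum number of permutations (default 10000).
#' @param stop_exceedances Early-stopping exceedance count (default 100);
#'   `Inf` disables early stopping.
#' @param seed Integer seed; required for reproducibility.
#' @param chunk Internal batch size for vectorized sampling.
#' @return List with `stat`, `pvalue`, `n_perms_run`, `n_exceedances`,
#'   `stopped_early`.
#' @export
rms_perm_test <- function(counts, max_perms = 10000L, stop_exceedances = 100L,
                          seed = NULL, chunk = 256L) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop("permutation test expects an r x 2 table")
  if (max_perms < 1L) stop("max_perms must be >= 1")
  if (is.null(seed)) stop("config error: a seed is required")
  obs <- rms_statistic(counts)
  n <- sum(counts)
  r <- nrow(counts)
  prob <- as.vector(outer(rowSums(counts), colSums(counts))) / n^2

  set.seed(seed)
  run <- 0L
  exc <- 0L
  stopped <- FALSE
  eps <- 1e-12
  while (run < max_perms) {
    b <- min(chunk, max_perms - run)
    draw <- stats::rmultinom(b, n, prob)        # (2r) x b, column-major cells
    m1 <- draw[seq_len(r), , drop = FALSE]       # mc column
    m2 <- draw[r + seq_len(r), , drop = FALSE]   # un column
    rs <- m1 + m2                                # row marginals per draw
    c1 <- colSums(m1); c2 <- colSums(m2)         # column marginals per draw
    dev1 <- m1 / n - rs * rep(c1, each = r) / n^2
    dev2 <- m2 / n - rs * rep(c2, each = r) / n^2
    stat <- sqrt((colSums(dev1^2) + colSums(dev2^2)) / (2 * r))
    hit <- stat >= obs - eps
    cum <- exc + cumsum(hit)
    if (is.finite(stop_exceedances) && any(cum >= stop_exceedances)) {
      at <- which(cum >= stop_exceedances)[1]
      run <- run + at
      exc <- cum[at]
      stopped <- TRUE
      break
    }
    run <- run + b
    exc <- exc + sum(hit)
  }
  list(stat = obs,
       pvalue = (exc + 1) / (run + 1),
       n_perms_run = run,
       n_exceedances = exc,
       stopped_early = stopped)
}

#' Deterministic per-site seed
#'
#' Derives a site-specific seed from the master seed and the site's
#' coordinates, so results do not depend on the order in which sites are
#' tested.
#' @keywords internal
site_seed <- function(master_seed, chrom, pos) {
  h <- 0
  for (ch in utf8ToInt(as.character(chrom))) h <- (h * 31 + ch) %% 2147480000
  as.integer((master_seed %% 2147480000 + h * 7919 + as.numeric(pos) * 2971) %%
               2147480000)
}

#' Test every cytosine for differential methylation
#'
#' Runs the RMS permutation test at each genome site (spike-in sites are
#' excluded) in the pooled CNN scope, comparing two sample groups.  The
#' per-site direction is the sign of the pooled second-group level minus the
#' pooled first-group level (`hyper` when the stress/second group is more
#' methylated).
#'
#' @param ms A [methylome_set()].
#' @param groups Named list of exactly two sample-id vectors; the first is
#'   the reference (control) group.
#' @param max_perms,stop_exceedances See [rms_perm_test()].
#' @param min_reads_per_group Coverage floor: sites where either group has
#'   fewer pooled reads are skipped (default 1, i.e. no extra floor).
#' @param pool_replicates If `TRUE`, replicates are pooled into a 2 x 2
#'   condition table instead of the default sample-per-row r x 2 table.
#' @param master_seed Master seed; per-site seeds are derived from it and
#'   the site coordinates.
#' @return data.frame with one row per genome site: chrom, pos, strand,
#'   context, tested, stat, pvalue, n_perms_run, n_exceedances, direction.
#' @export
test_sites <- function(ms, groups, max_perms = 10000L,
                       stop_exceedances = 100L, min_reads_per_group = 1L,
                       pool_replicates = FALSE, master_seed = 1L) {
  if (length(groups) != 2L)
    stop("test_sites compares exactly two groups")
  gidx <- resolve_groups(ms, groups)
  if (any(lengths(gidx) < 1L)) stop("each group needs >= 1 sample")
  idx <- genome_sites(ms)
  if (!length(idx)) stop("methylome_set has no genome sites")
  sites <- ms$sites[idx, , drop = FALSE]
  n_sites <- length(idx)

  cols <- unlist(gidx, use.names = FALSE)
  lab <- rep(names(groups), lengths(gidx))
  mc <- ms$mc[idx, cols, drop = FALSE]
  cov <- ms$cov[idx, cols, drop = FALSE]
  g1 <- lab == names(groups)[1]
  pooled_mc1 <- rowSums(mc[, g1, drop = FALSE])
  pooled_cov1 <- rowSums(cov[, g1, drop = FALSE])
  pooled_mc2 <- rowSums(mc[, !g1, drop = FALSE])
  pooled_cov2 <- rowSums(cov[, !g1, drop = FALSE])

  res <- data.frame(sites,
                    tested = FALSE, stat = NA_real_, pvalue = NA_real_,
                    n_perms_run = NA_integer_, n_exceedances = NA_integer_,
                    direction = "none", stringsAsFactors = FALSE)
  for (i in seq_len(n_sites)) {
    if (pooled_cov1[i] < min_reads_per_group ||
        pooled_cov2[i] < min_reads_per_group) next
    if (pool_replicates) {
      counts <- rbind(c(pooled_mc1[i], pooled_cov1[i] - pooled_mc1[i]),
                      c(pooled_mc2[i], pooled_cov2[i] - pooled_mc2[i]))
      if (any(rowSums(counts) == 0)) next
    } else {
      keep <- cov[i, ] > 0
      if (sum(keep) < 2L || length(unique(lab[keep])) < 2L) next
      counts <- cbind(mc[i, keep], cov[i, keep] - mc[i, keep])
    }
    pt <- rms_perm_test(counts, max_perms, stop_exceedances,
                        seed = site_seed(master_seed, sites$chrom[i],
                                         sites$pos[i]))
    res$tested[i] <- TRUE
    res$stat[i] <- pt$stat
    res$pvalue[i] <- pt$pvalue
    res$n_perms_run[i] <- pt$n_perms_run
    res$n_exceedances[i] <- pt$n_exceedances
    l1 <- pooled_mc1[i] / pooled_cov1[i]
    l2 <- pooled_mc2[i] / pooled_cov2[i]
    res$direction[i] <- if (l2 > l1) "hyper" else if (l2 < l1) "hypo" else "none"
  }
  res
}
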