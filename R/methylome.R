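#' Build a position-aligned methylome set from per-sample allc tables
#'
#' Takes one allc data.frame per sample and aligns them on the union of
#' (chrom, pos, strand) keys, so every sample has a count entry at every
#' site.  A sample lacking coverage at a site gets `total_reads = 0` (never
#' a missing row), keeping the matrices aligned.  One chromosome may be
#' reserved for the unmethylated spike-in control (e.g. lambda phage DNA
#' added before bisulfite conversion); it is excluded from genome-wide
#' analyses and used only to estimate the non-conversion rate.
#'
#' @param tables Named list of allc data.frames (names = sample ids), or a
#'   sample sheet data.frame with an `allc_path` column.
#' @param samples Sample metadata data.frame (`sample_id`, `condition`,
#'   `tissue`, `timepoint`, `replicate`, `genotype`).  Required when
#'   `tables` is a list.
#' @param spike_in_chrom Name of the spike-in control chromosome, or `NA`.
#' @return An object of class `methylome_set`: a list with `sites`
#'   (data.frame chrom/pos/strand/context), integer matrices `mc` and `cov`
#'   (sites x samples), `samples`, and `spike_in_chrom`.
#' @export
methylome_set <- function(tables, samples = NULL, spike_in_chrom = NA) {
  if (is.data.frame(tables)) {           # a sample sheet
    sheet <- tables
    if (is.null(sheet$allc_path))
      stop("sample sheet has no allc_path column")
    tables <- lapply(sheet$allc_path, read_allc)
    names(tables) <- sheet$sample_id
    samples <- sheet[, setdiff(names(sheet), "allc_path"), drop = FALSE]
  }
  if (is.null(samples))
    stop("sample metadata required")
  if (is.null(names(tables)) || !setequal(names(tables), samples$sample_id))
    stop("names(tables) must match samples$sample_id")
  tables <- tables[samples$sample_id]
  tables <- lapply(tables, validate_allc)

  keys <- unique(do.call(rbind, lapply(tables, function(t)
    t[, c("chrom", "pos", "strand", "context")])))
  keys <- keys[order(keys$chrom, keys$pos, keys$strand), , drop = FALSE]
  rownames(keys) <- NULL
  kid <- paste(keys$chrom, keys$pos, keys$strand)
  if (anyDuplicated(kid))
    stop("conflicting context annotations at the same (chrom, pos, strand)")

  n <- nrow(keys)
  mc <- cov <- matrix(0L, n, length(tables),
                      dimnames = list(NULL, names(tables)))
  for (s in names(tables)) {
    t <- tables[[s]]
    idx <- match(paste(t$chrom, t$pos, t$strand), kid)
    mc[idx, s] <- as.integer(t$mc_reads)
    cov[idx, s] <- as.integer(t$total_reads)
  }
  if (!is.na(spike_in_chrom) && !spike_in_chrom %in% keys$chrom)
    warning("spike-in chromosome '", spike_in_chrom, "' has no sites")
  structure(list(sites = keys, mc = mc, cov = cov, samples = samples,
                 spike_in_chrom = spike_in_chrom),
            class = "methylome_set")
}

#' @export
print.methylome_set <- function(x, ...) {
  cat(sprintf("methylome_set: %d sites x %d samples\n",
              nrow(x$sites), ncol(x$mc)))
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  if (!is.na(x$spike_in_chrom))
    cat("  spike-in control:", x$spike_in_chrom, "\n")
  invisible(x)
}

#' Restrict a methylome set to genome (non-spike-in) sites
#' @param ms A `methylome_set`.
#' @keywords internal
genome_sites <- function(ms) {
  if (is.na(ms$spike_in_chrom)) return(seq_len(nrow(ms$sites)))
  which(ms$sites$chrom != ms$spike_in_chrom)
}

subset_sites <- function(ms, idx) {
  structure(list(sites = ms$sites[idx, , drop = FALSE],
                 mc = ms$mc[idx, , drop = FALSE],
                 cov = ms$cov[idx, , drop = FALSE],
                 samples = ms$samples,
                 spike_in_chrom = ms$spike_in_chrom),
            class = "methylome_set")
}

#' Resolve a group partition against a methylome set's samples
#'
#' Groups are a named list of sample-id vectors, e.g.
#' `list(control = c("s1", ...), stress = c("s2", ...))`.  The paper-style
#' multi-timepoint pooling (e.g. 21/22/24-day samples into one 9-replicate
#' group) is expressed purely through this assignment.
#'
#' @keywords internal
resolve_groups <- function(ms, groups) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2L)
    stop("groups must be a named list of >= 2 sample-id vectors")
  miss <- setdiff(unlist(groups), ms$samples$sample_id)
  if (length(miss))
    stop("unknown sample id(s) in groups: ", paste(miss, collapse = ", "))
  if (any(duplicated(unlist(groups))))
    stop("groups must be disjoint")
  lapply(groups, function(g) match(g, colnames(ms$mc)))
}
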