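#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`,
#' clamped to `[0, 1]` and returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted values (q-values), same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  q <- pmin(1, cummin(pvalues[o] * m / (m:1)))
  q[order(o)]
}

#' Select the largest p-value cutoff controlling the FDR
#'
#' Two calibration methods are available.  `"bh"` applies the
#' Benjamini-Hochberg step-up rule: the cutoff is the largest sorted
#' p-value `p_(k)` with `p_(k) <= k * q / m`.  `"empirical_null"` uses
#' p-values recomputed after random relabeling of the group assignments: for
#' candidate cutoff `c` the estimated FDR is
#' `mean_fraction(null_p <= c) * m / #\{observed_p <= c\}`, and the largest
#' `c` with estimate `<= q` is chosen.  Either way the procedure returns the
#' largest cutoff that still satisfies the FDR requirement.
#'
#' @param observed_p Vector of observed p-values.
#' @param target_fdr Target FDR (e.g. 0.01).
#' @param method `"bh"` (default) or `"empirical_null"`.
#' @param null_p Numeric vector, or list of vectors (one per relabeling), of
#'   null p-values; required for `"empirical_null"`.
#' @return List with `target_fdr`, `pvalue_cutoff`, `n_significant`,
#'   `method`.  When no cutoff achieves the target, `pvalue_cutoff = 0` and
#'   `n_significant = 0`.
#' @export
select_fdr_cutoff <- function(observed_p, target_fdr,
                              method = c("bh", "empirical_null"),
                              null_p = NULL) {
  method <- match.arg(method)
  observed_p <- observed_p[!is.na(observed_p)]
  if (!length(observed_p)) stop("no observed p-values")
  m <- length(observed_p)
  cutoff <- 0
  if (method == "bh") {
    sp <- sort(observed_p)
    ok <- which(sp <= seq_len(m) * target_fdr / m)
    if (length(ok)) cutoff <- sp[max(ok)]
  } else {
    if (is.null(null_p)) stop("empirical_null requires null_p")
    if (!is.list(null_p)) null_p <- list(null_p)
    null_p <- lapply(null_p, function(p) p[!is.na(p)])
    cand <- sort(unique(observed_p))
    for (c_ in rev(cand)) {
      frac_null <- mean(vapply(null_p, function(p) mean(p <= c_), numeric(1)))
      est <- frac_null * m / sum(observed_p <= c_)
      if (est <= target_fdr) { cutoff <- c_; break }
    }
  }
  list(target_fdr = target_fdr,
       pvalue_cutoff = cutoff,
       n_significant = if (cutoff > 0) sum(observed_p <= cutoff) else 0L,
       method = method)
}
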