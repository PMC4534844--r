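# Independent oracles used to freeze expected values.  These deliberately
# re-derive quantities from first principles (own formulas, enumeration,
# exhaustive scans) rather than calling the implementation under test.

# RMS deviation of a table from its independence expectation, written out
# directly from the definition.
oracle_rms <- function(tab) {
  n <- sum(tab)
  f <- tab / n
  e <- (rowSums(tab) %o% colSums(tab)) / n^2
  sqrt(sum((f - e)^2) / length(tab))
}

# All ways to place n reads into k cells (compositions of n).
oracle_compositions <- function(n, k = 4L) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    rest <- oracle_compositions(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, rest)
  }
  unname(do.call(rbind, out))
}

# Exact p-value of the RMS test by exhaustive multinomial enumeration:
# P(stat(T) >= stat(obs)) with T ~ Multinomial(n, e/n) over the r x 2 cells
# (cells column-major: mc column then un column).
oracle_exact_pvalue <- function(obs_tab) {
  n <- sum(obs_tab)
  r <- nrow(obs_tab)
  prob <- as.vector(rowSums(obs_tab) %o% colSums(obs_tab)) / n^2
  obs_stat <- oracle_rms(obs_tab)
  outs <- oracle_compositions(n, 2L * r)
  p <- 0
  for (i in seq_len(nrow(outs))) {
    x <- outs[i, ]
    tab <- matrix(x, nrow = r)
    if (oracle_rms(tab) >= obs_stat - 1e-12)
      p <- p + stats::dmultinom(x, prob = prob)
  }
  p
}

# Exhaustive nearest-gene scan: for every gene on the region's chromosome
# compute overlap / signed gap independently, return the winner.
oracle_nearest <- function(chrom, start, end, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(g))) {
    ov <- min(end, g$end[i]) - max(start, g$start[i]) + 1
    if (ov > 0) {
      d <- 0; key <- c(-ov, 0)          # larger overlap wins, then id
    } else if (end < g$start[i]) {
      gap <- g$start[i] - end
      d <- if (g$strand[i] == "+") -gap else gap
      key <- c(0, gap)
    } else {
      gap <- start - g$end[i]
      d <- if (g$strand[i] == "+") gap else -gap
      key <- c(0, gap)
    }
    cand <- list(id = g$id[i], dist = d, key = key)
    if (is.null(best) ||
        key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2]) ||
        (identical(key, best$key) && cand$id < best$id))
      best <- cand
  }
  best
}

# Brute-force BH step-up: test every k explicitly.
oracle_bh_cutoff <- function(p, q) {
  sp <- sort(p)
  m <- length(p)
  cutoff <- 0
  for (k in seq_len(m)) if (sp[k] <= k * q / m) cutoff <- sp[k]
  cutoff
}

# Welch t-test p-value from the closed-form statistic and Satterthwaite df.
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}
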