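test_that("group t-tests are Welch by default and flag degenerate input", {
  a <- c(0.1, 0.12, 0.11); b <- c(0.6, 0.58, 0.62)
  tt <- group_ttest(a, b)
  expect_true(tt$testable)
  expect_lt(tt$pvalue, 0.001)
  expect_equal(tt$pvalue, oracle_welch_p(a, b))
  # zero variance in both groups is untestable, not an error
  z <- group_ttest(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_false(z$testable)
  expect_true(is.na(z$pvalue))
  expect_false(group_ttest(0.5, c(0.4, 0.6))$testable)  # < 2 replicates
  # nearly identical groups are far from significant
  set.seed(1)
  x <- runif(5)
  expect_gt(group_ttest(x, x + rnorm(5, 0, 1e-9))$pvalue, 0.5)
})

test_that("comparison families apply BH within the family", {
  lev <- rbind(a = c(0.1, 0.11, 0.1, 0.5, 0.52, 0.51),
               b = c(0.2, 0.22, 0.21, 0.2, 0.21, 0.22),
               c = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  colnames(lev) <- c("x1", "x2", "x3", "y1", "y2", "y3")
  cmp <- compare_groups(lev, c("x1", "x2", "x3"), c("y1", "y2", "y3"))
  expect_equal(cmp$testable, c(TRUE, TRUE, FALSE))
  expect_equal(cmp$qvalue[cmp$testable],
               bh_adjust(cmp$pvalue[cmp$testable]))
  expect_true(is.na(cmp$qvalue[3]))
})

test_that("a stably maintained methylation loss classifies as persistent", {
  # worked example: a region at 50% methylation under control dropping to
  # ~1.3% under stress and staying at ~1.5% after resupply (triplicates)
  set.seed(42)
  n_noise <- 30
  lev <- rbind(
    spx_like = c(0.50, 0.49, 0.51, 0.013, 0.012, 0.014, 0.015, 0.016, 0.014),
    matrix(runif(n_noise * 9, 0.18, 0.22), n_noise, 9))
  rownames(lev) <- c("spx_like", sprintf("null_%02d", seq_len(n_noise)))
  colnames(lev) <- c(paste0("ctl", 1:3), paste0("str", 1:3), paste0("res", 1:3))
  groups <- list(control = paste0("ctl", 1:3), stress = paste0("str", 1:3),
                 recovery = paste0("res", 1:3))
  out <- classify_persistence(lev, groups)
  expect_equal(as.character(out$call[out$dmr_id == "spx_like"]), "persistent")
  expect_lt(out$q_control_stress[1], 0.05)
  expect_lt(out$q_recovery_control[1], 0.05)
  expect_gte(out$q_stress_recovery[1], 0.05)
})

test_that("a reverting region classifies as transient and flat ones ambiguous", {
  set.seed(7)
  mk <- function(mc, ms, mr, sd = 0.01)
    c(rnorm(3, mc, sd), rnorm(3, ms, sd), rnorm(3, mr, sd))
  lev <- rbind(trans = mk(0.10, 0.40, 0.105),
               flat = mk(0.2, 0.2, 0.2),
               trans2 = mk(0.05, 0.55, 0.05))
  colnames(lev) <- c(paste0("ctl", 1:3), paste0("str", 1:3), paste0("res", 1:3))
  groups <- list(control = paste0("ctl", 1:3), stress = paste0("str", 1:3),
                 recovery = paste0("res", 1:3))
  out <- classify_persistence(lev, groups)
  expect_equal(as.character(out$call),
               c("transient", "ambiguous", "transient"))
  expect_error(classify_persistence(lev, groups["control"]), "recovery")
})

test_that("persistence recovery rate on generated truths exceeds 90%", {
  set.seed(11)
  n_each <- 20
  make_region <- function(persist) {
    base <- 0.05; delta <- 0.5
    rec <- if (persist) base + delta else base
    # per-sample weighted-level noise at ~240 pooled basecalls
    c(pmax(0, rnorm(3, base, 0.025)), rnorm(3, base + delta, 0.035),
      pmax(0, rnorm(3, rec, 0.035)))
  }
  lev <- rbind(t(replicate(n_each, make_region(TRUE))),
               t(replicate(n_each, make_region(FALSE))))
  rownames(lev) <- sprintf("r%02d", seq_len(2 * n_each))
  colnames(lev) <- c(paste0("ctl", 1:3), paste0("str", 1:3), paste0("res", 1:3))
  truth <- rep(c("persistent", "transient"), each = n_each)
  out <- classify_persistence(lev, list(control = paste0("ctl", 1:3),
                                        stress = paste0("str", 1:3),
                                        recovery = paste0("res", 1:3)))
  expect_gte(mean(as.character(out$call) == truth), 0.9)
})

test_that("onset fractions order expression before methylation on staged truth", {
  set.seed(5)
  ann <- data.frame(dmr_id = sprintf("d%d", 1:10),
                    nearest_gene = sprintf("g%d", 1:10))
  samples <- c(paste0("c", 1:3), paste0("s", 1:3))
  mk_lev <- function(delta) {
    m <- cbind(matrix(rnorm(30, 0.1, 0.01), 10, 3),
               matrix(rnorm(30, 0.1 + delta, 0.01), 10, 3))
    dimnames(m) <- list(ann$dmr_id, samples); m
  }
  mk_de <- function(active) data.frame(
    gene_id = ann$nearest_gene,
    log2fc = if (active) 3 else 0,
    qvalue = if (active) 1e-4 else 0.9,
    mean_expr_control = 1, mean_expr_stress = 1)
  gp <- list(control = paste0("c", 1:3), stress = paste0("s", 1:3))
  out <- onset_summary(ann,
                       list(t1 = mk_lev(0), t2 = mk_lev(0.4)),
                       list(t1 = gp, t2 = gp),
                       list(t1 = mk_de(TRUE), t2 = mk_de(TRUE)))
  expect_equal(out$frac_genes_de, c(1, 1))
  expect_lt(out$frac_dmrs_dm[1], 0.2)       # methylation not yet changed
  expect_gt(out$frac_dmrs_dm[2], 0.9)       # changes appear later
})

test_that("sample clustering merges identical samples first and writes Newick", {
  lev <- cbind(a = c(0.1, 0.2, 0.3), b = c(0.1, 0.2, 0.3),
               c = c(0.8, 0.9, 0.7))
  rownames(lev) <- c("d1", "d2", "d3")
  hc <- cluster_samples(lev)
  expect_equal(sort(hc$labels[-hc$merge[1, ]]), c("a", "b"))
  f <- withr::local_tempfile(fileext = ".nwk")
  cluster_samples(lev, newick_path = f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  expect_error(cluster_samples(lev[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("block-structured level matrices cluster by condition", {
  set.seed(3)
  block <- function(mu, n) matrix(rnorm(40 * n, mu, 0.02), 40, n)
  lev <- cbind(block(0.1, 5), block(0.6, 5))
  colnames(lev) <- c(paste0("c", 1:5), paste0("s", 1:5))
  rownames(lev) <- sprintf("d%02d", 1:40)
  hc <- cluster_samples(lev)
  two <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(two[paste0("c", 1:5)])), 1L)
  expect_equal(length(unique(two[paste0("s", 1:5)])), 1L)
  expect_false(two[["c1"]] == two[["s1"]])
})
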