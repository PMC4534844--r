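sig_df <- function(pos, direction = "hyper", chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             direction = rep_len(direction, length(pos)),
             stringsAsFactors = FALSE)
}

test_that("sites chain within 200 bp in the same direction", {
  b <- merge_sites(sig_df(c(100, 250, 460)), max_gap = 200, min_sites = 2)
  expect_equal(nrow(b), 2L)
  expect_equal(b$start, c(100L, 460L))
  expect_equal(b$end, c(250L, 460L))
  expect_equal(b$passed_min_sites, c(TRUE, FALSE))
})

test_that("blocks under the minimum site count are discarded", {
  b <- merge_sites(sig_df(seq(100, by = 20, length.out = 7)), min_sites = 8)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_sites, 7L)
  expect_false(b$passed_min_sites)
  b8 <- merge_sites(sig_df(seq(100, by = 20, length.out = 8)), min_sites = 8)
  expect_true(b8$passed_min_sites)
})

test_that("opposite directions never share a block", {
  pos <- seq(100, by = 50, length.out = 8)
  b <- merge_sites(sig_df(pos, rep(c("hyper", "hypo"), 4)), min_sites = 1)
  expect_equal(nrow(b), 8L)
  expect_true(all(b$n_sites == 1L))
  # same-direction runs chain across an interleaved boundary
  b2 <- merge_sites(sig_df(pos, rep(c("hyper", "hypo"), each = 4)),
                    min_sites = 2)
  expect_equal(nrow(b2), 2L)
  expect_equal(sort(b2$direction), c("hyper", "hypo"))
})

test_that("merging is idempotent under re-sorting and splits chromosomes", {
  set.seed(2)
  sites <- rbind(sig_df(sort(sample.int(5000, 40)), "hyper"),
                 sig_df(sort(sample.int(5000, 40)), "hyper", chrom = "chr2"))
  a <- merge_sites(sites, min_sites = 1)
  b <- merge_sites(sites[sample(nrow(sites)), ], min_sites = 1)
  expect_equal(a, b)
  expect_true(all(a$chrom %in% c("chr1", "chr2")))
  # same-direction spans are disjoint by construction
  for (ch in c("chr1", "chr2")) {
    x <- a[a$chrom == ch, ]
    if (nrow(x) > 1) expect_true(all(x$start[-1] > x$end[-nrow(x)]))
  }
})

test_that("directionless sites are excluded with a warning", {
  expect_warning(b <- merge_sites(sig_df(c(100, 150, 200),
                                         c("hyper", "none", "hyper")),
                                  min_sites = 1),
                 "direction 'none'")
  expect_equal(b$n_sites, 2L)
})

test_that("consistency requires k samples strictly beyond the group midpoint", {
  ctrl <- rep(0.05, 9)
  stress <- c(rep(0.60, 8), 0.07)
  cf <- consistency_filter(ctrl, stress, "hyper", k_required = 7)
  expect_true(cf$pass)
  expect_equal(cf$n_consistent_control, 9L)
  expect_equal(cf$n_consistent_stress, 8L)
  # only 6 of 9 separated -> fail at 7-of-9
  cf2 <- consistency_filter(ctrl, c(rep(0.60, 6), rep(0.07, 3)), "hyper", 7)
  expect_false(cf2$pass)
  expect_equal(cf2$n_consistent_stress, 6L)
  # identical group means: the midpoint separates nothing
  cf3 <- consistency_filter(rep(0.3, 9), rep(0.3, 9), "hyper", 7)
  expect_false(cf3$pass)
  # missing coverage below k fails with the coverage reason
  cf4 <- consistency_filter(c(0.05, 0.05, rep(NA, 7)), stress, "hyper", 7)
  expect_false(cf4$pass)
  expect_equal(cf4$reason, "insufficient coverage")
})

test_that("consistency is monotone in the required count", {
  set.seed(9)
  for (i in 1:20) {
    a <- runif(9, 0, 0.4); b <- runif(9, 0.2, 0.9)
    passes <- vapply(1:9, function(k)
      consistency_filter(a, b, "hyper", k)$pass, logical(1))
    expect_true(all(diff(rev(passes)) >= 0 | !any(passes)))
    if (passes[9]) expect_true(all(passes))
  }
})

test_that("an implanted region is recovered as a single hyper DMR", {
  set.seed(1234)
  n_bg <- 260; n_imp <- 12
  pos <- c(seq(1000, by = 500, length.out = n_bg),
           seq(200000, by = 15, length.out = n_imp))
  mu <- matrix(0.05, n_bg + n_imp, 18)
  mu[(n_bg + 1):(n_bg + n_imp), 10:18] <- 0.55
  cov <- matrix(rpois(18 * (n_bg + n_imp), 20), ncol = 18)
  mc <- matrix(rbinom(length(cov), cov, as.vector(mu)), ncol = 18)
  ms <- toy_methylome(mc, cov, 9, 9, pos = pos)
  g <- list(control = paste0("c", 1:9), stress = paste0("s", 1:9))
  # 10,000 permutations let single sites reach p ~ 1e-4, small enough for
  # the step-up rule to admit a 12-site region among ~270 tested sites
  cfg <- dmr_config("rice_root", master_seed = 77L)
  dmrs <- call_dmrs(ms, g, cfg)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$direction, "hyper")
  expect_lte(dmrs$start, 200000L + 15L)
  expect_gte(dmrs$end, 200000L + 15L * (n_imp - 2L))
  expect_gte(dmrs$n_sites, 8L)
  expect_true(dmrs$passed_consistency)
  # audit: every member site of the span is at or below the chosen cutoff
  sr <- attr(dmrs, "site_results")
  cal <- attr(dmrs, "calibration")
  member <- sr$pos >= dmrs$start & sr$pos <= dmrs$end & sr$direction == "hyper"
  expect_gte(sum(sr$pvalue[member] <= cal$pvalue_cutoff, na.rm = TRUE),
             dmrs$n_sites)
  lev <- attr(dmrs, "sample_levels")
  expect_equal(dim(lev), c(1L, 18L))
  expect_gt(mean(lev[1, 10:18]), mean(lev[1, 1:9]) + 0.3)
})

test_that("degenerate inputs fail loudly", {
  samp <- data.frame(sample_id = "a", condition = "plus_pi", tissue = "root",
                     timepoint = 1L, replicate = 1L, genotype = "WT")
  empty <- structure(list(sites = data.frame(chrom = character(),
                                             pos = integer(),
                                             strand = character(),
                                             context = character()),
                          mc = matrix(0L, 0, 1), cov = matrix(0L, 0, 1),
                          samples = samp, spike_in_chrom = NA),
                     class = "methylome_set")
  expect_error(call_dmrs(empty, list(control = "a", stress = "a"),
                         dmr_config()), "empty|>= 2")
})

test_that("profiles carry the study thresholds", {
  expect_equal(dmr_config("rice_root")[c("target_fdr", "min_sites",
                                         "k_required")],
               list(target_fdr = 0.01, min_sites = 8L, k_required = 7L))
  expect_equal(dmr_config("arabidopsis")[c("target_fdr", "min_sites",
                                           "k_required")],
               list(target_fdr = 0.2, min_sites = 5L, k_required = 2L))
  expect_equal(dmr_config("rice_shoot")$target_fdr, 0.05)
  expect_equal(dmr_config("panicle")$alpha_persistence, 0.1)
  expect_equal(dmr_config("rice_root", max_gap = 300L)$max_gap, 300L)
})
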