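test_that("nearest-gene distances are signed and binned strand-aware", {
  genes <- toy_genes(list("chr1", 5000, 8000, "+", "gA"),
                     list("chr1", 20000, 24000, "-", "gB"))
  d <- function(s, e) assign_nearest_gene(
    data.frame(chrom = "chr1", start = s, end = e), genes)
  # 500 bp upstream of a + strand TSS
  x <- d(4000, 4500)
  expect_equal(x$nearest_gene, "gA")
  expect_equal(x$signed_distance, -500)
  expect_equal(as.character(x$distance_bin), "0-1kb")
  # 1500 bp upstream -> next bin
  expect_equal(as.character(d(3000, 3500)$distance_bin), "1-2kb")
  # inside the span
  x <- d(6000, 6100)
  expect_equal(x$signed_distance, 0)
  expect_equal(as.character(x$distance_bin), "gene_body")
  # right of a - strand gene is upstream of its TSS (negative)
  x <- d(24800, 24900)
  expect_equal(x$nearest_gene, "gB")
  expect_equal(x$signed_distance, -800)
  # left of the - strand gene is downstream of its TES (positive)
  x <- d(17500, 17700)
  expect_equal(x$signed_distance, 2300)
  expect_equal(as.character(x$distance_bin), "2-4kb")
})

test_that("nearest-gene assignment matches an exhaustive scan on random toys", {
  set.seed(15)
  for (rep in 1:5) {
    n_g <- 12
    starts <- sort(sample.int(200000, n_g))
    genes <- data.frame(chrom = "chr1", start = starts,
                        end = starts + sample(500:2000, n_g, TRUE),
                        strand = sample(c("+", "-"), n_g, TRUE),
                        id = sprintf("g%02d", sample(n_g)),
                        stringsAsFactors = FALSE)
    dmr_s <- sort(sample.int(200000, 20))
    dmrs <- data.frame(chrom = "chr1", start = dmr_s, end = dmr_s + 150)
    got <- assign_nearest_gene(dmrs, genes)
    for (i in seq_len(nrow(dmrs))) {
      o <- oracle_nearest("chr1", dmrs$start[i], dmrs$end[i], genes)
      expect_equal(got$nearest_gene[i], o$id)
      expect_equal(got$signed_distance[i], o$dist)
    }
  }
})

test_that("DMRs off every gene chromosome stay unassigned with a warning", {
  genes <- toy_genes(list("chr1", 100, 500, "+", "gA"))
  expect_warning(
    out <- assign_nearest_gene(data.frame(chrom = "chrX", start = 1, end = 50),
                               genes),
    "unassigned")
  expect_true(is.na(out$nearest_gene))
  expect_error(assign_nearest_gene(data.frame(chrom = "chr1", start = 1,
                                              end = 50), genes[0, ]),
               "empty")
})

test_that("genome-normalized bins match hand-counted tiles on a toy genome", {
  # one + strand gene at 4001-6000 on a 10 kb chromosome, 200 bp tiles:
  # midpoints 101, 301, ... Tiles with midpoint in [4001,6000] -> gene_body
  genes <- toy_genes(list("chr1", 4001, 6000, "+", "g1"))
  dmrs <- data.frame(chrom = "chr1", start = c(4500, 3500, 9900),
                     end = c(4600, 3600, 9950))
  out <- normalized_distance_distribution(dmrs, genes,
                                          c(chr1 = 10000L), tile_bp = 200L)
  expect_equal(out$bin, c("gene_body", "0-1kb", "1-2kb", "2-4kb", "4-6kb",
                          ">6kb"))
  # midpoints 101..9901 step 200: gene_body 4101..5901 -> 10 tiles;
  # 0-1kb: 3101..3901 and 6101..6901 -> 10; 1-2kb: 2101..2901, 7101..7901
  # -> 10; 2-4kb: 101..1901, 8101..9901 -> 20; nothing farther on 10 kb
  expect_equal(out$n_genome_windows, c(10L, 10L, 10L, 20L, 0L, 0L))
  expect_equal(out$n_dmrs, c(1L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(out$normalized_value[1], 1 / 10)
  expect_error(normalized_distance_distribution(dmrs, genes,
                                                c(chr1 = 10000L), 0),
               "config error")
})

test_that("bin counts are conserved over assigned DMRs", {
  set.seed(3)
  genes <- toy_genes(list("chr1", 10000, 12000, "+", "gA"),
                     list("chr1", 50000, 53000, "-", "gB"))
  s <- sample.int(60000, 40)
  dmrs <- assign_nearest_gene(data.frame(chrom = "chr1", start = s,
                                         end = s + 100), genes)
  expect_equal(sum(table(dmrs$distance_bin)), 40L)
})

test_that("TE overlap uses inclusive coordinates and reports every hit", {
  tes <- data.frame(chrom = "chr1", start = c(1150L, 100L, 1190L),
                    end = c(1400L, 999L, 1210L), strand = "+",
                    id = c("TE1", "TE2", "TE3"),
                    te_class = c("MITE", "LTR", "LINE"),
                    stringsAsFactors = FALSE)
  dmr <- data.frame(dmr_id = "d1", chrom = "chr1", start = 1000L, end = 1200L)
  ov <- te_overlap(dmr, tes)
  expect_equal(nrow(ov), 2L)                       # spans TE1 and TE3
  expect_equal(ov$overlap_bp[ov$te_id == "TE1"], 51L)   # 1150..1200 inclusive
  expect_equal(ov$overlap_bp[ov$te_id == "TE3"], 11L)
  # adjacency in inclusive coordinates is not overlap
  expect_equal(nrow(te_overlap(data.frame(dmr_id = "d2", chrom = "chr1",
                                          start = 1000L, end = 1100L),
                               tes[2, ])), 0L)
  # symmetry of the overlap length
  rev_ov <- te_overlap(data.frame(dmr_id = "TE1", chrom = "chr1",
                                  start = 1150L, end = 1400L),
                       data.frame(chrom = "chr1", start = 1000L, end = 1200L,
                                  strand = "+", id = "d1", te_class = "x"))
  expect_equal(rev_ov$overlap_bp, 51L)
  summ <- te_class_summary(dmr, ov)
  expect_equal(summ$prop_te_overlap, 1)
  expect_setequal(summ$class_summary$te_class, c("MITE", "LINE"))
})

test_that("expression classes gate on FDR then bin the fold change", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2fc = c(2.3, 1.2, -1.5, 3),
                   qvalue = c(0.001, 0.01, 0.01, 0.2),
                   mean_expr_control = 1, mean_expr_stress = 1)
  cls <- expression_class(c("g1", "g2", "g3", "g4", "missing"), de)
  expect_equal(as.character(cls),
               c("up>4", "up2-4", "down>2", "ns", "absent"))
})

test_that("annotate_dmrs combines genes, TEs and expression", {
  genes <- toy_genes(list("chr1", 5000, 8000, "+", "g1"))
  tes <- data.frame(chrom = "chr1", start = 4000L, end = 4700L, strand = "+",
                    id = "TE1", te_class = "MITE", stringsAsFactors = FALSE)
  de <- data.frame(gene_id = "g1", log2fc = 2.5, qvalue = 0.001,
                   mean_expr_control = 2, mean_expr_stress = 11)
  dmrs <- data.frame(dmr_id = "d1", chrom = "chr1", start = 4400L,
                     end = 4600L, direction = "hyper", n_sites = 10L)
  ann <- annotate_dmrs(dmrs, genes, tes, de)
  expect_equal(ann$nearest_gene, "g1")
  expect_equal(ann$signed_distance, -400)
  expect_true(ann$te_overlap)
  expect_equal(ann$te_classes, "MITE")
  expect_equal(as.character(ann$expression_class), "up>4")
})
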