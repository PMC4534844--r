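# Small in-code fixtures shared across test files.

allc_df <- function(chrom, pos, strand = "+", context = "CHH",
                    mc = 0L, total = 10L) {
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             context = rep_len(context, length(pos)),
             mc_reads = rep_len(as.integer(mc), length(pos)),
             total_reads = rep_len(as.integer(total), length(pos)),
             stringsAsFactors = FALSE)
}

random_allc <- function(n = 40L, chroms = c("chr1", "chr2"), seed = 1L) {
  set.seed(seed)
  pos_by <- lapply(chroms, function(ch) sort(sample.int(100000L, n)))
  tot <- rpois(n * length(chroms), 12)
  data.frame(chrom = rep(chroms, each = n),
             pos = unlist(pos_by),
             strand = sample(c("+", "-"), n * length(chroms), replace = TRUE),
             context = sample(c("CG", "CHG", "CHH"), n * length(chroms),
                              replace = TRUE),
             mc_reads = rbinom(n * length(chroms), tot, 0.3),
             total_reads = tot, stringsAsFactors = FALSE)
}

# Two-group methylome set built directly from count matrices.
toy_methylome <- function(mc, cov, n_control, n_stress,
                          pos = seq_len(nrow(mc)) * 50L, chrom = "chr1",
                          context = "CHH", spike = NA) {
  samp <- data.frame(
    sample_id = c(sprintf("c%d", seq_len(n_control)),
                  sprintf("s%d", seq_len(n_stress))),
    condition = rep(c("plus_pi", "minus_pi"), c(n_control, n_stress)),
    tissue = "root", timepoint = 21L,
    replicate = c(seq_len(n_control), seq_len(n_stress)),
    genotype = "WT", stringsAsFactors = FALSE)
  dimnames(mc) <- dimnames(cov) <- list(NULL, samp$sample_id)
  structure(list(sites = data.frame(chrom = chrom, pos = as.integer(pos),
                                    strand = "+",
                                    context = rep_len(context, nrow(mc)),
                                    stringsAsFactors = FALSE),
                 mc = mc, cov = cov, samples = samp, spike_in_chrom = spike),
            class = "methylome_set")
}

toy_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]], id = r[[5]],
               stringsAsFactors = FALSE)))
}
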