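#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator.  The defaults
#' emulate a phosphate-starvation root experiment: a small two-chromosome
#' genome plus an unmethylated spike-in chromosome, TE-dense annotation
#' with a MITE-heavy class mix (69% MITE, the dominant rice TE class),
#' plant-like baseline methylation (TEs high in CG/CHG, low CHH;
#' background near zero outside CG gene-body methylation), ~20x coverage
#' with mild beta-binomial replicate overdispersion, 0.5% spike-in
#' non-conversion, and a 9-vs-9 design pooling three late stress
#' timepoints.  Implanted DMRs default to CHH hypermethylation of 12-site
#' runs inside TEs near genes with an effect of 0.5.
#'
#' @param genome Named vector of chromosome lengths (bp).
#' @param spike_in_chrom,spike_in_length Name and length of the
#'   unmethylated control chromosome.
#' @param n_genes,n_tes Feature counts.
#' @param te_class_mix Named proportions of TE classes.
#' @param te_near_gene_frac Fraction of TEs placed within 1 kb of a gene.
#' @param baseline_levels List with `te` and `background` per-context
#'   methylation levels.
#' @param site_spacing Mean spacing between cytosine sites (bp).
#' @param context_mix Named sampling proportions of CG/CHG/CHH contexts.
#' @param coverage_mean Mean reads per site (Poisson).
#' @param dispersion Beta-binomial overdispersion rho in `[0, 1)`; 0 gives
#'   pure binomial counts.
#' @param nc_rate Spike-in non-conversion rate injected at the read level:
#'   observed proportion = level + (1 - level) * nc_rate.
#' @param design Sample sheet data.frame (see [design_rice_root()],
#'   [design_recovery()]).
#' @param n_implants,implant_delta,implant_sites,implant_context,implant_direction
#'   Defaults used when building implants automatically.
#' @param implants Optional explicit implant data.frame (locus rule
#'   columns: chrom, start, direction, delta, n_sites, context,
#'   persistence_class); `NULL` = choose TE loci automatically.
#' @param seed Master seed; identical config + seed gives byte-identical
#'   output.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(genome = c(chr1 = 60000L, chr2 = 60000L),
                       spike_in_chrom = "lambda",
                       spike_in_length = 4000L,
                       n_genes = 16L, n_tes = 30L,
                       te_class_mix = c(MITE = 0.69, LTR = 0.13, LINE = 0.08,
                                        SINE = 0.05, Helitron = 0.05),
                       te_near_gene_frac = 0.7,
                       baseline_levels = list(
                         te = c(CG = 0.80, CHG = 0.50, CHH = 0.05),
                         background = c(CG = 0.10, CHG = 0.02, CHH = 0.02)),
                       site_spacing = 30L,
                       context_mix = c(CG = 0.25, CHG = 0.15, CHH = 0.60),
                       coverage_mean = 20,
                       dispersion = 0.01,
                       nc_rate = 0.005,
                       design = design_rice_root(),
                       n_implants = 8L, implant_delta = 0.5,
                       implant_sites = 12L, implant_context = "CHH",
                       implant_direction = "hyper",
                       implants = NULL,
                       seed = 1L) {
  stopifnot(all(te_class_mix >= 0), abs(sum(te_class_mix) - 1) < 1e-6,
            dispersion >= 0, dispersion < 1,
            nc_rate >= 0, nc_rate <= 1,
            implant_delta > 0, implant_delta <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Rice-root style 9-vs-9 design
#'
#' Three biological replicates per condition at three pooled late
#' timepoints (21, 22, 24 days), giving 9 control (+Pi) and 9 stress
#' (-Pi) samples.
#' @return Sample sheet data.frame.
#' @export
design_rice_root <- function() {
  g <- expand.grid(replicate = 1:3, timepoint = c(21L, 22L, 24L),
                   condition = c("plus_pi", "minus_pi"),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("root_%dd_%s_r%d", g$timepoint,
                                 ifelse(g$condition == "plus_pi", "pPi", "mPi"),
                                 g$replicate),
             condition = g$condition, tissue = "root",
             timepoint = g$timepoint, replicate = g$replicate,
             genotype = "WT", stringsAsFactors = FALSE)
}

#' Stress/recovery triplicate design
#'
#' Control (+Pi), stress (-Pi) and resupply (recovery) groups at a single
#' late timepoint, `n_rep` replicates each.
#' @param n_rep Replicates per condition (default 3).
#' @param timepoint Sampling day (default 52).
#' @return Sample sheet data.frame.
#' @export
design_recovery <- function(n_rep = 3L, timepoint = 52L) {
  g <- expand.grid(replicate = seq_len(n_rep),
                   condition = c("plus_pi", "minus_pi", "resupply"),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("root_%dd_%s_r%d", timepoint,
                                 c(plus_pi = "pPi", minus_pi = "mPi",
                                   resupply = "res")[g$condition],
                                 g$replicate),
             condition = g$condition, tissue = "root",
             timepoint = timepoint, replicate = g$replicate,
             genotype = "WT", stringsAsFactors = FALSE)
}

#' Group assignment implied by a sample sheet
#'
#' Maps conditions to the standard group names: `control` = plus_pi,
#' `stress` = minus_pi, `recovery` = resupply (when present).
#' @param samples Sample sheet data.frame.
#' @return Named list of sample-id vectors.
#' @export
design_groups <- function(samples) {
  g <- list(control = samples$sample_id[samples$condition == "plus_pi"],
            stress = samples$sample_id[samples$condition == "minus_pi"])
  if (any(samples$condition == "resupply"))
    g$recovery <- samples$sample_id[samples$condition == "resupply"]
  g
}

#' Beta-binomial random counts
#'
#' Mean `mu`, intra-class correlation `rho`; `rho = 0` reduces to the
#' binomial.
#' @keywords internal
rbetabinom <- function(n, size, mu, rho) {
  if (rho == 0) return(stats::rbinom(n, size, mu))
  s <- (1 - rho) / rho
  p <- ifelse(mu <= 0, 0, ifelse(mu >= 1, 1,
              stats::rbeta(n, mu * s, (1 - mu) * s)))
  stats::rbinom(n, size, p)
}

#' Simulate gene and TE annotation
#'
#' Genes are placed non-overlapping in per-chromosome slots; a
#' configurable fraction of TEs is placed within 1 kb of a random gene
#' (flanking, mimicking the TE-near-gene enrichment the implants exploit),
#' the rest intergenically.  Classes are sampled from the configured mix.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` and `tes` data.frames (the [read_features()]
#'   layout).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  total <- sum(cfg$genome)
  genes <- list(); slot_id <- 0L
  for (ch in names(cfg$genome)) {
    len <- cfg$genome[[ch]]
    k <- max(1L, round(cfg$n_genes * len / total))
    slot <- len / k
    for (j in seq_len(k)) {
      slot_id <- slot_id + 1L
      if (slot_id > cfg$n_genes) break
      glen <- round(stats::runif(1, min(1500, slot * 0.3), min(3000, slot * 0.6)))
      start <- round((j - 1) * slot + stats::runif(1, slot * 0.15, slot * 0.35))
      genes[[slot_id]] <- data.frame(
        chrom = ch, start = start, end = min(start + glen - 1L, len),
        strand = sample(c("+", "-"), 1), id = sprintf("gene_%03d", slot_id),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)

  tes <- vector("list", cfg$n_tes)
  for (i in seq_len(cfg$n_tes)) {
    tlen <- round(stats::runif(1, 250, 600))
    if (stats::runif(1) < cfg$te_near_gene_frac) {
      g <- genes[sample(nrow(genes), 1), ]
      gap <- round(stats::runif(1, 50, 1000))
      start <- if (stats::runif(1) < 0.5) g$start - gap - tlen else g$end + gap
      chrom <- g$chrom
    } else {
      chrom <- sample(names(cfg$genome), 1)
      start <- round(stats::runif(1, 1, cfg$genome[[chrom]] - tlen))
    }
    start <- max(1L, min(start, cfg$genome[[chrom]] - tlen))
    tes[[i]] <- data.frame(
      chrom = chrom, start = start, end = start + tlen - 1L,
      strand = sample(c("+", "-"), 1), id = sprintf("te_%03d", i),
      te_class = sample(names(cfg$te_class_mix), 1, prob = cfg$te_class_mix),
      stringsAsFactors = FALSE)
  }
  tes <- do.call(rbind, tes)
  list(genes = genes[order(genes$chrom, genes$start), ],
       tes = tes[order(tes$chrom, tes$start), ])
}

#' Choose implant loci inside TEs near genes
#' @keywords internal
default_implants <- function(cfg, genes, tes) {
  if (cfg$n_implants == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      direction = character(), delta = numeric(),
                      n_sites = integer(), context = character(),
                      persistence_class = character(),
                      stringsAsFactors = FALSE))
  span_needed <- cfg$implant_sites * 12L
  near <- suppressWarnings(assign_nearest_gene(tes, genes))
  ok <- which(tes$end - tes$start + 1L >= span_needed + 10L &
                abs(near$signed_distance) <= 1000)
  if (length(ok) < cfg$n_implants)
    ok <- union(ok, which(tes$end - tes$start + 1L >= span_needed + 10L))
  # truth loci must not overlap: greedily skip TEs that collide with an
  # already-chosen host
  pick <- integer(0)
  for (i in sort(ok)) {
    clash <- any(tes$chrom[pick] == tes$chrom[i] &
                   tes$start[pick] <= tes$end[i] &
                   tes$end[pick] >= tes$start[i])
    if (!clash) pick <- c(pick, i)
    if (length(pick) == cfg$n_implants) break
  }
  if (length(pick) < cfg$n_implants)
    stop("config error: not enough disjoint TEs can host ", cfg$n_implants,
         " implants of ", cfg$implant_sites, " sites")
  has_recovery <- any(cfg$design$condition == "resupply")
  pclass <- if (has_recovery)
    rep_len(c("persistent", "transient"), cfg$n_implants) else
    rep("na", cfg$n_implants)
  data.frame(chrom = tes$chrom[pick],
             start = tes$start[pick] + 5L,
             direction = cfg$implant_direction,
             delta = cfg$implant_delta,
             n_sites = cfg$implant_sites,
             context = cfg$implant_context,
             persistence_class = pclass,
             stringsAsFactors = FALSE)
}

#' Simulate per-sample methylomes with implanted DMRs and spike-in
#'
#' Each cytosine gets a true level from the context- and TE-dependent
#' baseline; implant loci add (or subtract) `delta` for stress samples,
#' and for recovery samples according to the implant's persistence class
#' (`persistent` keeps the stressed level, `transient` reverts to
#' baseline).  Read totals are Poisson(`coverage_mean`); methylated counts
#' are beta-binomial around the observed proportion
#' `level + (1 - level) * nc_rate`, which injects non-conversion at the
#' read level.  The spike-in chromosome is generated with true level 0, so
#' its observed proportion equals the non-conversion rate.
#'
#' @param cfg A [sim_config()].
#' @param genes,tes Annotation from [simulate_annotation()].
#' @return List with `ms` (a [methylome_set()]) and `truth` (one row per
#'   implant: locus, direction, delta, context, persistence_class,
#'   nearest_gene, te_overlap).
#' @export
simulate_methylomes <- function(cfg, genes, tes) {
  set.seed(cfg$seed + 1L)
  implants <- cfg$implants %||% default_implants(cfg, genes, tes)
  implants$end <- implants$start + (implants$n_sites - 1L) * 12L
  if (any(implants$end > cfg$genome[implants$chrom]))
    stop("config error: implant outside the genome")

  sites <- do.call(rbind, lapply(names(cfg$genome), function(ch) {
    n <- round(cfg$genome[[ch]] / cfg$site_spacing)
    data.frame(chrom = ch,
               pos = sort(sample.int(cfg$genome[[ch]], n)),
               strand = sample(c("+", "-"), n, replace = TRUE),
               context = sample(names(cfg$context_mix), n, replace = TRUE,
                                prob = cfg$context_mix),
               stringsAsFactors = FALSE)
  }))
  # carve out implant spans, then lay down evenly spaced implant site runs
  for (i in seq_len(nrow(implants))) {
    drop <- sites$chrom == implants$chrom[i] &
      sites$pos >= implants$start[i] - 5L & sites$pos <= implants$end[i] + 5L
    sites <- sites[!drop, , drop = FALSE]
  }
  imp_sites <- do.call(rbind, lapply(seq_len(nrow(implants)), function(i)
    data.frame(chrom = implants$chrom[i],
               pos = implants$start[i] + (seq_len(implants$n_sites[i]) - 1L) * 12L,
               strand = "+", context = implants$context[i],
               implant = i, stringsAsFactors = FALSE)))
  sites$implant <- 0L
  sites <- rbind(sites, imp_sites)
  # spike-in control sites
  spike <- data.frame(chrom = cfg$spike_in_chrom,
                      pos = seq(5L, cfg$spike_in_length, by = 10L),
                      strand = "+",
                      context = sample(CONTEXTS,
                                       length(seq(5L, cfg$spike_in_length, by = 10L)),
                                       replace = TRUE, prob = c(.25, .15, .6)),
                      implant = -1L, stringsAsFactors = FALSE)
  sites <- rbind(sites, spike)
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), ]
  rownames(sites) <- NULL

  in_te <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(tes))) {
    hit <- sites$chrom == tes$chrom[i] & sites$pos >= tes$start[i] &
      sites$pos <= tes$end[i]
    in_te <- in_te | hit
  }
  base <- ifelse(in_te, cfg$baseline_levels$te[sites$context],
                 cfg$baseline_levels$background[sites$context])
  base[sites$implant == -1L] <- 0      # spike-in truly unmethylated

  n_s <- nrow(sites); samp <- cfg$design
  mc <- cov <- matrix(0L, n_s, nrow(samp),
                      dimnames = list(NULL, samp$sample_id))
  for (j in seq_len(nrow(samp))) {
    lev <- base
    cond <- samp$condition[j]
    for (i in seq_len(nrow(implants))) {
      idx <- sites$implant == i
      sgn <- if (implants$direction[i] == "hyper") 1 else -1
      shifted <- pmin(1, pmax(0, base[idx] + sgn * implants$delta[i]))
      if (cond == "minus_pi") lev[idx] <- shifted
      if (cond == "resupply" &&
          implants$persistence_class[i] == "persistent") lev[idx] <- shifted
    }
    total <- stats::rpois(n_s, cfg$coverage_mean)
    obs <- lev + (1 - lev) * cfg$nc_rate
    mc[, j] <- rbetabinom(n_s, total, obs, cfg$dispersion)
    cov[, j] <- total
  }

  ms <- structure(list(sites = sites[, c("chrom", "pos", "strand", "context")],
                       mc = mc, cov = cov, samples = samp,
                       spike_in_chrom = cfg$spike_in_chrom),
                  class = "methylome_set")
  nearest <- suppressWarnings(assign_nearest_gene(implants, genes))
  ovl <- te_overlap(cbind(implants, dmr_id = sprintf("implant_%02d",
                                                     seq_len(nrow(implants)))),
                    tes)
  truth <- data.frame(implant_id = sprintf("implant_%02d", seq_len(nrow(implants))),
                      chrom = implants$chrom, start = implants$start,
                      end = implants$end, direction = implants$direction,
                      delta = implants$delta, context = implants$context,
                      persistence_class = implants$persistence_class,
                      nearest_gene = nearest$nearest_gene,
                      te_overlap = sprintf("implant_%02d",
                                           seq_len(nrow(implants))) %in% ovl$dmr_id,
                      stringsAsFactors = FALSE)
  list(ms = ms, truth = truth)
}

#' Simulate a matched differential-expression table
#'
#' Genes nearest to hyper implants are flagged as strongly induced
#' (log2 fold change 2.2-3.6, q < 0.001) with probability `prob_linked`;
#' all other genes get null-like fold changes and non-significant
#' q-values.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene annotation.
#' @param truth Truth table from [simulate_methylomes()].
#' @param prob_linked Probability that an implant's nearest gene is
#'   induced (default 1).
#' @return DE data.frame in the [read_de_table()] layout.
#' @export
simulate_de_table <- function(cfg, genes, truth, prob_linked = 1) {
  set.seed(cfg$seed + 2L)
  linked <- unique(truth$nearest_gene[truth$direction == "hyper"])
  linked <- linked[!is.na(linked)]
  linked <- linked[stats::runif(length(linked)) < prob_linked]
  n <- nrow(genes)
  is_l <- genes$id %in% linked
  log2fc <- ifelse(is_l, stats::runif(n, 2.2, 3.6), stats::rnorm(n, 0, 0.3))
  q <- ifelse(is_l, stats::runif(n, 1e-6, 1e-3), stats::runif(n, 0.2, 1))
  ctrl <- stats::runif(n, 1, 50)
  data.frame(gene_id = genes$id, log2fc = log2fc, qvalue = q,
             mean_expr_control = ctrl, mean_expr_stress = ctrl * 2^log2fc,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic experiment
#'
#' Runs [simulate_annotation()], [simulate_methylomes()] and
#' [simulate_de_table()] under one config.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes`, `tes`, `ms`, `truth`, `de`, `config`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  meth <- simulate_methylomes(cfg, ann$genes, ann$tes)
  de <- simulate_de_table(cfg, ann$genes, meth$truth)
  list(genes = ann$genes, tes = ann$tes, ms = meth$ms, truth = meth$truth,
       de = de, config = cfg)
}

#' Write a simulated experiment in the pipeline's input formats
#'
#' Produces exactly what the readers consume: one allc TSV per sample, a
#' GFF3 gene annotation, a BED TE annotation (name field `id;class`), a DE
#' TSV, a sample sheet TSV with `allc_path`, a truth TSV and a YAML config
#' snapshot.
#'
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ms <- sim$ms
  for (s in colnames(ms$mc)) {
    df <- data.frame(ms$sites, mc_reads = ms$mc[, s],
                     total_reads = ms$cov[, s])
    write_allc(df, file.path(dir, paste0(s, ".allc.tsv")))
  }
  gr <- GenomicRanges::GRanges(sim$genes$chrom,
                               IRanges::IRanges(sim$genes$start, sim$genes$end),
                               strand = sim$genes$strand)
  gr$type <- "gene"; gr$ID <- sim$genes$id
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  bed <- GenomicRanges::GRanges(sim$tes$chrom,
                                IRanges::IRanges(sim$tes$start, sim$tes$end),
                                strand = sim$tes$strand)
  bed$name <- paste(sim$tes$id, sim$tes$te_class, sep = ";")
  rtracklayer::export(bed, file.path(dir, "tes.bed"), format = "bed")
  utils::write.table(sim$de, file.path(dir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sheet <- sim$ms$samples
  sheet$allc_path <- paste0(sheet$sample_id, ".allc.tsv")
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  scal <- cfg[vapply(cfg, function(x)
    is.atomic(x) && length(x) <= 8 && !is.data.frame(x), logical(1))]
  yaml::write_yaml(scal, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate a site-level two-group mixture (no spatial structure)
#'
#' A stripped-down generator for calibration studies of the per-site test:
#' `n_sites` independent cytosines, a fraction of which carry a true group
#' difference in methylation proportion; everything else follows the same
#' count model as [simulate_methylomes()] (Poisson coverage, beta-binomial
#' replicate noise).  Sites are spaced 1 kb apart so no merging can occur.
#'
#' @param n_sites Number of cytosines (default 2000).
#' @param n_control,n_stress Replicates per group.
#' @param prop_diff Fraction of truly differential sites (default 0.1).
#' @param p_control,p_stress Methylation proportions (null sites use
#'   `p_control` in both groups).
#' @param coverage_mean,dispersion Count model parameters.
#' @param seed Seed.
#' @return List with `ms` (a [methylome_set()] without spike-in), `truth`
#'   (logical vector, TRUE = truly differential) and `groups`.
#' @export
simulate_site_mixture <- function(n_sites = 2000L, n_control = 9L,
                                  n_stress = 9L, prop_diff = 0.1,
                                  p_control = 0.1, p_stress = 0.6,
                                  coverage_mean = 20, dispersion = 0.01,
                                  seed = 1L) {
  set.seed(seed)
  truth <- seq_len(n_sites) <= round(prop_diff * n_sites)
  samp <- data.frame(
    sample_id = c(sprintf("ctrl_r%d", seq_len(n_control)),
                  sprintf("stress_r%d", seq_len(n_stress))),
    condition = rep(c("plus_pi", "minus_pi"), c(n_control, n_stress)),
    tissue = "root", timepoint = 21L,
    replicate = c(seq_len(n_control), seq_len(n_stress)),
    genotype = "WT", stringsAsFactors = FALSE)
  n_samp <- nrow(samp)
  mc <- cov <- matrix(0L, n_sites, n_samp,
                      dimnames = list(NULL, samp$sample_id))
  for (j in seq_len(n_samp)) {
    mu <- ifelse(truth & samp$condition[j] == "minus_pi",
                 p_stress, p_control)
    total <- stats::rpois(n_sites, coverage_mean)
    mc[, j] <- rbetabinom(n_sites, total, mu, dispersion)
    cov[, j] <- total
  }
  ms <- structure(list(sites = data.frame(chrom = "chr1",
                                          pos = seq_len(n_sites) * 1000L,
                                          strand = "+", context = "CHH",
                                          stringsAsFactors = FALSE),
                       mc = mc, cov = cov, samples = samp,
                       spike_in_chrom = NA),
                  class = "methylome_set")
  list(ms = ms, truth = truth, groups = design_groups(samp))
}
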