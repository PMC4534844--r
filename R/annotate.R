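#' Assign each DMR to its nearest gene with a signed distance and bin
#'
#' A DMR overlapping a gene span gets distance 0 and bin `gene_body`
#' (overlapping several genes, the one with the largest overlap wins, ties
#' broken by lexicographically smaller id).  Otherwise the distance is the
#' minimal gap to the gene, signed strand-aware: negative upstream of the
#' TSS, positive downstream of the TES.  The nearest gene minimizes the
#' unsigned distance (ties lexicographic).  Distances are binned as
#' `gene_body`, `0-1kb`, `1-2kb`, `2-4kb`, `4-6kb`, `>6kb`.
#'
#' @param dmrs data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally `dmr_id`.
#' @param genes Gene feature data.frame from [read_features()].
#' @return `dmrs` with added columns `nearest_gene`, `signed_distance`,
#'   `distance_bin` (`NA` with a warning when the DMR's chromosome has no
#'   gene).
#' @export
assign_nearest_gene <- function(dmrs, genes) {
  if (!nrow(genes)) stop("gene list is empty")
  dmrs <- as.data.frame(dmrs)
  n <- nrow(dmrs)
  nearest <- rep(NA_character_, n)
  sdist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == dmrs$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    ov_bp <- pmax(0L, pmin(dmrs$end[i], g$end) - pmax(dmrs$start[i], g$start) + 1L)
    if (any(ov_bp > 0)) {
      cand <- which(ov_bp == max(ov_bp))
      pick <- cand[order(g$id[cand])][1]
      nearest[i] <- g$id[pick]
      sdist[i] <- 0
      next
    }
    left <- dmrs$end[i] < g$start          # DMR entirely 5' of span in genome coords
    gap <- ifelse(left, g$start - dmrs$end[i], dmrs$start[i] - g$end)
    # upstream-of-TSS iff (left & + strand) or (right & - strand)
    upstream <- left == (g$strand == "+")
    signed <- ifelse(upstream, -gap, gap)
    pick <- order(gap, g$id)[1]
    nearest[i] <- g$id[pick]
    sdist[i] <- signed[pick]
  }
  if (anyNA(nearest))
    warning(sum(is.na(nearest)),
            " DMR(s) unassigned: no gene on their chromosome")
  dmrs$nearest_gene <- nearest
  dmrs$signed_distance <- sdist
  dmrs$distance_bin <- distance_bin(sdist)
  dmrs
}

#' Bin an (unsigned) gene distance
#' @param signed_distance Signed distances (0 = within gene body).
#' @return Factor with levels gene_body, 0-1kb, 1-2kb, 2-4kb, 4-6kb, >6kb.
#' @export
distance_bin <- function(signed_distance) {
  d <- abs(signed_distance)
  lab <- ifelse(is.na(d), NA_character_,
         ifelse(d == 0, "gene_body",
         ifelse(d <= 1000, "0-1kb",
         ifelse(d <= 2000, "1-2kb",
         ifelse(d <= 4000, "2-4kb",
         ifelse(d <= 6000, "4-6kb", ">6kb"))))))
  factor(lab, levels = DISTANCE_BINS)
}

#' Genome-normalized distribution of DMR distances to genes
#'
#' Counts DMRs per distance bin and normalizes by the number of genomic
#' regions falling in that bin category: the genome is tiled into
#' non-overlapping `tile_bp` windows and each tile is assigned a bin by
#' applying the nearest-gene rule to its midpoint.  The tile size defaults
#' to 200 bp, on the order of a typical DMR.
#'
#' @param dmrs DMR data.frame (annotated or not; `distance_bin` is computed
#'   if absent).
#' @param genes Gene features.
#' @param genome_sizes Named vector of chromosome lengths (bp).
#' @param tile_bp Tile width in bp (default 200).
#' @return data.frame per bin: bin, n_genome_windows, n_dmrs,
#'   normalized_value (`n_dmrs / n_genome_windows`).
#' @export
normalized_distance_distribution <- function(dmrs, genes, genome_sizes,
                                             tile_bp = 200L) {
  if (tile_bp <= 0) stop("config error: tile_bp must be positive")
  if (is.null(dmrs$distance_bin)) dmrs <- assign_nearest_gene(dmrs, genes)
  tiles <- do.call(rbind, lapply(names(genome_sizes), function(ch) {
    s <- seq(1L, genome_sizes[[ch]], by = tile_bp)
    mid <- pmin(s + tile_bp %/% 2L, genome_sizes[[ch]])
    data.frame(chrom = ch, start = mid, end = mid)
  }))
  tiles <- suppressWarnings(assign_nearest_gene(tiles, genes))
  n_tiles <- table(tiles$distance_bin)
  n_dmrs <- table(dmrs$distance_bin)
  data.frame(bin = DISTANCE_BINS,
             n_genome_windows = as.integer(n_tiles[DISTANCE_BINS]),
             n_dmrs = as.integer(n_dmrs[DISTANCE_BINS]),
             normalized_value = as.numeric(n_dmrs[DISTANCE_BINS]) /
               as.numeric(n_tiles[DISTANCE_BINS]))
}

#' Transposable-element overlaps of DMRs
#'
#' Reports every TE with at least one bp of (1-based inclusive) overlap; a
#' DMR is "TE-overlapping" iff it has at least one entry, and may carry
#' several TE classes.
#'
#' @param dmrs DMR data.frame with `dmr_id`, `chrom`, `start`, `end`.
#' @param tes TE features from [read_features()] (with `te_class`).
#' @return data.frame with one row per (DMR, TE) overlap: dmr_id, te_id,
#'   te_class, overlap_bp.
#' @export
te_overlap <- function(dmrs, tes) {
  empty <- data.frame(dmr_id = character(), te_id = character(),
                      te_class = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(dmrs) || !nrow(tes)) return(empty)
  ids <- dmrs$dmr_id %||% paste0("region_", seq_len(nrow(dmrs)))
  gd <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start, dmrs$end))
  gt <- GenomicRanges::GRanges(tes$chrom,
                               IRanges::IRanges(tes$start, tes$end))
  hits <- GenomicRanges::findOverlaps(gd, gt)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gd)[qi], IRanges::ranges(gt)[si]))
  data.frame(dmr_id = ids[qi], te_id = tes$id[si],
             te_class = tes$te_class[si], overlap_bp = ov,
             stringsAsFactors = FALSE)
}

#' Summary of TE overlap proportions and class composition
#'
#' @param dmrs DMR data.frame.
#' @param overlaps Output of [te_overlap()].
#' @return List with `prop_te_overlap` (fraction of DMRs hitting any TE) and
#'   `class_summary` (data.frame: te_class, n_dmrs, proportion of
#'   TE-overlapping DMRs carrying that class).
#' @export
te_class_summary <- function(dmrs, overlaps) {
  ids <- dmrs$dmr_id %||% paste0("region_", seq_len(nrow(dmrs)))
  hit <- unique(overlaps$dmr_id)
  per_class <- unique(overlaps[, c("dmr_id", "te_class")])
  tab <- table(per_class$te_class)
  list(prop_te_overlap = length(hit) / max(1L, length(ids)),
       class_summary = data.frame(te_class = names(tab),
                                  n_dmrs = as.integer(tab),
                                  proportion = as.integer(tab) /
                                    max(1L, length(hit))))
}

#' Expression class of DMR-associated genes
#'
#' Classifies each gene's stress response from a differential-expression
#' table: `up>4` (induced more than 4-fold), `up2-4`, `down>2`, `ns` (no
#' significant change beyond 2-fold), `absent` (not in the table).
#' Significance requires `qvalue < alpha` on top of the fold-change
#' threshold.
#'
#' @param gene_ids Character vector of gene ids.
#' @param de DE table from [read_de_table()].
#' @param fc_thresholds Fold-change thresholds, default `c(2, 4)`.
#' @param alpha FDR gate (default 0.05).
#' @return Factor of classes aligned with `gene_ids`.
#' @export
expression_class <- function(gene_ids, de, fc_thresholds = c(2, 4),
                             alpha = 0.05) {
  lo <- log2(fc_thresholds[1]); hi <- log2(fc_thresholds[2])
  m <- match(gene_ids, de$gene_id)
  fc <- de$log2fc[m]; q <- de$qvalue[m]
  cls <- ifelse(is.na(m), "absent",
         ifelse(q >= alpha, "ns",
         ifelse(fc > hi, "up>4",
         ifelse(fc > lo, "up2-4",
         ifelse(fc < -lo, "down>2", "ns")))))
  factor(cls, levels = c("up>4", "up2-4", "down>2", "ns", "absent"))
}

#' Annotate a DMR set against genes, TEs and expression
#'
#' Convenience wrapper combining [assign_nearest_gene()], [te_overlap()]
#' and [expression_class()].
#'
#' @param dmrs A `dmr_set` or DMR data.frame.
#' @param genes,tes Feature data.frames.
#' @param de Optional DE table; when `NULL` the expression class is omitted.
#' @param alpha FDR gate for the expression class.
#' @return Annotated data.frame with nearest-gene, distance, bin,
#'   `te_overlap` flag, `te_classes` (collapsed ;-list) and
#'   `expression_class`; the full overlap table is attached as attribute
#'   `te_overlaps`.
#' @export
annotate_dmrs <- function(dmrs, genes, tes, de = NULL, alpha = 0.05) {
  ann <- assign_nearest_gene(as.data.frame(dmrs), genes)
  ov <- te_overlap(ann, tes)
  ids <- ann$dmr_id %||% paste0("region_", seq_len(nrow(ann)))
  ann$te_overlap <- ids %in% ov$dmr_id
  ann$te_classes <- vapply(ids, function(id) {
    cls <- unique(ov$te_class[ov$dmr_id == id])
    if (length(cls)) paste(sort(cls), collapse = ";") else NA_character_
  }, character(1))
  if (!is.null(de))
    ann$expression_class <- expression_class(ann$nearest_gene, de,
                                             alpha = alpha)
  attr(ann, "te_overlaps") <- ov
  ann
}
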