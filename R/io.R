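#' Read a per-cytosine "allc" count table
#'
#' An allc table is a 6-column TSV with one row per strand-resolved cytosine:
#' `chrom`, `pos` (1-based), `strand` (+/-), `context` (CG/CHG/CHH),
#' `mc_reads` (methylated basecalls), `total_reads` (total basecalls).
#' A header line is optional and detected automatically.
#'
#' @param path Path to the TSV file.
#' @return A data.frame sorted by (chrom, pos) with the six columns above.
#' @export
read_allc <- function(path) {
  if (!file.exists(path)) stop("allc file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "strand", "context",
                                        "mc_reads", "total_reads"))
  validate_allc(df, path)
}

validate_allc <- function(df, path = "<data>") {
  if (ncol(df) != 6L) stop("allc table must have 6 columns: ", path)
  names(df) <- c("chrom", "pos", "strand", "context", "mc_reads", "total_reads")
  df$context <- toupper(df$context)
  bad <- which(!df$context %in% CONTEXTS)
  if (length(bad))
    stop(sprintf("parse error in %s line %d: unknown context '%s'",
                 path, bad[1], df$context[bad[1]]))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("parse error in %s line %d: strand must be + or -",
                 path, bad[1]))
  if (!is.numeric(df$pos) || !is.numeric(df$mc_reads) ||
      !is.numeric(df$total_reads))
    stop("parse error in ", path, ": non-numeric pos/count column")
  bad <- which(df$pos < 1 | df$pos != round(df$pos))
  if (length(bad))
    stop(sprintf("validation error in %s line %d: pos must be a positive integer",
                 path, bad[1]))
  bad <- which(df$mc_reads < 0 | df$total_reads < 0)
  if (length(bad))
    stop(sprintf("validation error in %s line %d: negative read count",
                 path, bad[1]))
  bad <- which(df$mc_reads > df$total_reads)
  if (length(bad))
    stop(sprintf("validation error in %s line %d: mc_reads (%d) > total_reads (%d)",
                 path, bad[1], df$mc_reads[bad[1]], df$total_reads[bad[1]]))
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an allc table
#'
#' Inverse of [read_allc()]: `read_allc(write_allc(x, f))` reproduces `x`.
#'
#' @param df allc data.frame as returned by [read_allc()].
#' @param path Output path.
#' @param header Write a header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_allc <- function(df, path, header = TRUE) {
  df <- validate_allc(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read gene or TE features from GFF3 or BED
#'
#' The dialect is inferred from the file extension (`.gff`/`.gff3` vs
#' `.bed`).  BED half-open 0-based coordinates are converted to the package's
#' internal 1-based inclusive convention on read.  For TE features the class
#' is taken from the GFF3 `te_class` (or `class`) attribute, or from the BED
#' name field after a `;` separator (`id;class`).
#'
#' @param path Feature file.
#' @param kind `"gene"` or `"te"`.
#' @return data.frame with columns chrom, start, end, strand, id and, for
#'   `kind = "te"`, te_class.
#' @export
read_features <- function(path, kind = c("gene", "te")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("feature file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("gff", "gff3", "bed"))
    stop("format error: unknown feature file extension '.", ext, "'")
  if (file.size(path) == 0L ||
      !any(nzchar(trimws(grep("^#", readLines(path), invert = TRUE, value = TRUE))))) {
    warning("empty feature file: ", path)
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), id = character(),
                      stringsAsFactors = FALSE)
    if (kind == "te") out$te_class <- character()
    return(out)
  }
  gr <- rtracklayer::import(path, format = if (ext == "bed") "bed" else "gff3")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "+"
  meta <- S4Vectors::mcols(gr)
  nm <- if (ext == "bed") {
    as.character(meta$name)
  } else {
    id <- if ("ID" %in% names(meta)) as.character(meta$ID) else NA_character_
    if (all(is.na(id)) && "Name" %in% names(meta)) id <- as.character(meta$Name)
    id
  }
  if (kind == "te") {
    if (ext == "bed") {
      parts <- strsplit(nm, ";", fixed = TRUE)
      out$id <- vapply(parts, `[`, character(1), 1L)
      out$te_class <- vapply(parts, function(p)
        if (length(p) >= 2L) p[2L] else NA_character_, character(1))
    } else {
      out$id <- nm
      cls <- if ("te_class" %in% names(meta)) as.character(meta$te_class)
             else if ("class" %in% names(meta)) as.character(meta$class)
             else NA_character_
      out$te_class <- cls
    }
  } else {
    out$id <- nm
  }
  if (any(is.na(out$id)) || any(!nzchar(out$id)))
    stop("validation error: feature without an id in ", path)
  if (anyDuplicated(out$id))
    stop("validation error: duplicate feature ids in ", path)
  if (any(out$start > out$end))
    stop("validation error: start > end in ", path)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read a differential-expression table
#'
#' TSV with header `gene_id, log2fc, qvalue, mean_expr_control,
#' mean_expr_stress` (extra columns are ignored).
#'
#' @param path Path to the TSV.
#' @return Validated data.frame, one row per gene.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "qvalue", "mean_expr_control",
            "mean_expr_stress")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: DE table missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, need]
  if (anyDuplicated(df$gene_id))
    stop("validation error: duplicate gene_id in DE table: ",
         df$gene_id[duplicated(df$gene_id)][1])
  if (any(df$qvalue < 0 | df$qvalue > 1, na.rm = TRUE))
    stop("validation error: qvalue outside [0,1] in DE table")
  df
}

#' Read a sample sheet
#'
#' TSV with header `sample_id, condition, tissue, timepoint, replicate,
#' genotype` and optionally `allc_path` pointing at each sample's count
#' table (relative paths are resolved against the sheet's directory).
#'
#' @param path Path to the TSV.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "tissue", "timepoint", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: sample sheet missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("validation error: duplicate sample_id in sample sheet")
  if (is.null(df$genotype)) df$genotype <- "WT"
  if (!is.null(df$allc_path)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$allc_path)
    df$allc_path[rel] <- file.path(dirname(path), df$allc_path[rel])
  }
  df
}
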