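#' Gene models
#'
#' A gene model records the strand-aware TSS and TES (both genomic
#' coordinates, 0-based), the exon structure, and the biotype. On the `+`
#' strand `tss < tes`; on the `-` strand `tss > tes` (the TSS sits at the
#' genomically rightmost end). Exons are stored as list columns of 0-based
#' half-open (start, end) pairs, sorted and non-overlapping, contained in
#' `[min(tss, tes), max(tss, tes))`.
#'
#' @param gene_id character gene identifiers (unique).
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param tss,tes transcription start / end sites (bp, 0-based).
#' @param exon_starts,exon_ends lists of integer vectors, one per gene.
#' @param biotype `"protein_coding"` or `"other"`.
#' @return Data frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tes,
                        exon_starts, exon_ends,
                        biotype = "protein_coding") {
  n <- length(gene_id)
  if (!is.list(exon_starts)) exon_starts <- list(exon_starts)
  if (!is.list(exon_ends)) exon_ends <- list(exon_ends)
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(rep_len(chrom, n)),
    strand = as.character(rep_len(strand, n)),
    tss = as.integer(rep_len(tss, n)),
    tes = as.integer(rep_len(tes, n)),
    biotype = as.character(rep_len(biotype, n)),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- lapply(rep_len(exon_starts, n), as.integer)
  df$exon_ends <- lapply(rep_len(exon_ends, n), as.integer)
  validate_gene_models(df)
  class(df) <- c("gene_models", "data.frame")
  df
}

validate_gene_models <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop("gene_models: gene_id must be unique", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene_models: strand must be '+' or '-'", call. = FALSE)
  }
  if (!all(df$biotype %in% c("protein_coding", "other"))) {
    stop("gene_models: biotype must be 'protein_coding' or 'other'",
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]
    ee <- df$exon_ends[[i]]
    g0 <- min(df$tss[i], df$tes[i])
    g1 <- max(df$tss[i], df$tes[i])
    if (length(es) != length(ee) || length(es) == 0) {
      stop(sprintf("gene %s: exon start/end lists malformed", df$gene_id[i]),
           call. = FALSE)
    }
    if (any(ee <= es)) {
      stop(sprintf("gene %s: exon end <= start", df$gene_id[i]), call. = FALSE)
    }
    if (is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)])) {
      stop(sprintf("gene %s: exons must be sorted and non-overlapping",
                   df$gene_id[i]), call. = FALSE)
    }
    if (min(es) < g0 || max(ee) > g1) {
      stop(sprintf("gene %s: exons outside gene body", df$gene_id[i]),
           call. = FALSE)
    }
  }
  invisible(df)
}

is_gene_models <- function(x) inherits(x, "gene_models")

gene_span <- function(genes) {
  data.frame(start = pmin(genes$tss, genes$tes),
             end = pmax(genes$tss, genes$tes))
}

#' Read/write gene models as a tab table
#'
#' Header + 8 tab-separated columns: gene_id, chrom, strand, tss, tes,
#' exon_starts, exon_ends (comma-separated lists), biotype.
#'
#' @param path file path.
#' @return [gene_models()].
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "character",
                                         "character", "character"))
  gene_models(
    gene_id = df$gene_id, chrom = df$chrom, strand = df$strand,
    tss = df$tss, tes = df$tes,
    exon_starts = lapply(strsplit(df$exon_starts, ","), as.integer),
    exon_ends = lapply(strsplit(df$exon_ends, ","), as.integer),
    biotype = df$biotype
  )
}

#' @rdname read_gene_table
#' @param genes a [gene_models()] object.
#' @export
write_gene_table <- function(genes, path) {
  stopifnot(is_gene_models(genes))
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss, tes = genes$tes,
    exon_starts = vapply(genes$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, "", collapse = ","),
    biotype = genes$biotype,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
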