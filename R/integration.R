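#' Classify a differential gene table
#'
#' Up = adjusted p below `alpha` and log2FC > 0; down = adjusted p below
#' `alpha` and log2FC < 0. Genes with log2FC exactly 0 belong to neither.
#'
#' @param table data frame with columns `gene_id`, `log2fc`, `padj`
#'   (`gene_id` unique, `padj` in \[0, 1\]).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
classify_deg <- function(table, alpha = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(table)))
  if (anyDuplicated(table$gene_id)) {
    stop("classify_deg: gene_id must be unique", call. = FALSE)
  }
  if (any(table$padj < 0 | table$padj > 1, na.rm = TRUE)) {
    stop("classify_deg: padj must lie in [0, 1]", call. = FALSE)
  }
  sig <- !is.na(table$padj) & table$padj < alpha
  list(up = table$gene_id[sig & table$log2fc > 0],
       down = table$gene_id[sig & table$log2fc < 0])
}

#' Fraction of one gene set covered by another
#'
#' @param set_a,set_b character vectors of gene ids; `set_a` non-empty.
#' @return List: `n_a`, `n_b`, `n_overlap`, `fraction` (= |A∩B| / |A|).
#' @export
overlap_fraction <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0) {
    stop("overlap_fraction: set A is empty", call. = FALSE)
  }
  n_ov <- length(intersect(set_a, set_b))
  list(n_a = length(set_a), n_b = length(set_b), n_overlap = n_ov,
       fraction = n_ov / length(set_a))
}

#' Permutation test for gene-set overlap
#'
#' The null model draws `|B|` genes uniformly without replacement from the
#' universe, `n_permutations` times, and counts how often the null overlap
#' with A reaches the observed overlap. The empirical p uses the +1
#' correction, `p = (1 + #\{null >= obs\}) / (1 + n_permutations)`, so it is
#' never exactly zero. Deterministic given `seed`; the caller's RNG state
#' is restored on exit. Set `permute = "A"` to randomize A's labels
#' instead (equivalent under the null).
#'
#' @param set_a,set_b gene sets, both subsets of `universe`.
#' @param universe character vector of all candidate genes.
#' @param n_permutations at least 100.
#' @param seed integer seed (mandatory).
#' @param permute which set's membership to randomize (`"B"` default).
#' @return List of class `overlap_result`: `observed_overlap`,
#'   `universe_size`, `set_sizes`, `fraction_of_A`, `permutation_p`,
#'   `n_permutations`, `seed`, `null_mean`.
#' @export
permutation_overlap_test <- function(set_a, set_b, universe,
                                     n_permutations = 1000, seed,
                                     permute = c("B", "A")) {
  permute <- match.arg(permute)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("permutation_overlap_test: A and B must be subsets of the universe",
         call. = FALSE)
  }
  if (n_permutations < 100) {
    stop("permutation_overlap_test: need n_permutations >= 100", call. = FALSE)
  }
  observed <- length(intersect(set_a, set_b))
  fixed <- if (permute == "B") set_a else set_b
  m <- if (permute == "B") length(set_b) else length(set_a)
  in_fixed <- universe %in% fixed
  U <- length(universe)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  cnt <- 0L
  total <- 0
  for (k in seq_len(n_permutations)) {
    ov <- sum(in_fixed[sample.int(U, m)])
    total <- total + ov
    if (ov >= observed) cnt <- cnt + 1L
  }
  structure(list(
    observed_overlap = observed,
    universe_size = U,
    set_sizes = c(A = length(set_a), B = length(set_b)),
    fraction_of_A = if (length(set_a)) observed / length(set_a) else 0,
    permutation_p = (1 + cnt) / (1 + n_permutations),
    n_permutations = n_permutations,
    seed = seed,
    null_mean = total / n_permutations
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d (|A|=%d, |B|=%d, universe %d); permutation p = %.4g (%d permutations, null mean %.2f)\n",
    x$observed_overlap, x$set_sizes[["A"]], x$set_sizes[["B"]],
    x$universe_size, x$permutation_p, x$n_permutations, x$null_mean))
  invisible(x)
}

#' Classify active TF targets from ChIP x ATAC x RNA
#'
#' ChIP peaks overlapping at least one open-chromatin region define the
#' "bound in open chromatin" peak set; their annotated genes (unique) are
#' the candidate targets. Targets also upregulated are "activated", those
#' downregulated "repressed"; together these are the factor's active
#' targets. Reported fractions: `pct_up_explained` = |activated| / |up|,
#' `pct_down_explained` = |repressed| / |down|, `pct_chip_active` =
#' |activated ∪ repressed| / |candidate targets|. A fraction with a zero
#' denominator is reported as 0.
#'
#' @param chip_peaks [interval_set()] of ChIP peaks (named).
#' @param open_regions [interval_set()] of accessible regions.
#' @param annotations peak-to-gene mapping covering all ChIP peaks: either
#'   a [annotate_peaks()] result or a data frame with columns `name` and
#'   `nearest_gene` (or `gene_id`).
#' @param up_genes,down_genes character vectors of differential genes.
#' @return List of class `target_sets`.
#' @export
active_target_classification <- function(chip_peaks, open_regions,
                                         annotations, up_genes, down_genes) {
  stopifnot(is_interval_set(chip_peaks), is_interval_set(open_regions))
  gene_col <- if ("nearest_gene" %in% names(annotations)) "nearest_gene"
              else "gene_id"
  map <- stats::setNames(as.character(annotations[[gene_col]]),
                         annotations$name)
  missing <- setdiff(chip_peaks$name, names(map))
  if (length(missing)) {
    stop(sprintf("active_target_classification: %d ChIP peaks lack an annotation (e.g. '%s')",
                 length(missing), missing[1]), call. = FALSE)
  }
  ov <- intersect_sets(chip_peaks, open_regions)
  open_peaks <- unique(ov$a_name)
  chip_open_genes <- sort(unique(stats::na.omit(map[open_peaks])))
  up_genes <- unique(up_genes)
  down_genes <- unique(down_genes)
  activated <- intersect(chip_open_genes, up_genes)
  repressed <- intersect(chip_open_genes, down_genes)
  active <- union(activated, repressed)
  if (length(chip_open_genes) == 0) {
    warning("no ChIP peaks fall in open chromatin; fractions reported as 0")
  }
  frac <- function(num, den) if (den == 0) 0 else num / den
  structure(list(
    chip_open_peaks = sort(open_peaks),
    n_chip_peaks = nrow(chip_peaks),
    n_chip_open_peaks = length(open_peaks),
    chip_open_genes = chip_open_genes,
    n_chip_open_genes = length(chip_open_genes),
    up_genes = up_genes, down_genes = down_genes,
    activated = sort(activated), repressed = sort(repressed),
    pct_up_explained = frac(length(activated), length(up_genes)),
    pct_down_explained = frac(length(repressed), length(down_genes)),
    pct_chip_active = frac(length(active), length(chip_open_genes))
  ), class = "target_sets")
}

#' @export
print.target_sets <- function(x, ...) {
  cat(sprintf("ChIP peaks in open chromatin: %d/%d, annotated to %d unique genes\n",
              x$n_chip_open_peaks, x$n_chip_peaks, x$n_chip_open_genes))
  cat(sprintf("activated %d/%d up genes (%.2f%%); repressed %d/%d down genes (%.2f%%)\n",
              length(x$activated), length(x$up_genes),
              100 * x$pct_up_explained,
              length(x$repressed), length(x$down_genes),
              100 * x$pct_down_explained))
  cat(sprintf("active targets: %d/%d candidate genes (%.2f%%)\n",
              length(union(x$activated, x$repressed)), x$n_chip_open_genes,
              100 * x$pct_chip_active))
  invisible(x)
}

#' Motif co-occurrence pairs within open regions
#'
#' For each region containing at least one hit of family A and one of
#' family B (hits must already satisfy whole-motif containment, as
#' produced by [scan_sequences()]), every A x B pair is emitted with the
#' absolute distance between motif midpoints (robust to differing motif
#' widths). The summary reports: the region denominator, regions with any
#' A hit, regions with both families, the total pair count, the fraction
#' of pairs closer than `distance_cutoff` (default 1 kb), pair counts per
#' region class (when `annotations` of the regions are supplied) and per
#' family-B member.
#'
#' @param open_regions [interval_set()] of regions (non-overlapping).
#' @param hits_a,hits_b `motif_hits` data frames (family B may pool
#'   several motifs, e.g. TEAD1-4).
#' @param annotations optional [annotate_peaks()] result for
#'   `open_regions` (matched by region name) used to attach region
#'   classes.
#' @param distance_cutoff bp cutoff for the "close pairs" fraction.
#' @return List of class `cooccurrence` with `pairs` (data frame) and
#'   `summary` (list).
#' @export
cooccurrence_pairs <- function(open_regions, hits_a, hits_b,
                               annotations = NULL, distance_cutoff = 1000) {
  stopifnot(is_interval_set(open_regions))
  region_key <- function(i) {
    ifelse(is.na(open_regions$name[i]),
           sprintf("%s:%d-%d", open_regions$chrom[i], open_regions$start[i],
                   open_regions$end[i]),
           open_regions$name[i])
  }
  assign_regions <- function(hits) {
    if (nrow(hits) == 0) return(integer(0))
    hs <- interval_set(hits$chrom, hits$start, hits$end,
                       name = as.character(seq_len(nrow(hits))))
    cc <- contained_in(hs, open_regions)
    idx <- rep(NA_integer_, nrow(hits))
    idx[as.integer(cc$inner_name)] <- cc$outer_idx
    idx
  }
  ra <- assign_regions(hits_a)
  rb <- assign_regions(hits_b)
  class_by_region <- rep(NA_character_, nrow(open_regions))
  if (!is.null(annotations)) {
    m <- match(open_regions$name, annotations$name)
    class_by_region <- annotations$region_class[m]
  }
  pair_rows <- list()
  with_both <- intersect(unique(stats::na.omit(ra)), unique(stats::na.omit(rb)))
  for (r in sort(with_both)) {
    ia <- which(!is.na(ra) & ra == r)
    ib <- which(!is.na(rb) & rb == r)
    grid <- expand.grid(a = ia, b = ib)
    mid_a <- (hits_a$start[grid$a] + hits_a$end[grid$a]) / 2
    mid_b <- (hits_b$start[grid$b] + hits_b$end[grid$b]) / 2
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      region_name = region_key(r),
      region_class = class_by_region[r],
      chrom = open_regions$chrom[r],
      a_motif = hits_a$motif_id[grid$a],
      a_start = hits_a$start[grid$a], a_end = hits_a$end[grid$a],
      a_strand = hits_a$strand[grid$a],
      b_motif = hits_b$motif_id[grid$b],
      b_start = hits_b$start[grid$b], b_end = hits_b$end[grid$b],
      b_strand = hits_b$strand[grid$b],
      distance_bp = abs(mid_a - mid_b),
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else data.frame(
    region_name = character(), region_class = character(),
    chrom = character(), a_motif = character(), a_start = integer(),
    a_end = integer(), a_strand = character(), b_motif = character(),
    b_start = integer(), b_end = integer(), b_strand = character(),
    distance_bp = numeric(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$chrom, pairs$a_start, pairs$b_start), ]
  rownames(pairs) <- NULL
  cls_tab <- table(factor(pairs$region_class,
                          levels = c("promoter", "exon", "intron", "TTS",
                                     "intergenic")))
  summary <- list(
    n_regions = nrow(open_regions),
    n_regions_with_a = length(unique(stats::na.omit(ra))),
    n_regions_with_b = length(unique(stats::na.omit(rb))),
    n_regions_with_both = length(with_both),
    n_pairs = nrow(pairs),
    distance_cutoff_bp = distance_cutoff,
    frac_pairs_below_cutoff =
      if (nrow(pairs)) mean(pairs$distance_bp < distance_cutoff) else 0,
    pairs_per_class = stats::setNames(as.integer(cls_tab), names(cls_tab)),
    pairs_per_b_motif = if (nrow(pairs))
      as.list(table(pairs$b_motif)) else list()
  )
  structure(list(pairs = pairs, summary = summary), class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  s <- x$summary
  cat(sprintf("regions with family-A motif: %d/%d; with both families: %d\n",
              s$n_regions_with_a, s$n_regions, s$n_regions_with_both))
  cat(sprintf("%d A-B pairs; %.1f%% closer than %d bp\n", s$n_pairs,
              100 * s$frac_pairs_below_cutoff, s$distance_cutoff_bp))
  invisible(x)
}
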