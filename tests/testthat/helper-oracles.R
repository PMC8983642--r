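# Brute-force oracles and random fixture builders. These deliberately avoid
# the package's GenomicRanges-backed code paths: interval oracles are direct
# all-vs-all arithmetic, the merge oracle is a per-base occupancy mask, the
# scan oracle enumerates windows one by one.

rand_iset <- function(n, chroms = paste0("c", 1:3), max_pos = 10000,
                      max_w = 400, label = NULL) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  interval_set(chrom, start, start + w,
               name = sprintf("iv%04d", seq_len(n)), label = label)
}

bf_intersect <- function(a, b, min_overlap = 1L) {
  idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  same <- a$chrom[idx$i] == b$chrom[idx$j]
  ov <- pmin(a$end[idx$i], b$end[idx$j]) - pmax(a$start[idx$i], b$start[idx$j])
  keep <- which(same & ov >= min_overlap)
  out <- data.frame(
    chrom = a$chrom[idx$i[keep]],
    a_idx = idx$i[keep], a_start = a$start[idx$i[keep]],
    a_end = a$end[idx$i[keep]], a_name = a$name[idx$i[keep]],
    b_idx = idx$j[keep], b_start = b$start[idx$j[keep]],
    b_end = b$end[idx$j[keep]], b_name = b$name[idx$j[keep]],
    overlap_bp = ov[keep], stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$a_start, out$b_start, out$a_end, out$b_end), ]
  rownames(out) <- NULL
  out
}

bf_contained <- function(inner, outer) {
  idx <- expand.grid(i = seq_len(nrow(inner)), j = seq_len(nrow(outer)))
  keep <- which(inner$chrom[idx$i] == outer$chrom[idx$j] &
                  inner$start[idx$i] >= outer$start[idx$j] &
                  inner$end[idx$i] <= outer$end[idx$j])
  out <- data.frame(
    chrom = inner$chrom[idx$i[keep]],
    inner_idx = idx$i[keep], inner_start = inner$start[idx$i[keep]],
    inner_end = inner$end[idx$i[keep]], inner_name = inner$name[idx$i[keep]],
    outer_idx = idx$j[keep], outer_start = outer$start[idx$j[keep]],
    outer_end = outer$end[idx$j[keep]], outer_name = outer$name[idx$j[keep]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$inner_start, out$outer_start,
                   out$inner_end, out$outer_end), ]
  rownames(out) <- NULL
  out
}

# per-base occupancy merge oracle (coordinates must stay small)
bf_merge <- function(a) {
  rows <- list()
  for (cm in sort(unique(a$chrom))) {
    sub <- a[a$chrom == cm, , drop = FALSE]
    mask <- logical(max(sub$end))
    for (i in seq_len(nrow(sub))) {
      mask[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    r <- rle(mask)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in which(r$values)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cm, start = starts[k] - 1L, end = stops[k],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# exhaustive per-window scan oracle
bf_scan <- function(genome, regions, pwm) {
  w <- pwm$width
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_str <- function(s) {
    b <- strsplit(s, "")[[1]]
    if (!all(b %in% bases)) return(NA_real_)
    sum(pwm$bits[cbind(match(b, bases), seq_len(w))])
  }
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    seq <- as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                           regions$start[i] + 1L,
                                           regions$end[i]))
    L <- nchar(seq)
    if (L < w) next
    for (o in 0:(L - w)) {
      win <- substr(seq, o + 1L, o + w)
      fwd <- score_str(win)
      rcwin <- paste(rev(comp[strsplit(win, "")[[1]]]), collapse = "")
      rev_ <- score_str(rcwin)
      for (strand in c("+", "-")) {
        sc <- if (strand == "+") fwd else rev_
        if (!is.na(sc) && sc >= pwm$threshold_bits) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = regions$chrom[i], start = regions$start[i] + o,
            end = regions$start[i] + o + w, strand = strand,
            score_bits = sc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), score_bits = numeric())
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random genome as DNAStringSet
rand_genome <- function(lengths) {
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  Biostrings::DNAStringSet(seqs)
}

# scaled-down but feasible generator configuration for unit tests
quick_sim_config <- function(seed, ...) {
  args <- list(seed = seed,
               n_chromosomes = 2, chrom_length_bp = 600000,
               n_genes = 60, n_open_regions = 40,
               n_chip_peaks = 36, chip_in_open_fraction = 0.834,
               n_multi_peak_genes = 4,
               n_up = 20, n_down = 16,
               frac_up_explained = 0.5, frac_down_explained = 0.5,
               n_diff_regions = 25, frac_diff_explained = 0.6,
               n_planted_pairs = 8, n_regions_motif_a_only = 5,
               n_tf_rows = 30)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# strip provenance/rowname attributes for data-frame comparisons
iv_df <- function(x, cols = c("chrom", "start", "end", "name", "score",
                              "strand")) {
  d <- as.data.frame(x)[, cols, drop = FALSE]
  attr(d, "label") <- NULL
  rownames(d) <- NULL
  d
}

# hand-built two-gene annotation fixture
#   g1: + strand, c1, tss 5000, tes 8000, exons [5000,5500) and [7000,8000)
#   g2: - strand, c1, tss 20000, tes 17000, exons [17000,18000), [19500,20000)
two_gene_fixture <- function() {
  gene_models(
    gene_id = c("g1", "g2"), chrom = "c1", strand = c("+", "-"),
    tss = c(5000, 20000), tes = c(8000, 17000),
    exon_starts = list(c(5000, 7000), c(17000, 19500)),
    exon_ends = list(c(5500, 8000), c(18000, 20000)),
    biotype = c("protein_coding", "other")
  )
}

point_peaks <- function(mids, chrom = "c1", half = 50) {
  interval_set(chrom, mids - half, mids + half,
               name = sprintf("p%02d", seq_along(mids)))
}
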