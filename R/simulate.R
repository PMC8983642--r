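## Synthetic study generator.
##
## Lays the genome out as fixed-size slots, one placed object per slot
## (a gene, a decoy open region, or a ChIP peak outside open chromatin).
## Geometry constants below guarantee, by construction, that (i) every
## planted peak/region annotates to its intended gene under the
## nearest-TSS rule, (ii) promoter-mode placements classify as promoter
## and intergenic-mode ones as intergenic under the midpoint rule, and
## (iii) everything fits inside its slot. They are internal: changing
## them requires re-deriving the distance arguments in the vignette.
.SLOT_BP <- 12000L
.GENE_OFFSET <- 4500L          # gene body starts here within its slot
.GENE_LEN_RANGE <- c(1500L, 3000L)
.INTERGENIC_OFFSET <- 2800L    # upstream distance of intergenic placements
.DECOY_CENTER <- 6000L         # center of objects in gene-less slots
.PEAK_HALF <- 100L             # ChIP peaks are 200 bp
.MIN_SEG <- 80L                # minimum exon/intron segment

#' Configuration of the synthetic study
#'
#' Defaults are the packaged study conditions: a 1200-gene universe on
#' four chromosomes, 237 ChIP peaks of which 197 fall in open chromatin,
#' 233 open regions, 116 differentially accessible regions, 70 up / 56
#' down differential genes with planted explained fractions 21.42% /
#' 19.63%, a planted differential-region/DEG overlap of 22.48%, 79%
#' protein-coding genes, and 40 planted motif pairs (distances 50-900 bp)
#' plus 33 regions carrying only the family-A motif.
#'
#' @param seed integer seed (mandatory); all randomness derives from it.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_genes number of gene models; genes not differential are null.
#' @param protein_coding_fraction fraction of genes with biotype
#'   protein_coding.
#' @param n_open_regions open (accessible) regions; those not hosting a
#'   ChIP peak are intergenic decoys.
#' @param region_length_range open-region length range in bp.
#' @param n_chip_peaks,chip_in_open_fraction ChIP peaks and the fraction
#'   placed wholly inside open regions (each such peak targets one gene).
#' @param n_multi_peak_genes target genes given a second ChIP peak in the
#'   same open region (exercises the unique-gene reduction).
#' @param n_up,n_down differential gene counts; the remaining genes are
#'   non-differential.
#' @param alpha adjusted-p cutoff used when assigning padj values.
#' @param frac_up_explained,frac_down_explained planted fraction of
#'   up/down genes that are ChIP-in-open targets.
#' @param n_diff_regions differentially accessible regions (a subset of
#'   the ChIP-in-open regions).
#' @param frac_diff_explained planted fraction of differential regions
#'   whose gene is also a differential gene.
#' @param n_planted_pairs regions given one family-A plus one family-B
#'   motif; one pair per region.
#' @param n_regions_motif_a_only regions given only a family-A motif.
#' @param pair_distance_range_bp motif midpoint distances to plant.
#' @param noise_rate per-gene probability that a differential gene fails
#'   detection (padj pushed above alpha); 0 disables noise.
#' @param n_tf_rows rows of the synthetic differential-binding TF table.
#' @param motif_a,motif_b consensus strings planted for the two families.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 4,
                              chrom_length_bp = 3900000,
                              n_genes = 1200,
                              protein_coding_fraction = 0.79,
                              n_open_regions = 233,
                              region_length_range = c(1000, 1600),
                              n_chip_peaks = 237,
                              chip_in_open_fraction = 0.831,
                              n_multi_peak_genes = 20,
                              n_up = 70,
                              n_down = 56,
                              alpha = 0.05,
                              frac_up_explained = 0.2142,
                              frac_down_explained = 0.1963,
                              n_diff_regions = 116,
                              frac_diff_explained = 0.2248,
                              n_planted_pairs = 40,
                              n_regions_motif_a_only = 33,
                              pair_distance_range_bp = c(50, 900),
                              noise_rate = 0,
                              n_tf_rows = 100,
                              motif_a = "TTGCGTGACGTC",
                              motif_b = "ACATTCCTGGCA") {
  if (missing(seed) || is.null(seed)) {
    stop("simulation_config: seed is mandatory", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              n_genes = as.integer(n_genes),
              protein_coding_fraction = protein_coding_fraction,
              n_open_regions = as.integer(n_open_regions),
              region_length_range = as.integer(region_length_range),
              n_chip_peaks = as.integer(n_chip_peaks),
              chip_in_open_fraction = chip_in_open_fraction,
              n_multi_peak_genes = as.integer(n_multi_peak_genes),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              alpha = alpha,
              frac_up_explained = frac_up_explained,
              frac_down_explained = frac_down_explained,
              n_diff_regions = as.integer(n_diff_regions),
              frac_diff_explained = frac_diff_explained,
              n_planted_pairs = as.integer(n_planted_pairs),
              n_regions_motif_a_only = as.integer(n_regions_motif_a_only),
              pair_distance_range_bp = as.integer(pair_distance_range_bp),
              noise_rate = noise_rate,
              n_tf_rows = as.integer(n_tf_rows),
              motif_a = toupper(motif_a), motif_b = toupper(motif_b))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

## derived counts used throughout the generator
.sim_counts <- function(cfg) {
  n_in_open <- round(cfg$n_chip_peaks * cfg$chip_in_open_fraction)
  list(
    n_in_open = n_in_open,
    n_chip_out = cfg$n_chip_peaks - n_in_open,
    n_extra_open = cfg$n_open_regions - n_in_open,
    n_expl_up = round(cfg$frac_up_explained * cfg$n_up),
    n_expl_down = round(cfg$frac_down_explained * cfg$n_down),
    n_diff_expl = round(cfg$frac_diff_explained * cfg$n_diff_regions)
  )
}

validate_simulation_config <- function(cfg) {
  fr <- c(cfg$protein_coding_fraction, cfg$chip_in_open_fraction,
          cfg$frac_up_explained, cfg$frac_down_explained,
          cfg$frac_diff_explained, cfg$noise_rate, cfg$alpha)
  if (any(fr < 0 | fr > 1)) {
    stop("simulation_config: all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$chrom_length_bp <= 0) {
    stop("simulation_config: chromosome length must be positive",
         call. = FALSE)
  }
  k <- .sim_counts(cfg)
  if (k$n_chip_out < 0 || k$n_extra_open < 0) {
    stop("simulation_config: more in-open ChIP peaks than peaks or open regions",
         call. = FALSE)
  }
  if (k$n_expl_up > cfg$n_up || k$n_expl_down > cfg$n_down) {
    stop("simulation_config: more explained genes than differential genes",
         call. = FALSE)
  }
  if (k$n_expl_up + k$n_expl_down > k$n_in_open) {
    stop("simulation_config: explained genes exceed ChIP-in-open targets",
         call. = FALSE)
  }
  if (k$n_in_open > cfg$n_genes) {
    stop("simulation_config: more targets than genes", call. = FALSE)
  }
  if ((cfg$n_up - k$n_expl_up) + (cfg$n_down - k$n_expl_down) >
        cfg$n_genes - k$n_in_open) {
    stop("simulation_config: not enough non-target genes for unexplained DEGs",
         call. = FALSE)
  }
  if (cfg$n_up + cfg$n_down > cfg$n_genes) {
    stop("simulation_config: differential genes exceed gene count",
         call. = FALSE)
  }
  if (cfg$n_diff_regions > k$n_in_open) {
    stop("simulation_config: differential regions exceed ChIP-in-open regions",
         call. = FALSE)
  }
  if (k$n_diff_expl > k$n_expl_up + k$n_expl_down) {
    stop("simulation_config: explained differential regions exceed explained genes",
         call. = FALSE)
  }
  if (cfg$n_diff_regions - k$n_diff_expl >
        k$n_in_open - (k$n_expl_up + k$n_expl_down)) {
    stop("simulation_config: not enough unexplained targets for differential regions",
         call. = FALSE)
  }
  if (cfg$n_planted_pairs + cfg$n_regions_motif_a_only > cfg$n_diff_regions) {
    stop("simulation_config: motif regions exceed differential regions",
         call. = FALSE)
  }
  w <- max(nchar(cfg$motif_a), nchar(cfg$motif_b))
  if (cfg$region_length_range[1] < max(cfg$pair_distance_range_bp) + w + 2) {
    stop("simulation_config: regions too short for the requested pair distances",
         call. = FALSE)
  }
  if (cfg$region_length_range[1] < 1000) {
    stop("simulation_config: minimum region length is 1000 bp", call. = FALSE)
  }
  if (cfg$n_multi_peak_genes > k$n_in_open) {
    stop("simulation_config: multi-peak genes exceed targets", call. = FALSE)
  }
  if (min(cfg$pair_distance_range_bp) < w + 1) {
    stop("simulation_config: pair distances must exceed the motif width",
         call. = FALSE)
  }
  invisible(cfg)
}

## Deterministic slot layout: gene slots and "special" slots (decoy open
## regions, out-of-open ChIP peaks) interleaved evenly along the genome.
.slot_layout <- function(cfg) {
  k <- .sim_counts(cfg)
  per_chrom <- cfg$chrom_length_bp %/% .SLOT_BP
  n_specials <- k$n_extra_open + k$n_chip_out
  n_used <- cfg$n_genes + n_specials
  if (n_used > per_chrom * cfg$n_chromosomes) {
    stop(sprintf(
      "cannot place %d genes + %d auxiliary objects without overlap: only %d slots of %d bp available",
      cfg$n_genes, n_specials, per_chrom * cfg$n_chromosomes, .SLOT_BP),
      call. = FALSE)
  }
  purpose <- rep("gene", n_used)
  if (n_specials > 0) {
    sp_idx <- unique(round(seq(2, n_used - 1, length.out = n_specials)))
    while (length(sp_idx) < n_specials) {  # collisions after rounding
      extra <- setdiff(seq(2, n_used - 1), sp_idx)
      sp_idx <- sort(c(sp_idx, extra[seq_len(n_specials - length(sp_idx))]))
    }
    # interleave the two kinds evenly along the genome
    kinds <- c(rep("extra_open", k$n_extra_open),
               rep("chip_out", k$n_chip_out))
    ord <- order(c(seq_len(k$n_extra_open) / (k$n_extra_open + 1),
                   seq_len(k$n_chip_out) / (k$n_chip_out + 1)))
    purpose[sp_idx] <- kinds[ord]
  }
  i <- seq_len(n_used)
  data.frame(
    slot = i,
    chrom = sprintf("chr%d", (i - 1L) %/% per_chrom + 1L),
    start = as.integer(((i - 1L) %% per_chrom) * .SLOT_BP),
    purpose = purpose,
    stringsAsFactors = FALSE
  )
}

#' Generate a random genome
#'
#' i.i.d. uniform A/C/G/T background of the configured shape;
#' deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return A named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$chrom_length_bp <= 0) {
    stop("make_genome: zero-length chromosome requested", call. = FALSE)
  }
  set.seed(config$seed)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(DNA_BASES, config$chrom_length_bp, replace = TRUE),
          collapse = "")
  }, "")
  names(seqs) <- sprintf("chr%d", seq_len(config$n_chromosomes))
  Biostrings::DNAStringSet(seqs)
}

#' Generate non-overlapping gene models
#'
#' One gene per gene slot of the layout: random strand, length, 1-5 exons
#' (first and last segments are exons; all segments at least 80 bp) and
#' biotype drawn at the configured protein-coding fraction. Deterministic
#' given the config seed.
#'
#' @param config a [simulation_config()].
#' @param genome the genome from [make_genome()] (bounds check only).
#' @return A [gene_models()] data frame in genomic order.
#' @export
make_gene_models <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- .slot_layout(config)
  gs <- layout[layout$purpose == "gene", , drop = FALSE]
  set.seed(config$seed + 1L)
  n <- nrow(gs)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  glen <- sample(seq(.GENE_LEN_RANGE[1], .GENE_LEN_RANGE[2]), n,
                 replace = TRUE)
  biotype <- ifelse(stats::runif(n) < config$protein_coding_fraction,
                    "protein_coding", "other")
  g0 <- gs$start + .GENE_OFFSET
  g1 <- g0 + glen
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample.int(5L, 1L)
    nseg <- 2L * k - 1L
    rem <- glen[i] - .MIN_SEG * nseg
    props <- diff(c(0, sort(stats::runif(nseg - 1L)), 1))
    extra <- floor(rem * props)
    extra[nseg] <- extra[nseg] + (rem - sum(extra))
    widths <- .MIN_SEG + extra
    bounds <- g0[i] + cumsum(c(0L, widths))
    exon_starts[[i]] <- bounds[seq(1, nseg, by = 2)]
    exon_ends[[i]] <- bounds[seq(2, nseg + 1, by = 2)]
  }
  gene_models(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = gs$chrom, strand = strand,
    tss = ifelse(strand == "+", g0, g1),
    tes = ifelse(strand == "+", g1, g0),
    exon_starts = exon_starts, exon_ends = exon_ends,
    biotype = biotype
  )
}

.nearest_gene_id <- function(genes, chrom, pos) {
  gi <- which(genes$chrom == chrom)
  if (length(gi) == 0) return(NA_character_)
  k <- order(abs(pos - genes$tss[gi]), genes$gene_id[gi])[1]
  genes$gene_id[gi[k]]
}

## flip one base (deterministically) to destroy a spurious motif window
.flip_base <- function(b) c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]

#' Simulate the full regulatory landscape
#'
#' Places open regions and ChIP peaks, plants consensus motifs at recorded
#' positions and pair distances, constructs the differential gene and
#' region tables with the configured explained fractions, and returns
#' everything together with an exact `ground_truth` record. A scan-back
#' self-check verifies that re-scanning the emitted genome recovers
#' exactly the planted motif instances (spurious background matches are
#' destroyed by flipping one base outside planted footprints).
#'
#' @param config a [simulation_config()].
#' @param genome from [make_genome()].
#' @param genes from [make_gene_models()].
#' @return List of class `simulated_study` with elements `config`,
#'   `genome`, `genes`, `open_regions`, `chip_peaks`, `deg`,
#'   `diff_regions`, `tf_scores`, `motifs`, `pwms`, `annotations_map`,
#'   `ground_truth`.
#' @export
simulate_landscape <- function(config, genome, genes) {
  stopifnot(inherits(config, "simulation_config"))
  cnt <- .sim_counts(config)
  layout <- .slot_layout(config)
  gene_slots <- layout[layout$purpose == "gene", , drop = FALSE]
  stopifnot(nrow(gene_slots) == config$n_genes, nrow(genes) == config$n_genes)
  set.seed(config$seed + 2L)

  ## --- roles -------------------------------------------------------------
  target_idx <- sample.int(config$n_genes, cnt$n_in_open)
  expl_up_idx <- target_idx[seq_len(cnt$n_expl_up)]
  expl_down_idx <- target_idx[cnt$n_expl_up + seq_len(cnt$n_expl_down)]
  non_targets <- sample(setdiff(seq_len(config$n_genes), target_idx))
  unexpl_up_idx <- non_targets[seq_len(config$n_up - cnt$n_expl_up)]
  unexpl_down_idx <- non_targets[config$n_up - cnt$n_expl_up +
                                   seq_len(config$n_down - cnt$n_expl_down)]
  up_idx <- c(expl_up_idx, unexpl_up_idx)
  down_idx <- c(expl_down_idx, unexpl_down_idx)

  ## --- target regions and peaks ------------------------------------------
  gsp <- gene_span(genes)
  mode <- sample(c("promoter", "intergenic"), cnt$n_in_open, replace = TRUE)
  L <- sample(seq(config$region_length_range[1],
                  config$region_length_range[2]), cnt$n_in_open,
              replace = TRUE)
  center <- integer(cnt$n_in_open)
  for (j in seq_len(cnt$n_in_open)) {
    i <- target_idx[j]
    center[j] <- if (mode[j] == "promoter") {
      genes$tss[i]
    } else if (genes$strand[i] == "+") {
      gsp$start[i] - .INTERGENIC_OFFSET
    } else {
      gsp$end[i] + .INTERGENIC_OFFSET
    }
  }
  t_regions <- data.frame(
    chrom = genes$chrom[target_idx],
    start = center - L %/% 2L,
    end = center - L %/% 2L + L,
    name = sprintf("or_%s", genes$gene_id[target_idx]),
    gene_id = genes$gene_id[target_idx],
    mode = mode, center = center,
    stringsAsFactors = FALSE
  )
  peaks <- data.frame(
    chrom = t_regions$chrom,
    start = center - .PEAK_HALF, end = center + .PEAK_HALF,
    name = sprintf("pk_%s", t_regions$gene_id),
    gene_id = t_regions$gene_id,
    class = ifelse(mode == "promoter", "promoter", "intergenic"),
    stringsAsFactors = FALSE
  )
  if (config$n_multi_peak_genes > 0) {
    mi <- seq_len(config$n_multi_peak_genes)
    i2 <- target_idx[mi]
    mid2 <- ifelse(mode[mi] == "promoter",
                   ifelse(genes$strand[i2] == "+",
                          genes$tss[i2] - 400L, genes$tss[i2] + 400L),
                   center[mi] + 300L)
    peaks <- rbind(peaks, data.frame(
      chrom = t_regions$chrom[mi],
      start = mid2 - .PEAK_HALF, end = mid2 + .PEAK_HALF,
      name = sprintf("pk_%s_b", t_regions$gene_id[mi]),
      gene_id = t_regions$gene_id[mi],
      class = peaks$class[mi],
      stringsAsFactors = FALSE
    ))
  }

  ## --- decoy open regions and out-of-open peaks ---------------------------
  eo <- layout[layout$purpose == "extra_open", , drop = FALSE]
  e_L <- if (nrow(eo)) sample(seq(config$region_length_range[1],
                                  config$region_length_range[2]),
                              nrow(eo), replace = TRUE) else integer(0)
  e_regions <- data.frame(
    chrom = eo$chrom,
    start = eo$start + .DECOY_CENTER - e_L %/% 2L,
    end = eo$start + .DECOY_CENTER - e_L %/% 2L + e_L,
    name = sprintf("or_extra_%03d", seq_len(nrow(eo))),
    gene_id = NA_character_, mode = "decoy",
    center = eo$start + .DECOY_CENTER,
    stringsAsFactors = FALSE
  )
  co <- layout[layout$purpose == "chip_out", , drop = FALSE]
  out_peaks <- data.frame(
    chrom = co$chrom,
    start = co$start + .DECOY_CENTER - .PEAK_HALF,
    end = co$start + .DECOY_CENTER + .PEAK_HALF,
    name = sprintf("pk_out_%03d", seq_len(nrow(co))),
    gene_id = vapply(seq_len(nrow(co)), function(i) {
      .nearest_gene_id(genes, co$chrom[i], co$start[i] + .DECOY_CENTER)
    }, ""),
    class = "intergenic",
    stringsAsFactors = FALSE
  )

  all_regions <- rbind(t_regions, e_regions)
  open_regions <- interval_set(all_regions$chrom, all_regions$start,
                               all_regions$end, name = all_regions$name,
                               label = "open_regions")
  all_peaks <- rbind(peaks, out_peaks)
  chip_peaks <- interval_set(all_peaks$chrom, all_peaks$start, all_peaks$end,
                             name = all_peaks$name, label = "chip_peaks")

  ## --- differential regions ----------------------------------------------
  expl_gene_ids <- genes$gene_id[c(expl_up_idx, expl_down_idx)]
  other_target_ids <- setdiff(genes$gene_id[target_idx], expl_gene_ids)
  diff_expl_genes <- sample(expl_gene_ids, cnt$n_diff_expl)
  diff_other_genes <- sample(other_target_ids,
                             config$n_diff_regions - cnt$n_diff_expl)
  diff_gene_set <- c(diff_expl_genes, diff_other_genes)
  is_diff <- all_regions$gene_id %in% diff_gene_set
  n_reg <- nrow(all_regions)
  reg_lfc <- ifelse(is_diff,
                    sample(c(-1, 1), n_reg, replace = TRUE) *
                      stats::runif(n_reg, 0.5, 3),
                    stats::runif(n_reg, -0.3, 0.3))
  reg_padj <- ifelse(is_diff, stats::runif(n_reg, 0, config$alpha * 0.8),
                     stats::runif(n_reg, config$alpha + 0.1, 1))
  ann_gene <- all_regions$gene_id
  for (i in which(is.na(ann_gene))) {
    ann_gene[i] <- .nearest_gene_id(genes, all_regions$chrom[i],
                                    all_regions$center[i])
  }
  diff_regions <- data.frame(
    region_name = all_regions$name,
    chrom = all_regions$chrom, start = all_regions$start,
    end = all_regions$end,
    log2fc = reg_lfc, padj = reg_padj, annotated_gene = ann_gene,
    stringsAsFactors = FALSE
  )
  diff_regions <- diff_regions[order(diff_regions$chrom, diff_regions$start), ]
  rownames(diff_regions) <- NULL

  ## --- motif planting -----------------------------------------------------
  wa <- nchar(config$motif_a)
  wb <- nchar(config$motif_b)
  pair_genes <- sample(diff_gene_set, config$n_planted_pairs)
  a_only_genes <- sample(setdiff(diff_gene_set, pair_genes),
                         config$n_regions_motif_a_only)
  seqs <- as.character(genome)
  planted <- list()
  pair_truth <- list()
  plant_one <- function(chrom, start, motif, consensus) {
    strand <- sample(c("+", "-"), 1L)
    s <- if (strand == "+") consensus else revcomp(consensus)
    substr(seqs[[chrom]], start + 1L, start + nchar(s)) <<- s
    data.frame(motif_id = motif, chrom = chrom, start = start,
               end = start + nchar(s), strand = strand,
               stringsAsFactors = FALSE)
  }
  reg_row <- function(gene) which(t_regions$gene_id == gene)
  for (g in pair_genes) {
    r <- reg_row(g)
    d <- sample(seq(config$pair_distance_range_bp[1],
                    config$pair_distance_range_bp[2]), 1L)
    Lr <- t_regions$end[r] - t_regions$start[r]
    span <- d + max(wa, wb)
    off <- sample.int(Lr - span + 1L, 1L) - 1L
    a_first <- stats::runif(1) < 0.5
    s1 <- t_regions$start[r] + off
    s2 <- s1 + d   # equal-width motifs: midpoint distance == start distance
    a_start <- if (a_first) s1 else s2
    b_start <- if (a_first) s2 else s1
    ha <- plant_one(t_regions$chrom[r], a_start, "AHR_SYN", config$motif_a)
    hb <- plant_one(t_regions$chrom[r], b_start, "TEAD_SYN", config$motif_b)
    planted[[length(planted) + 1L]] <- ha
    planted[[length(planted) + 1L]] <- hb
    pair_truth[[length(pair_truth) + 1L]] <- data.frame(
      region_name = t_regions$name[r],
      region_class = ifelse(t_regions$mode[r] == "promoter", "promoter",
                            "intergenic"),
      a_start = a_start, b_start = b_start,
      distance_bp = abs((a_start + wa / 2) - (b_start + wb / 2)),
      stringsAsFactors = FALSE
    )
  }
  for (g in a_only_genes) {
    r <- reg_row(g)
    Lr <- t_regions$end[r] - t_regions$start[r]
    off <- sample.int(Lr - wa + 1L, 1L) - 1L
    planted[[length(planted) + 1L]] <-
      plant_one(t_regions$chrom[r], t_regions$start[r] + off, "AHR_SYN",
                config$motif_a)
  }
  planted_hits <- do.call(rbind, planted)
  pair_truth <- do.call(rbind, pair_truth)

  ## --- sanitize: destroy spurious background matches ----------------------
  motifs <- list(AHR_SYN = consensus_pfm("AHR_SYN", config$motif_a),
                 TEAD_SYN = consensus_pfm("TEAD_SYN", config$motif_b))
  pwms <- lapply(motifs, pfm_to_pwm)
  hit_key <- function(h) paste(h$motif_id, h$chrom, h$start, h$strand)
  planted_keys <- hit_key(planted_hits)
  footprint_cover <- function(chrom, pos) {
    any(planted_hits$chrom == chrom & planted_hits$start <= pos &
          planted_hits$end > pos)
  }
  for (round in 1:6) {
    g2 <- Biostrings::DNAStringSet(seqs)
    hits <- do.call(rbind, lapply(pwms, function(p)
      scan_sequences(g2, open_regions, p)))
    spur <- hits[!hit_key(hits) %in% planted_keys, , drop = FALSE]
    if (nrow(spur) == 0) break
    if (round == 6) {
      stop("simulate_landscape: could not sanitize spurious motif matches",
           call. = FALSE)
    }
    for (i in seq_len(nrow(spur))) {
      pos <- setdiff(seq(spur$start[i], spur$end[i] - 1L),
                     Filter(function(p) footprint_cover(spur$chrom[i], p),
                            seq(spur$start[i], spur$end[i] - 1L)))
      p <- pos[1]
      b <- substr(seqs[[spur$chrom[i]]], p + 1L, p + 1L)
      substr(seqs[[spur$chrom[i]]], p + 1L, p + 1L) <- .flip_base(b)
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  found <- do.call(rbind, lapply(pwms, function(p)
    scan_sequences(genome, open_regions, p)))
  if (!setequal(hit_key(found), planted_keys) ||
      nrow(found) != nrow(planted_hits)) {
    stop("simulate_landscape: scan-back self-check failed", call. = FALSE)
  }

  ## --- differential gene table --------------------------------------------
  n <- config$n_genes
  categ <- rep("null", n)
  categ[up_idx] <- "up"
  categ[down_idx] <- "down"
  lfc <- stats::runif(n, -0.4, 0.4)
  padj <- stats::runif(n, config$alpha + 0.1, 1)
  lfc[up_idx] <- stats::runif(length(up_idx), 0.5, 4)
  lfc[down_idx] <- -stats::runif(length(down_idx), 0.5, 4)
  padj[c(up_idx, down_idx)] <- stats::runif(length(up_idx) +
                                              length(down_idx),
                                            0, config$alpha * 0.9)
  if (config$noise_rate > 0) {
    dd <- c(up_idx, down_idx)
    drop <- dd[stats::runif(length(dd)) < config$noise_rate]
    padj[drop] <- stats::runif(length(drop), config$alpha + 0.1, 1)
  }
  deg <- data.frame(gene_id = genes$gene_id, log2fc = lfc, padj = padj,
                    stringsAsFactors = FALSE)

  ## --- TF differential-binding score table --------------------------------
  n_tf <- config$n_tf_rows
  tf_ids <- c("AHR_SYN", "TEAD_SYN", sprintf("TF%03d", seq_len(n_tf - 2L)))
  tf_scores <- data.frame(
    motif_id = tf_ids,
    differential_binding_score = c(-6, 6, stats::rnorm(n_tf - 2L)),
    neg_log10_p = c(7, 8, stats::runif(n_tf - 2L, 0, 1.3)),
    stringsAsFactors = FALSE
  )

  ## --- ground truth --------------------------------------------------------
  realized_up <- deg$gene_id[deg$padj < config$alpha & deg$log2fc > 0]
  realized_down <- deg$gene_id[deg$padj < config$alpha & deg$log2fc < 0]
  target_genes <- genes$gene_id[target_idx]
  activated <- intersect(genes$gene_id[expl_up_idx], realized_up)
  repressed <- intersect(genes$gene_id[expl_down_idx], realized_down)
  frac0 <- function(a, b) if (b == 0) 0 else a / b
  ground_truth <- list(
    target_genes = sort(target_genes),
    planted_up = sort(genes$gene_id[up_idx]),
    planted_down = sort(genes$gene_id[down_idx]),
    realized_up = sort(realized_up),
    realized_down = sort(realized_down),
    activated = sort(activated),
    repressed = sort(repressed),
    pct_up_explained = frac0(length(activated), length(realized_up)),
    pct_down_explained = frac0(length(repressed), length(realized_down)),
    pct_chip_active = frac0(length(union(activated, repressed)),
                            length(target_genes)),
    n_chip_open_peaks = nrow(peaks),
    n_chip_open_genes = length(target_genes),
    diff_genes = sort(diff_gene_set),
    diff_overlap_fraction =
      frac0(length(intersect(diff_gene_set,
                             union(realized_up, realized_down))),
            length(diff_gene_set)),
    region_class = stats::setNames(
      c(ifelse(t_regions$mode == "promoter", "promoter", "intergenic"),
        rep("intergenic", nrow(e_regions))),
      c(t_regions$name, e_regions$name)),
    peak_class = stats::setNames(all_peaks$class, all_peaks$name),
    peak_gene = stats::setNames(all_peaks$gene_id, all_peaks$name),
    planted_hits = planted_hits,
    pairs = pair_truth,
    n_pairs = config$n_planted_pairs,
    n_regions_with_a = config$n_planted_pairs + config$n_regions_motif_a_only,
    n_regions_with_both = config$n_planted_pairs,
    frac_pairs_below_1kb =
      if (is.null(pair_truth)) 0 else mean(pair_truth$distance_bp < 1000),
    tf_planted_extremes = c("AHR_SYN", "TEAD_SYN")
  )

  structure(list(
    config = config,
    genome = genome,
    genes = genes,
    open_regions = open_regions,
    chip_peaks = chip_peaks,
    deg = deg,
    diff_regions = diff_regions,
    tf_scores = tf_scores,
    motifs = motifs,
    pwms = pwms,
    annotations_map = data.frame(name = all_peaks$name,
                                 gene_id = all_peaks$gene_id,
                                 stringsAsFactors = FALSE),
    ground_truth = ground_truth
  ), class = "simulated_study")
}

#' Run the whole generator
#'
#' @param config a [simulation_config()].
#' @return A `simulated_study` (see [simulate_landscape()]).
#' @export
simulate_study <- function(config) {
  genome <- make_genome(config)
  genes <- make_gene_models(config, genome)
  simulate_landscape(config, genome, genes)
}

#' Write a simulated study to disk
#'
#' Emits `genome.fa`, `genes.tab`, `open_regions.bed`, `chip_peaks.bed`,
#' `deg.tab`, `diff_regions.tab`, `tf_scores.tab`, `motifs.jaspar`,
#' `annotations_map.tab`, `ground_truth.json` and `manifest.json`.
#' Byte-identical across runs with the same config.
#'
#' @param sim a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_genome_fasta(sim$genome, fp("genome.fa"))
  write_gene_table(sim$genes, fp("genes.tab"))
  write_bed(sim$open_regions, fp("open_regions.bed"))
  write_bed(sim$chip_peaks, fp("chip_peaks.bed"))
  utils::write.table(sim$deg, fp("deg.tab"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$diff_regions, fp("diff_regions.tab"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$tf_scores, fp("tf_scores.tab"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_jaspar_pfm(sim$motifs, fp("motifs.jaspar"))
  utils::write.table(sim$annotations_map, fp("annotations_map.tab"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$ground_truth, fp("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(seed = sim$config$seed,
                   config = unclass(sim$config),
                   files = c("genome.fa", "genes.tab", "open_regions.bed",
                             "chip_peaks.bed", "deg.tab", "diff_regions.tab",
                             "tf_scores.tab", "motifs.jaspar",
                             "annotations_map.tab", "ground_truth.json"))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
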