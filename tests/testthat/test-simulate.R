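test_that("genome generation is deterministic and near-uniform", {
  cfg <- quick_sim_config(seed = 3)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1)
  write_genome_fasta(g2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # 1 Mb chromosome: every base frequency within 0.25 +/- 0.01
  cfg1 <- quick_sim_config(seed = 4, n_chromosomes = 1,
                           chrom_length_bp = 1000000)
  gm <- make_genome(cfg1)
  fr <- Biostrings::alphabetFrequency(gm[[1]])[c("A", "C", "G", "T")] / 1e6
  expect_true(all(abs(fr - 0.25) < 0.01))

  expect_error(quick_sim_config(seed = 1, chrom_length_bp = 0), "positive")
})

test_that("gene models are valid, non-overlapping and biotype-controlled", {
  for (seed in 1:5) {
    cfg <- quick_sim_config(seed = seed)
    genes <- make_gene_models(cfg, make_genome(cfg))
    expect_equal(nrow(genes), cfg$n_genes)
    # validated on construction (exon bounds, sortedness); check overlap
    for (cm in unique(genes$chrom)) {
      g <- genes[genes$chrom == cm, ]
      sp <- data.frame(s = pmin(g$tss, g$tes), e = pmax(g$tss, g$tes))
      sp <- sp[order(sp$s), ]
      expect_true(all(sp$s[-1] >= sp$e[-nrow(sp)]))
    }
  }
  cfg_pc <- quick_sim_config(seed = 2, protein_coding_fraction = 1)
  genes <- make_gene_models(cfg_pc, make_genome(cfg_pc))
  expect_true(all(genes$biotype == "protein_coding"))
})

test_that("infeasible configurations error out before generation", {
  expect_error(quick_sim_config(seed = 1, frac_up_explained = 1.5),
               "fractions")
  # explained genes cannot exceed the ChIP-in-open target count
  expect_error(quick_sim_config(seed = 1, n_up = 200, n_down = 100),
               "exceed")
  expect_error(quick_sim_config(seed = 1, n_planted_pairs = 30),
               "motif regions")
  expect_error(quick_sim_config(seed = 1,
                                pair_distance_range_bp = c(50, 2000)),
               "too short")
  # too many objects for the genome
  expect_error(make_gene_models(
    quick_sim_config(seed = 1, chrom_length_bp = 60000),
    NULL), "cannot place")
})

test_that("the landscape plants exactly the configured structure", {
  cfg <- quick_sim_config(seed = 5)
  sim <- simulate_study(cfg)
  gt <- sim$ground_truth

  # explained fractions exact with noise off (planted 0.5 of 20 and 16)
  expect_equal(gt$pct_up_explained, 0.5)
  expect_equal(gt$pct_down_explained, 0.5)
  expect_equal(length(gt$target_genes), 30)
  expect_equal(gt$n_chip_open_peaks, 34)  # 30 targets + 4 second peaks

  # DEG table is consistent with the planted sets
  d <- classify_deg(sim$deg, cfg$alpha)
  expect_setequal(d$up, gt$realized_up)
  expect_setequal(d$down, gt$realized_down)

  # ChIP-in-open count matches the config
  ov <- intersect_sets(sim$chip_peaks, sim$open_regions)
  expect_equal(length(unique(ov$a_name)), gt$n_chip_open_peaks)

  # scan-back: rescanning the emitted genome finds exactly the planted hits
  found <- do.call(rbind, lapply(sim$pwms, function(p)
    scan_sequences(sim$genome, sim$open_regions, p)))
  key <- function(h) paste(h$motif_id, h$chrom, h$start, h$strand)
  expect_setequal(key(found), key(gt$planted_hits))
  expect_equal(nrow(found), nrow(gt$planted_hits))

  # pair distances are within the configured range
  expect_true(all(gt$pairs$distance_bp >= cfg$pair_distance_range_bp[1] &
                    gt$pairs$distance_bp <= cfg$pair_distance_range_bp[2]))
  expect_equal(nrow(gt$pairs), cfg$n_planted_pairs)
})

test_that("the generator's annotation geometry matches the pipeline's annotator", {
  cfg <- quick_sim_config(seed = 6)
  sim <- simulate_study(cfg)
  ann <- annotate_peaks(sim$open_regions, sim$genes)
  truth <- sim$ground_truth$region_class[ann$name]
  expect_equal(ann$region_class, unname(truth))
  ann_pk <- annotate_peaks(sim$chip_peaks, sim$genes)
  map <- sim$ground_truth$peak_gene[ann_pk$name]
  # out-of-open decoy peaks keep their nearest gene; targets must match
  expect_equal(ann_pk$nearest_gene, unname(map))
})

test_that("a full write is byte-identical across runs with the same seed", {
  cfg <- quick_sim_config(seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # emitted files re-parse into the same objects (writer encodes NA score as 0)
  sim <- simulate_study(cfg)
  cols <- c("chrom", "start", "end", "name", "strand")
  expect_equal(iv_df(read_bed(file.path(d1, "open_regions.bed")), cols),
               iv_df(sim$open_regions, cols))
  genes2 <- read_gene_table(file.path(d1, "genes.tab"))
  expect_equal(genes2$tss, sim$genes$tss)
})

test_that("detection noise dilutes but does not bias explained fractions", {
  cfg <- quick_sim_config(seed = 9, noise_rate = 0.3,
                          n_up = 20, n_down = 16)
  sim <- simulate_study(cfg)
  gt <- sim$ground_truth
  d <- classify_deg(sim$deg, cfg$alpha)
  expect_lt(length(d$up), cfg$n_up)
  # ground truth records the realized (post-noise) sets exactly
  expect_equal(gt$pct_up_explained,
               length(intersect(gt$activated, d$up)) / length(d$up))
  expect_true(abs(gt$pct_up_explained - 0.5) < 0.35)
})
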