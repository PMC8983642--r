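test_that("JASPAR PFM parsing normalizes row order and round-trips", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 demo",
               "A [ 1 2 3 4 5 6 7 8 ]",
               "C [ 0 0 1 0 0 2 0 0 ]",
               "T [ 9 8 7 6 5 4 3 2 ]",
               "G [ 1 1 1 1 1 1 1 1 ]",
               ">M2",
               "A [ 10 0 0 0 10 0 0 0 ]",
               "C [ 0 10 0 0 0 10 0 0 ]",
               "G [ 0 0 10 0 0 0 10 0 ]",
               "T [ 0 0 0 10 0 0 0 10 ]"), f)
  ms <- parse_jaspar_pfm(f)
  expect_length(ms, 2)
  expect_equal(ncol(ms$M1$counts), 8)
  # row order normalized to A,C,G,T
  expect_equal(ms$M1$counts["T", 1], 9, ignore_attr = TRUE)
  f2 <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar_pfm(ms, f2)
  ms2 <- parse_jaspar_pfm(f2)
  expect_equal(ms2$M1$counts, ms$M1$counts)
  expect_equal(ms2$M2$counts, ms$M2$counts)

  writeLines(c(">bad", "A [ 1 2 3 4 5 6 7 8 ]", "C [ 1 2 3 4 5 6 7 8 ]",
               "G [ 1 2 3 4 5 6 7 8 ]", "T [ 1 2 3 4 5 6 7 ]"), f)
  expect_error(parse_jaspar_pfm(f), "unequal width")
  writeLines(c(">bad", "A [ 1 2 3 4 5 6 7 -8 ]", "C [ 1 2 3 4 5 6 7 8 ]",
               "G [ 1 2 3 4 5 6 7 8 ]", "T [ 1 2 3 4 5 6 7 8 ]"), f)
  expect_error(parse_jaspar_pfm(f), "negative|nonnegative")
})

test_that("log-odds scores match the analytic cases", {
  # width-6 consensus PWM, no pseudocount, uniform background:
  # the consensus window scores 6 * log2(4) = 12 bits
  p <- pfm_to_pwm(consensus_pfm("C6", "CGTCGT"), pseudocount = 0)
  expect_equal(p$max_score, 12, tolerance = 1e-9)
  bg <- paste(rep("A", 100), collapse = "")
  seq <- paste0(substr(bg, 1, 40), "CGTCGT", substr(bg, 47, 100))
  genome <- Biostrings::DNAStringSet(c(c1 = seq))
  hits <- scan_sequences(genome, interval_set("c1", 0, 100), p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 40)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score_bits, 12, tolerance = 1e-9)

  # uniform PWM scores 0 bits everywhere
  u <- pfm_to_pwm(pfm("U", matrix(25, 4, 6)), pseudocount = 0)
  uh <- scan_sequences(genome, interval_set("c1", 0, 100), u)
  expect_true(all(abs(uh$score_bits) < 1e-9))
})

test_that("regions shorter than the motif and N windows yield no hits", {
  p <- pfm_to_pwm(consensus_pfm("C6", "CGTCGT"), pseudocount = 0)
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTCGTNCGTCGT"))
  expect_equal(nrow(scan_sequences(genome, interval_set("c1", 0, 4), p)), 0)
  # the window overlapping N is skipped; the clean consensus at 8 is found
  h <- scan_sequences(genome, interval_set("c1", 0, 14), p)
  expect_equal(h$start, c(1, 8))
})

test_that("scanner agrees with the exhaustive window oracle", {
  set.seed(23)
  genome <- rand_genome(c(c1 = 3000, c2 = 2000))
  regions <- interval_set(c("c1", "c1", "c2"), c(0, 1500, 100),
                          c(400, 1900, 600),
                          name = c("r1", "r2", "r3"))
  counts <- matrix(sample(0:40, 32, TRUE), 4, 8)
  p <- pfm_to_pwm(pfm("R", counts), threshold_frac = 0.7)
  got <- scan_sequences(genome, regions, p)
  expect_equal(as.data.frame(got)[, c("chrom", "start", "end", "strand",
                                      "score_bits")],
               bf_scan(genome, regions, p), ignore_attr = TRUE)
})

test_that("scanning the reverse-complemented genome mirrors the hit set", {
  set.seed(29)
  L <- 2000
  genome <- rand_genome(c(c1 = L))
  rc <- Biostrings::DNAStringSet(c(c1 = revcomp(as.character(genome[[1]]))))
  p <- pfm_to_pwm(pfm("R", matrix(sample(0:30, 28, TRUE), 4, 7)),
                  threshold_frac = 0.7)
  h1 <- scan_sequences(genome, interval_set("c1", 0, L), p)
  h2 <- scan_sequences(rc, interval_set("c1", 0, L), p)
  expect_equal(nrow(h1), nrow(h2))
  mirrored <- data.frame(start = L - h2$end, end = L - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score_bits = h2$score_bits)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  h1o <- as.data.frame(h1)[order(h1$start, h1$strand),
                           c("start", "end", "strand", "score_bits")]
  expect_equal(h1o, mirrored, ignore_attr = TRUE)
})

test_that("raising the threshold never adds hits", {
  set.seed(31)
  genome <- rand_genome(c(c1 = 4000))
  regions <- interval_set("c1", 0, 4000)
  counts <- matrix(sample(0:40, 32, TRUE), 4, 8)
  prev <- Inf
  for (tf in c(0.5, 0.65, 0.8, 0.95)) {
    n <- nrow(scan_sequences(genome, regions,
                             pfm_to_pwm(pfm("R", counts),
                                        threshold_frac = tf)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("planted motif ranks first in enrichment with a Fisher oracle", {
  # deterministic background of A's so the only hits are the planted ones
  n_fg <- 100; n_bg <- 200; rl <- 100
  mk <- function(n, planted) {
    vapply(seq_len(n), function(i) {
      s <- paste(rep("A", rl), collapse = "")
      if (i <= planted) substr(s, 21, 28) <- "CGTCGTCG"
      s
    }, "")
  }
  seq_fg <- paste(mk(n_fg, 80), collapse = "")
  seq_bg <- paste(mk(n_bg, 10), collapse = "")
  genome <- Biostrings::DNAStringSet(c(fg = seq_fg, bg = seq_bg))
  fg <- interval_set("fg", (0:(n_fg - 1)) * rl, (1:n_fg) * rl)
  bg <- interval_set("bg", (0:(n_bg - 1)) * rl, (1:n_bg) * rl)
  pwms <- list(pfm_to_pwm(consensus_pfm("PLANTED", "CGTCGTCG")),
               pfm_to_pwm(consensus_pfm("DECOY", "GTACGTAC")))
  enr <- motif_enrichment(fg, bg, genome, pwms)
  expect_equal(enr$motif_id[1], "PLANTED")
  expect_equal(enr$fg_hit_regions[1], 80)
  expect_equal(enr$bg_hit_regions[1], 10)
  oracle_p <- fisher.test(matrix(c(80, 20, 10, 190), 2),
                          alternative = "greater")$p.value
  expect_equal(enr$p_value[1], oracle_p, tolerance = 1e-12)
  # motif absent everywhere: fractions 0 and p = 1
  expect_equal(enr$fg_fraction[2], 0)
  expect_equal(enr$bg_fraction[2], 0)
  expect_equal(enr$p_value[2], 1)
  # identical foreground and background: odds ratio 1, p not significant
  same <- motif_enrichment(fg, fg, genome, pwms)
  expect_equal(same$odds_ratio[same$motif_id == "PLANTED"], 1)
  expect_gt(same$p_value[same$motif_id == "PLANTED"], 0.4)
  expect_error(motif_enrichment(fg, bg[0, ], genome, pwms), "zero regions")
})

test_that("top-quantile TF selection matches the direct quantile oracle", {
  tab <- data.frame(motif_id = sprintf("m%03d", 1:100),
                    differential_binding_score = 1:100,
                    neg_log10_p = 0)
  sel <- select_top_tf_motifs(tab)
  expect_setequal(sel, sprintf("m%03d", c(1:5, 96:100)))

  # all-equal table: strict inequalities select nothing
  same <- data.frame(motif_id = letters[1:10],
                     differential_binding_score = 3, neg_log10_p = 1)
  expect_length(select_top_tf_motifs(same), 0)

  # a single extreme p is picked up through the p-value arm
  tab2 <- data.frame(motif_id = sprintf("t%02d", 1:20),
                     differential_binding_score = 0,
                     neg_log10_p = c(rep(0, 19), 5))
  expect_equal(select_top_tf_motifs(tab2), "t20")
  # intersection mode additionally requires an extreme score
  expect_length(select_top_tf_motifs(tab2, mode = "intersection"), 0)
})
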