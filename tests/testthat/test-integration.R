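test_that("differential-gene classification applies the padj/sign rule", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2fc = c(2, -1, 3), padj = c(0.01, 0.04, 0.2))
  d <- classify_deg(tab)
  expect_equal(d$up, "g1")
  expect_equal(d$down, "g2")
  expect_length(classify_deg(tab, alpha = 0)$up, 0)

  set.seed(41)
  big <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                    log2fc = round(rnorm(1000), 2),
                    padj = runif(1000))
  d2 <- classify_deg(big)
  expect_equal(d2$up, big$gene_id[big$padj < 0.05 & big$log2fc > 0])
  expect_equal(d2$down, big$gene_id[big$padj < 0.05 & big$log2fc < 0])
  # zero fold change is in neither set
  z <- data.frame(gene_id = "z", log2fc = 0, padj = 0.001)
  expect_length(unlist(classify_deg(z)), 0)
})

test_that("overlap fraction is |A intersect B| / |A|", {
  expect_equal(overlap_fraction(paste0("g", 1:4), c("g2", "g3", "z"))$fraction,
               0.5)
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b", "c"))$fraction, 1)
  expect_error(overlap_fraction(character(0), "a"), "empty")
})

test_that("permutation test hits its analytic edges and is seed-stable", {
  uni <- sprintf("u%04d", 1:1000)
  a <- uni[1:30]
  r <- permutation_overlap_test(a, a, uni, n_permutations = 200, seed = 1)
  expect_equal(r$permutation_p, 1 / 201)

  # disjoint sets: observed overlap 0 can never be exceeded, p = 1
  uni2 <- sprintf("v%05d", 1:10000)
  r2 <- permutation_overlap_test(uni2[1:30], uni2[5001:5040], uni2,
                                 n_permutations = 200, seed = 2)
  expect_equal(r2$permutation_p, 1)

  r3a <- permutation_overlap_test(a, uni[21:60], uni, 500, seed = 7)
  r3b <- permutation_overlap_test(a, uni[21:60], uni, 500, seed = 7)
  expect_identical(r3a, r3b)
  r3c <- permutation_overlap_test(a, uni[21:60], uni, 500, seed = 8)
  expect_lt(abs(r3c$permutation_p - r3a$permutation_p), 0.1)

  expect_error(permutation_overlap_test(c(a, "not_in_universe"), a, uni,
                                        200, seed = 1), "subsets")
  expect_error(permutation_overlap_test(a, a, uni, 50, seed = 1), ">= 100")
})

test_that("permutation p decreases as the planted overlap grows", {
  uni <- sprintf("u%03d", 1:500)
  a <- uni[1:50]
  ps <- vapply(c(0, 10, 20, 30), function(k) {
    b <- c(uni[seq_len(k)], uni[100 + seq_len(50 - k)])
    permutation_overlap_test(a, b, uni, 500, seed = 3)$permutation_p
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("active-target classification reproduces the worked arithmetic", {
  peaks <- interval_set("c1", (1:10) * 1000, (1:10) * 1000 + 100,
                        name = sprintf("pk%02d", 1:10))
  open <- interval_set("c1", 0, 20000, name = "open")
  ann <- data.frame(name = sprintf("pk%02d", 1:10),
                    gene_id = paste0("g", 1:10))
  ts <- active_target_classification(peaks, open, ann,
                                     up_genes = c("g1", "g2", "x1", "x2"),
                                     down_genes = c("g3", "y1"))
  expect_setequal(ts$activated, c("g1", "g2"))
  expect_equal(ts$repressed, "g3")
  expect_equal(ts$pct_up_explained, 0.5)
  expect_equal(ts$pct_down_explained, 0.5)
  expect_equal(ts$pct_chip_active, 0.3)

  empty <- active_target_classification(peaks, open, ann, character(0),
                                        character(0))
  expect_equal(empty$pct_up_explained, 0)
  expect_equal(empty$pct_chip_active, 0)

  far <- interval_set("c2", 0, 100, name = "far")
  expect_warning(
    none <- active_target_classification(peaks, far, ann, "g1", "g2"),
    "no ChIP peaks")
  expect_equal(none$pct_chip_active, 0)
  expect_error(active_target_classification(peaks, open, ann[1:5, ],
                                            "g1", "g2"), "lack an annotation")
})

test_that("co-occurrence emits all within-region pairs with midpoint distances", {
  region <- interval_set("c1", 0, 1000, name = "r1")
  ha <- data.frame(chrom = "c1", start = 94L, end = 106L, motif_id = "A",
                   strand = "+", score_bits = 10)
  hb <- data.frame(chrom = "c1", start = 394L, end = 406L, motif_id = "B",
                   strand = "-", score_bits = 10)
  cc <- cooccurrence_pairs(region, ha, hb)
  expect_equal(cc$summary$n_pairs, 1)
  expect_equal(cc$pairs$distance_bp, 300)
  expect_equal(cc$summary$frac_pairs_below_cutoff, 1)

  # hits in different regions never pair
  two <- interval_set("c1", c(0, 2000), c(1000, 3000), name = c("r1", "r2"))
  hb2 <- transform(hb, start = 2394L, end = 2406L)
  cc2 <- cooccurrence_pairs(two, ha, hb2)
  expect_equal(cc2$summary$n_pairs, 0)
  expect_equal(cc2$summary$n_regions_with_a, 1)
  expect_equal(cc2$summary$n_regions_with_b, 1)
  expect_equal(cc2$summary$n_regions_with_both, 0)
})

test_that("pair count equals the per-region product of hit counts", {
  set.seed(47)
  n_reg <- 20
  regions <- interval_set("c1", (0:(n_reg - 1)) * 2000,
                          (0:(n_reg - 1)) * 2000 + 1000,
                          name = sprintf("r%02d", 1:n_reg))
  mk_hits <- function(motif, lambda) {
    rows <- list()
    for (i in seq_len(n_reg)) {
      k <- rpois(1, lambda)
      if (k == 0) next
      s <- regions$start[i] + sample.int(980, k)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "c1", start = s, end = s + 12L, motif_id = motif,
        strand = "+", score_bits = 20)
    }
    do.call(rbind, rows)
  }
  ha <- mk_hits("A", 1.2)
  hb <- mk_hits("B", 0.8)
  cc <- cooccurrence_pairs(regions, ha, hb)
  per_region <- vapply(seq_len(n_reg), function(i) {
    na <- sum(ha$start >= regions$start[i] & ha$end <= regions$end[i])
    nb <- sum(hb$start >= regions$start[i] & hb$end <= regions$end[i])
    na * nb
  }, numeric(1))
  expect_equal(cc$summary$n_pairs, sum(per_region))
  # distances match brute-force midpoint arithmetic
  for (r in unique(cc$pairs$region_name)) {
    i <- match(r, regions$name)
    sa <- ha$start[ha$start >= regions$start[i] & ha$end <= regions$end[i]]
    sb <- hb$start[hb$start >= regions$start[i] & hb$end <= regions$end[i]]
    dd <- abs(outer(sa + 6, sb + 6, "-"))
    expect_equal(sort(cc$pairs$distance_bp[cc$pairs$region_name == r]),
                 sort(as.numeric(dd)))
  }
})
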