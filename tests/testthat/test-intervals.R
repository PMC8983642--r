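test_that("BED parsing maps fields and rejects malformed lines by number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "track name=peaks",
               "chr1\t100\t200\tpk1\t0\t+",
               "chr2\t50\t80"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 2)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x[x$chrom == "chr1", ]$start, 100)
  expect_equal(x[x$chrom == "chr1", ]$end, 200)
  expect_equal(x[x$chrom == "chr1", ]$name, "pk1")
  expect_equal(x[x$chrom == "chr1", ]$strand, "+")

  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\tab\t200", f)
  expect_error(read_bed(f), "line 1")
  writeLines("chr1\t100\t200\tx\t0\tz", f)
  expect_error(read_bed(f), "strand")
})

test_that("BED writer round-trips a 50-interval set exactly", {
  set.seed(11)
  x <- interval_set(sample(paste0("chr", 1:3), 50, TRUE),
                    start = s <- sample.int(1e5, 50),
                    end = s + sample.int(500, 50),
                    name = sprintf("pk%02d", 1:50),
                    score = sample(0:1000, 50),
                    strand = sample(c("+", "-", "*"), 50, TRUE))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(iv_df(y), iv_df(x))
})

test_that("intersection reports overlap widths and respects chromosomes", {
  a <- interval_set("chr1", 100, 200)
  b <- interval_set("chr1", 150, 250)
  p <- intersect_sets(a, b)
  expect_equal(nrow(p), 1)
  expect_equal(p$overlap_bp, 50)

  b2 <- interval_set("chr2", 100, 200)
  expect_equal(nrow(intersect_sets(a, b2)), 0)
  expect_equal(nrow(intersect_sets(a, interval_set(character(0),
                                                   integer(0),
                                                   integer(0)))), 0)
})

test_that("containment excludes partial overlaps", {
  outer <- interval_set("chr1", 100, 200, name = "o")
  expect_equal(nrow(contained_in(interval_set("chr1", 120, 130), outer)), 1)
  expect_equal(nrow(contained_in(interval_set("chr1", 95, 105), outer)), 0)
  # shared boundary still counts as contained
  expect_equal(nrow(contained_in(interval_set("chr1", 100, 200), outer)), 1)
})

test_that("interval operations agree with brute-force oracles", {
  set.seed(101)
  for (rep in 1:25) {
    a <- rand_iset(sample(20:120, 1))
    b <- rand_iset(sample(20:120, 1))
    expect_equal(intersect_sets(a, b), bf_intersect(a, b))
    expect_equal(contained_in(a, b), bf_contained(a, b))
    m <- merge_set(a)
    expect_equal(as.data.frame(m)[, c("chrom", "start", "end")],
                 bf_merge(a), ignore_attr = TRUE)
  }
})

test_that("merge collapses book-ended intervals, preserves coverage, idempotent", {
  a <- interval_set(c("chr1", "chr1"), c(100, 150), c(200, 250))
  m <- merge_set(a)
  expect_equal(as.data.frame(m)[, c("start", "end")],
               data.frame(start = 100L, end = 250L))
  d <- interval_set(c("chr1", "chr1"), c(100, 300), c(200, 400))
  expect_equal(nrow(merge_set(d)), 2)
  # book-ended intervals merge (bedtools merge default)
  t2 <- interval_set(c("chr1", "chr1"), c(100, 200), c(200, 300))
  expect_equal(nrow(merge_set(t2)), 1)

  set.seed(5)
  for (rep in 1:10) {
    x <- rand_iset(60, max_pos = 9000, max_w = 800)
    m1 <- merge_set(x)
    expect_equal(as.data.frame(merge_set(m1)), as.data.frame(m1))
    expect_equal(covered_bp(x), sum(bf_merge(x)$end - bf_merge(x)$start))
  }
})

test_that("consensus is the merged union with per-sample support counts", {
  s1 <- interval_set("chr1", 100, 200)
  s2 <- interval_set("chr1", 150, 250)
  cp <- consensus_peaks(list(s1, s2))
  expect_equal(cp$start, 100)
  expect_equal(cp$end, 250)
  expect_equal(cp$support, 2)

  one <- rand_iset(30)
  expect_equal(as.data.frame(consensus_peaks(list(one)))[, c("chrom", "start", "end")],
               as.data.frame(merge_set(one))[, c("chrom", "start", "end")])
  expect_error(consensus_peaks(list()), "at least one sample")

  # k identical samples: consensus = merge, support = k everywhere
  set.seed(7)
  x <- rand_iset(40)
  k <- 4
  ck <- consensus_peaks(rep(list(x), k))
  expect_equal(as.data.frame(ck)[, c("chrom", "start", "end")],
               as.data.frame(merge_set(x))[, c("chrom", "start", "end")])
  expect_true(all(ck$support == k))
})

test_that("self-intersection of a merged set yields one full-width self pair each", {
  set.seed(21)
  m <- merge_set(rand_iset(80))
  p <- intersect_sets(m, m)
  expect_equal(nrow(p), nrow(m))
  expect_true(all(p$a_idx == p$b_idx))
  expect_equal(p$overlap_bp, (m$end - m$start)[p$a_idx])
})

test_that("containment pairs are a subset of intersection pairs", {
  set.seed(33)
  for (rep in 1:10) {
    a <- rand_iset(60)
    b <- rand_iset(60)
    cc <- contained_in(a, b)
    ii <- intersect_sets(a, b)
    expect_true(all(paste(cc$inner_idx, cc$outer_idx) %in%
                      paste(ii$a_idx, ii$b_idx)))
  }
})
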