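#' Genomic interval sets
#'
#' An `interval_set` is a data frame of 0-based half-open genomic intervals
#' (the BED convention), sorted by (chrom, start, end), with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand` and an optional
#' provenance `label` attribute. All coordinates are kept 0-based half-open
#' internally; conversion to the 1-based closed convention happens only at
#' the boundary with GenomicRanges.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start positions.
#' @param end integer vector, exclusive end positions; must satisfy
#'   `end > start`.
#' @param name optional interval identifiers.
#' @param score optional numeric scores.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param label optional provenance tag (e.g. sample or condition).
#' @return A data frame of class `interval_set`.
#' @export
#' @examples
#' interval_set("chr1", 100, 200, name = "pk1")
interval_set <- function(chrom, start, end, name = NA_character_,
                         score = NA_real_, strand = "*", label = NULL) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = as.character(rep_len(chrom, n)),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    name = as.character(rep_len(name, n)),
    score = as.numeric(rep_len(score, n)),
    strand = as.character(rep_len(strand, n)),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    df <- df[0, , drop = FALSE]
  }
  validate_intervals(df)
  new_interval_set(df, label = label)
}

new_interval_set <- function(df, label = NULL) {
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  attr(df, "label") <- label
  df
}

validate_intervals <- function(df, context = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(context, ": start/end must be integer coordinates", call. = FALSE)
  }
  if (any(df$start < 0)) {
    stop(context, ": start must be >= 0", call. = FALSE)
  }
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("%s: end <= start (width must be positive) at row %d",
                 context, bad[1]), call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-", "*"))) {
    stop(context, ": strand must be one of '+', '-', '*'", call. = FALSE)
  }
  invisible(df)
}

is_interval_set <- function(x) inherits(x, "interval_set")

#' @export
print.interval_set <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("interval_set with %d intervals%s\n", nrow(x),
              if (is.null(lbl)) "" else paste0(" [", lbl, "]")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

## interval_set (0-based half-open) -> GRanges (1-based closed), strand
## deliberately dropped: accessibility and peak overlap are unstranded.
## A shared seqlevel universe avoids spurious cross-set warnings.
.as_gr <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header; columns 1-3 mandatory, 4 = name, 5 = score,
#' 6 = strand. Lines starting with `#`, `track` or `browser` are skipped.
#' A `"."` name is read as missing; a `"."` strand as unstranded.
#'
#' @param path path to the BED file.
#' @param label provenance label; defaults to the file name.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, label = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("BED parse error at line %d: fewer than 3 columns", i),
           call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("BED parse error at line %d: non-integer coordinate", i),
           call. = FALSE)
    }
    if (e <= s || s < 0) {
      stop(sprintf("BED parse error at line %d: end <= start or start < 0", i),
           call. = FALSE)
    }
    nm <- if (length(f) >= 4 && f[4] != ".") f[4] else NA_character_
    sc <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
    st <- if (length(f) >= 6) f[6] else "*"
    if (st == ".") st <- "*"
    if (!st %in% c("+", "-", "*")) {
      stop(sprintf("BED parse error at line %d: unknown strand symbol '%s'",
                   i, st), call. = FALSE)
    }
    j <- j + 1L
    out[[j]] <- data.frame(chrom = f[1], start = s, end = e, name = nm,
                           score = sc, strand = st, stringsAsFactors = FALSE)
  }
  df <- if (j == 0) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out[seq_len(j)])
  }
  new_interval_set(df, label = label)
}

#' Write an interval set as BED
#'
#' Emits BED6 when any of name/score/strand is informative, BED3 otherwise.
#' Missing names are written as `"."`, missing scores as `0`, unstranded as
#' `"."`. Output order is the set's deterministic (chrom, start, end) order.
#'
#' @param x an [interval_set()].
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(is_interval_set(x))
  six <- nrow(x) > 0 &&
    (any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != "*"))
  if (six) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     x$chrom, x$start, x$end,
                     ifelse(is.na(x$name), ".", x$name),
                     ifelse(is.na(x$score), "0", format(x$score,
                                                        scientific = FALSE,
                                                        trim = TRUE)),
                     ifelse(x$strand == "*", ".", x$strand))
  } else {
    lines <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals from `a` and `b` on the same chromosome
#' that overlap by at least `min_overlap` bp. Pairs are sorted by
#' (chrom, a_start, b_start, a_end, b_end) for reproducibility. Strand is
#' ignored.
#'
#' @param a,b [interval_set()] objects.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return Data frame with one row per overlapping pair: the coordinates and
#'   names of both intervals, their row indices in `a`/`b`, and `overlap_bp`.
#' @export
intersect_sets <- function(a, b, min_overlap = 1L) {
  stopifnot(is_interval_set(a), is_interval_set(b))
  empty <- data.frame(chrom = character(), a_idx = integer(),
                      a_start = integer(), a_end = integer(),
                      a_name = character(), b_idx = integer(),
                      b_start = integer(), b_end = integer(),
                      b_name = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  lev <- union(unique(a$chrom), unique(b$chrom))
  h <- GenomicRanges::findOverlaps(.as_gr(a, lev), .as_gr(b, lev),
                                   minoverlap = as.integer(min_overlap))
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  if (length(qi) == 0) return(empty)
  out <- data.frame(
    chrom = a$chrom[qi],
    a_idx = qi, a_start = a$start[qi], a_end = a$end[qi], a_name = a$name[qi],
    b_idx = si, b_start = b$start[si], b_end = b$end[si], b_name = b$name[si],
    overlap_bp = pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$a_start, out$b_start, out$a_end, out$b_end), ]
  rownames(out) <- NULL
  out
}

#' Whole-interval containment
#'
#' Reports pairs where an `inner` interval lies wholly inside an `outer`
#' interval on the same chromosome (`inner.start >= outer.start` and
#' `inner.end <= outer.end`); partial overlaps are excluded. This is the
#' "whole motif contained within the region" rule used when assigning motif
#' hits to accessible regions.
#'
#' @param inner,outer [interval_set()] objects.
#' @return Data frame of contained pairs sorted by
#'   (chrom, inner_start, outer_start).
#' @export
contained_in <- function(inner, outer) {
  stopifnot(is_interval_set(inner), is_interval_set(outer))
  empty <- data.frame(chrom = character(), inner_idx = integer(),
                      inner_start = integer(), inner_end = integer(),
                      inner_name = character(), outer_idx = integer(),
                      outer_start = integer(), outer_end = integer(),
                      outer_name = character(), stringsAsFactors = FALSE)
  if (nrow(inner) == 0 || nrow(outer) == 0) return(empty)
  lev <- union(unique(inner$chrom), unique(outer$chrom))
  h <- GenomicRanges::findOverlaps(.as_gr(inner, lev), .as_gr(outer, lev),
                                   type = "within")
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  if (length(qi) == 0) return(empty)
  out <- data.frame(
    chrom = inner$chrom[qi],
    inner_idx = qi, inner_start = inner$start[qi], inner_end = inner$end[qi],
    inner_name = inner$name[qi],
    outer_idx = si, outer_start = outer$start[si], outer_end = outer$end[si],
    outer_name = outer$name[si],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$inner_start, out$outer_start,
                   out$inner_end, out$outer_end), ]
  rownames(out) <- NULL
  out
}

#' Merge overlapping and book-ended intervals
#'
#' Collapses overlapping and touching intervals on the same chromosome
#' (matching the `bedtools merge` default). Total covered bp is preserved.
#'
#' @param a an [interval_set()].
#' @return A merged [interval_set()]; names/scores/strand are dropped.
#' @export
merge_set <- function(a) {
  stopifnot(is_interval_set(a))
  if (nrow(a) == 0) return(a)
  r <- GenomicRanges::reduce(.as_gr(a))
  interval_set(as.character(GenomicRanges::seqnames(r)),
               GenomicRanges::start(r) - 1L,
               GenomicRanges::end(r),
               label = attr(a, "label"))
}

#' Consensus peaks across samples
#'
#' The consensus is the merge of the union of all samples' peaks (a peak
#' appearing in at least one sample contributes). Each consensus interval is
#' annotated with `support`, the number of samples having at least one peak
#' inside it.
#'
#' @param samples a list of [interval_set()] objects, one per sample.
#' @return An [interval_set()] with a `support` column and names
#'   `consensus_1, consensus_2, ...` in (chrom, start) order.
#' @export
consensus_peaks <- function(samples) {
  if (!is.list(samples) || length(samples) == 0) {
    stop("consensus_peaks: need at least one sample interval set",
         call. = FALSE)
  }
  stopifnot(all(vapply(samples, is_interval_set, logical(1))))
  pooled <- do.call(rbind, lapply(samples, function(s) {
    as.data.frame(s)[, c("chrom", "start", "end", "name", "score", "strand")]
  }))
  merged <- merge_set(new_interval_set(pooled))
  gr_m <- .as_gr(merged)
  support <- integer(nrow(merged))
  lev <- unique(merged$chrom)
  for (s in samples) {
    if (nrow(s) == 0) next
    h <- GenomicRanges::findOverlaps(
      .as_gr(s, union(unique(s$chrom), lev)),
      .as_gr(merged, union(unique(s$chrom), lev)), type = "within")
    contrib <- unique(S4Vectors::subjectHits(h))
    support[contrib] <- support[contrib] + 1L
  }
  merged$name <- sprintf("consensus_%d", seq_len(nrow(merged)))
  merged$support <- support
  merged
}

#' Total covered basepairs of an interval set
#' @param x an [interval_set()].
#' @return Integer, the size of the union of `x`.
#' @export
covered_bp <- function(x) {
  m <- merge_set(x)
  sum(m$end - m$start)
}
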