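DNA_BASES <- c("A", "C", "G", "T")

#' Position frequency matrices
#'
#' A PFM holds per-position base counts (rows A, C, G, T in that fixed
#' order), e.g. as distributed by JASPAR. Width must be at least 4.
#'
#' @param motif_id motif identifier.
#' @param counts numeric 4 x width matrix of nonnegative counts; rows are
#'   taken to be A, C, G, T (rownames are normalized).
#' @return List of class `pfm`.
#' @export
pfm <- function(motif_id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("pfm: counts must have 4 rows (A,C,G,T)",
                              call. = FALSE)
  if (ncol(counts) < 4) stop("pfm: motif width must be >= 4", call. = FALSE)
  if (any(counts < 0) || anyNA(counts)) {
    stop("pfm: counts must be nonnegative", call. = FALSE)
  }
  rownames(counts) <- DNA_BASES
  structure(list(motif_id = motif_id, counts = counts), class = "pfm")
}

#' Build a sharp PFM from a consensus string
#' @param motif_id motif identifier.
#' @param consensus a string over A/C/G/T.
#' @param count per-position count given to the consensus base.
#' @return A [pfm()] with `count` on the consensus base, 0 elsewhere.
#' @export
consensus_pfm <- function(motif_id, consensus, count = 100) {
  b <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(b %in% DNA_BASES))
  m <- matrix(0, 4, length(b), dimnames = list(DNA_BASES, NULL))
  m[cbind(match(b, DNA_BASES), seq_along(b))] <- count
  pfm(motif_id, m)
}

#' Parse a JASPAR-format PFM file
#'
#' Records are a `>ID NAME` header followed by four rows like
#' `A [ 4 19 0 ... ]` (brackets optional). Row order in the file may be
#' arbitrary; output rows are normalized to A, C, G, T.
#'
#' @param path file path.
#' @return Named list of [pfm()] objects.
#' @export
parse_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("JASPAR parse error: no '>' records",
                               call. = FALSE)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    id <- strsplit(sub("^>\\s*", "", lines[heads[k]]), "\\s+")[[1]][1]
    body <- lines[seq(heads[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) != 4) {
      stop(sprintf("JASPAR parse error in record '%s': expected 4 base rows",
                   id), call. = FALSE)
    }
    rows <- list()
    for (ln in body) {
      m <- regmatches(ln, regexec("^([ACGT])\\s*\\[?\\s*([^]]*)\\]?\\s*$", ln))[[1]]
      if (length(m) != 3) {
        stop(sprintf("JASPAR parse error in record '%s': bad row '%s'",
                     id, ln), call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (anyNA(vals)) {
        stop(sprintf("JASPAR parse error in record '%s': non-numeric count",
                     id), call. = FALSE)
      }
      rows[[m[2]]] <- vals
    }
    if (!setequal(names(rows), DNA_BASES)) {
      stop(sprintf("JASPAR parse error in record '%s': need rows A,C,G,T",
                   id), call. = FALSE)
    }
    w <- unique(lengths(rows))
    if (length(w) != 1) {
      stop(sprintf("JASPAR parse error in record '%s': rows of unequal width",
                   id), call. = FALSE)
    }
    counts <- do.call(rbind, rows[DNA_BASES])
    if (any(counts < 0)) {
      stop(sprintf("JASPAR parse error in record '%s': negative counts", id),
           call. = FALSE)
    }
    out[[id]] <- pfm(id, counts)
  }
  out
}

#' @rdname parse_jaspar_pfm
#' @param pfms a list of [pfm()] objects.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  lines <- unlist(lapply(pfms, function(x) {
    c(paste0(">", x$motif_id),
      vapply(DNA_BASES, function(b) {
        sprintf("%s [ %s ]", b,
                paste(format(x$counts[b, ], scientific = FALSE, trim = TRUE),
                      collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a PFM to a log-odds position weight matrix
#'
#' Column probabilities are `(count + pseudocount * background) /
#' (column_total + pseudocount)` (pseudocount distributed by the background
#' model, JASPAR/TOBIAS style) and scores are log2 odds against the
#' background ("bits"). The default hit threshold is `threshold_frac`
#' (80%) of the maximum achievable score; no threshold is stated by
#' footprinting tools' upstream references, so this is deliberately
#' configurable and echoed in reports.
#'
#' @param x a [pfm()].
#' @param background base composition (A,C,G,T), must sum to 1.
#' @param pseudocount added per column, spread by background (default 0.8).
#' @param threshold_bits explicit hit threshold; overrides `threshold_frac`.
#' @param threshold_frac fraction of the maximum score used as threshold.
#' @return List of class `pwm` with elements `motif_id`, `probs`, `bits`,
#'   `background`, `pseudocount`, `width`, `max_score`, `threshold_bits`.
#' @export
pfm_to_pwm <- function(x, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       pseudocount = 0.8, threshold_bits = NULL,
                       threshold_frac = 0.8) {
  stopifnot(inherits(x, "pfm"))
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  if (abs(sum(background) - 1) > 1e-9) {
    stop("pfm_to_pwm: background must sum to 1", call. = FALSE)
  }
  tot <- colSums(x$counts) + pseudocount
  if (any(tot <= 0)) {
    stop("pfm_to_pwm: column totals must be positive after pseudocount",
         call. = FALSE)
  }
  probs <- sweep(x$counts + pseudocount * background, 2, tot, "/")
  bits <- log2(probs / background)
  max_score <- sum(apply(bits, 2, max))
  structure(list(
    motif_id = x$motif_id,
    probs = probs,
    bits = bits,
    background = background,
    pseudocount = pseudocount,
    width = ncol(probs),
    max_score = max_score,
    threshold_bits = if (is.null(threshold_bits)) threshold_frac * max_score
                     else threshold_bits
  ), class = "pwm")
}

## bits matrix for scoring the reverse complement of a forward window
.revcomp_bits <- function(bits) {
  bits[c("T", "G", "C", "A"), rev(seq_len(ncol(bits))), drop = FALSE]
}

## score every window of width w starting at 1..K given base indices
## (1..4, NA for N); windows containing N score NA.
.window_scores <- function(idx, bits) {
  w <- ncol(bits)
  K <- length(idx) - w + 1L
  if (K < 1L) return(numeric(0))
  acc <- numeric(K)
  for (j in seq_len(w)) {
    acc <- acc + bits[cbind(idx[j:(j + K - 1L)], j)]
  }
  acc
}

#' Scan regions of a genome with a PWM
#'
#' Every window of motif width inside each region is scored on the forward
#' strand and against the reverse complement; windows scoring at least the
#' PWM's `threshold_bits` are reported as hits, in forward-genome
#' coordinates. Windows containing N are skipped. Because windows are
#' enumerated inside each region, every reported hit is wholly contained in
#' its region. Regions shorter than the motif yield no hits. Overlapping
#' hits of the same motif are all reported.
#'
#' @param genome a named `DNAStringSet`.
#' @param regions an [interval_set()] within chromosome bounds.
#' @param pwm a [pfm_to_pwm()] object.
#' @return Data frame of class `motif_hits`: `chrom`, `start`, `end`
#'   (0-based half-open), `motif_id`, `strand`, `score_bits`,
#'   `region_name`, `region_idx`, sorted by (chrom, start, strand).
#' @export
scan_sequences <- function(genome, regions, pwm) {
  stopifnot(is_interval_set(regions), inherits(pwm, "pwm"))
  w <- pwm$width
  bits_rc <- .revcomp_bits(pwm$bits)
  res <- list()
  for (i in seq_len(nrow(regions))) {
    seq <- region_sequence(genome, regions$chrom[i], regions$start[i],
                           regions$end[i])
    idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
    sf <- .window_scores(idx, pwm$bits)
    if (length(sf) == 0) next
    sr <- .window_scores(idx, bits_rc)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") sf else sr
      hit <- which(!is.na(sc) & sc >= pwm$threshold_bits)
      if (length(hit) == 0) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = regions$chrom[i],
        start = regions$start[i] + hit - 1L,
        end = regions$start[i] + hit - 1L + w,
        motif_id = pwm$motif_id,
        strand = strand,
        score_bits = sc[hit],
        region_name = if (is.na(regions$name[i]))
          sprintf("%s:%d-%d", regions$chrom[i], regions$start[i],
                  regions$end[i]) else regions$name[i],
        region_idx = i,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res)) {
    do.call(rbind, res)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               motif_id = character(), strand = character(),
               score_bits = numeric(), region_name = character(),
               region_idx = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Write motif hits as BED6
#'
#' The BED score column carries `score_bits * 100`, rounded to the nearest
#' integer (BED scores are integers by convention).
#'
#' @param hits output of [scan_sequences()].
#' @param path output path.
#' @export
write_hits_bed <- function(hits, path) {
  x <- interval_set(hits$chrom, hits$start, hits$end,
                    name = hits$motif_id,
                    score = round(hits$score_bits * 100),
                    strand = hits$strand)
  write_bed(x, path)
}

#' Motif enrichment of foreground vs background regions
#'
#' For each PWM, regions are dichotomised by presence of at least one
#' contained hit and compared between foreground and background with a
#' one-sided Fisher exact test (enrichment in foreground). Motifs are
#' ranked by p value, then by descending odds ratio. This is a simplified
#' region-level enrichment in the spirit of HOMER's known-motif analysis.
#'
#' @param foreground,background non-empty [interval_set()] objects.
#' @param genome a named `DNAStringSet`.
#' @param pwms list of `pwm` objects.
#' @return Data frame: `motif_id`, `fg_hit_regions`, `fg_n`, `fg_fraction`,
#'   `bg_hit_regions`, `bg_n`, `bg_fraction`, `odds_ratio`, `p_value`,
#'   ranked best-first.
#' @export
motif_enrichment <- function(foreground, background, genome, pwms) {
  stopifnot(is_interval_set(foreground), is_interval_set(background))
  if (nrow(foreground) == 0) {
    stop("motif_enrichment: empty foreground", call. = FALSE)
  }
  if (nrow(background) == 0) {
    stop("motif_enrichment: background with zero regions", call. = FALSE)
  }
  fg_n <- nrow(foreground)
  bg_n <- nrow(background)
  rows <- lapply(pwms, function(p) {
    a <- length(unique(scan_sequences(genome, foreground, p)$region_idx))
    b <- length(unique(scan_sequences(genome, background, p)$region_idx))
    if (a == 0 && b == 0) {
      or <- 1
      pv <- 1
    } else {
      tab <- matrix(c(a, fg_n - a, b, bg_n - b), nrow = 2)
      pv <- stats::fisher.test(tab, alternative = "greater")$p.value
      num <- a * (bg_n - b)
      den <- (fg_n - a) * b
      or <- if (den == 0) Inf else num / den
    }
    data.frame(motif_id = p$motif_id,
               fg_hit_regions = a, fg_n = fg_n, fg_fraction = a / fg_n,
               bg_hit_regions = b, bg_n = bg_n, bg_fraction = b / bg_n,
               odds_ratio = or, p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -out$odds_ratio, out$motif_id), ]
  rownames(out) <- NULL
  out
}

#' Top-quantile selection of TF motifs from a differential binding table
#'
#' Selects rows whose differential binding score lies strictly below the
#' `quantile` quantile or strictly above the `1 - quantile` quantile, or
#' (union, the default) whose `-log10(p)` lies strictly above its
#' `1 - quantile` quantile. Quantiles use linear interpolation
#' (`stats::quantile` type 7); strict inequalities mean an all-equal table
#' selects nothing. `mode = "intersection"` requires both an extreme score
#' and an extreme p.
#'
#' @param table data frame with columns `motif_id`,
#'   `differential_binding_score`, `neg_log10_p`.
#' @param quantile tail fraction (default 0.05).
#' @param mode `"union"` (default) or `"intersection"`.
#' @return Character vector of selected `motif_id`s (table order).
#' @export
select_top_tf_motifs <- function(table, quantile = 0.05,
                                 mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(nrow(table) >= 1, all(table$neg_log10_p >= 0))
  s <- table$differential_binding_score
  p <- table$neg_log10_p
  lo <- stats::quantile(s, quantile, names = FALSE, type = 7)
  hi <- stats::quantile(s, 1 - quantile, names = FALSE, type = 7)
  ph <- stats::quantile(p, 1 - quantile, names = FALSE, type = 7)
  sel_s <- s < lo | s > hi
  sel_p <- p > ph
  sel <- if (mode == "union") sel_s | sel_p else sel_s & sel_p
  table$motif_id[sel]
}
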