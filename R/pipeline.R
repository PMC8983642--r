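.PIPELINE_KEYS <- c("simulate", "inputs", "alpha", "promoter_window",
                    "tts_window", "n_permutations", "threshold_frac",
                    "seed", "out_dir", "family_a", "family_b",
                    "distance_cutoff_bp")
.INPUT_KEYS_REQUIRED <- c("genome", "genes", "open_regions", "chip_peaks",
                          "deg", "diff_regions")
.INPUT_KEYS_OPTIONAL <- c("tf_scores", "motifs")

.fill_pipeline_defaults <- function(y) {
  defaults <- list(alpha = 0.05, promoter_window = c(1000, 100),
                   tts_window = c(100, 1000), n_permutations = 10000,
                   threshold_frac = 0.8, out_dir = NULL,
                   family_a = "AHR_SYN", family_b = "TEAD_SYN",
                   distance_cutoff_bp = 1000)
  for (k in names(defaults)) {
    if (is.null(y[[k]])) y[k] <- defaults[k]
  }
  y
}

validate_pipeline_config <- function(y) {
  unknown <- setdiff(names(y), .PIPELINE_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key: '%s'", unknown[1]),
         call. = FALSE)
  }
  has_sim <- !is.null(y$simulate)
  has_inp <- !is.null(y$inputs)
  if (has_sim && has_inp) {
    stop("configuration has both 'simulate' and 'inputs' blocks",
         call. = FALSE)
  }
  if (!has_sim && !has_inp) {
    stop("configuration needs a 'simulate' or an 'inputs' block",
         call. = FALSE)
  }
  if (is.null(y$seed)) {
    stop("missing mandatory key 'seed'", call. = FALSE)
  }
  if (has_sim) {
    ok <- setdiff(names(formals(simulation_config)), "seed")
    bad <- setdiff(names(y$simulate), ok)
    if (length(bad)) {
      stop(sprintf("unknown configuration key: 'simulate.%s'", bad[1]),
           call. = FALSE)
    }
  } else {
    miss <- setdiff(.INPUT_KEYS_REQUIRED, names(y$inputs))
    if (length(miss)) {
      stop(sprintf("missing mandatory key 'inputs.%s'", miss[1]),
           call. = FALSE)
    }
    bad <- setdiff(names(y$inputs),
                   c(.INPUT_KEYS_REQUIRED, .INPUT_KEYS_OPTIONAL))
    if (length(bad)) {
      stop(sprintf("unknown configuration key: 'inputs.%s'", bad[1]),
           call. = FALSE)
    }
  }
  y <- .fill_pipeline_defaults(y)
  y$seed <- as.integer(y$seed)
  class(y) <- "pipeline_config"
  y
}

#' Load and validate a pipeline configuration
#'
#' YAML key/value file with either a `simulate:` block (keys of
#' [simulation_config()]) or an `inputs:` block (paths to genome.fa,
#' genes.tab, open_regions.bed — one path or a list of per-sample peak
#' files — chip_peaks.bed, deg.tab, diff_regions.tab, and optionally
#' tf_scores.tab and a JASPAR motifs file). Defaults are filled
#' (alpha 0.05, 10,000 permutations, -1000/+100 promoter window,
#' 80%-of-max motif threshold); unknown keys are rejected by name.
#' `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return List of class `pipeline_config`.
#' @export
load_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Default simulate-mode configuration
#'
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param n_permutations permutations for the overlap test.
#' @param simulate named overrides for [simulation_config()].
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function(seed, out_dir = NULL,
                                    n_permutations = 10000,
                                    simulate = list()) {
  validate_pipeline_config(list(simulate = simulate, seed = seed,
                                out_dir = out_dir,
                                n_permutations = n_permutations))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the integration pipeline end to end
#'
#' Stage order: (optional) simulate -> consensus peaks -> annotation ->
#' differential-gene classification -> differential-region/DEG overlap
#' with permutation test -> active-target classification -> motif scan of
#' ChIP-supported differential regions (whole-motif containment by
#' construction) -> motif co-occurrence -> motif enrichment of bound vs
#' unbound open regions -> top-quantile TF selection -> report. The
#' orchestration adds no computation of its own: every reported number is
#' the output of one exported module operation, and every fraction in the
#' report carries its numerator and denominator. Rerunning with an
#' identical config reproduces `report.json` bit-exactly.
#'
#' @param config a `pipeline_config` (see [load_config()],
#'   [default_pipeline_config()]).
#' @return The report, an `integration_report` list; files (`report.json`,
#'   tab tables, `log.txt`) are written to `config$out_dir` (a temporary
#'   directory if unset).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- if (is.null(config$out_dir)) tempfile("tfscope_run_")
             else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time()),
                                       sprintf(fmt, ...)))
  }

  ## ---- inputs ----
  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", {
      simulate_study(do.call(simulation_config,
                             c(list(seed = config$seed),
                               config$simulate[setdiff(names(config$simulate),
                                                       "seed")])))
    })
    genome <- sim$genome
    genes <- sim$genes
    open_sets <- list(sim$open_regions)
    chip_peaks <- sim$chip_peaks
    deg <- sim$deg
    diff_regions <- sim$diff_regions
    tf_scores <- sim$tf_scores
    pwms <- sim$pwms
    logf("simulated study with seed %d (%d genes, %d open regions, %d ChIP peaks)",
         config$seed, nrow(genes), nrow(sim$open_regions), nrow(chip_peaks))
  } else {
    inp <- config$inputs
    sim <- NULL
    genome <- .stage("load_genome", read_genome_fasta(inp$genome))
    genes <- .stage("load_genes", read_gene_table(inp$genes))
    open_sets <- .stage("load_open_regions",
                        lapply(unlist(inp$open_regions), read_bed))
    chip_peaks <- .stage("load_chip_peaks", read_bed(inp$chip_peaks))
    deg <- .stage("load_deg",
                  utils::read.table(inp$deg, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
    diff_regions <- .stage("load_diff_regions",
                           utils::read.table(inp$diff_regions, header = TRUE,
                                             sep = "\t",
                                             stringsAsFactors = FALSE))
    tf_scores <- if (!is.null(inp$tf_scores)) {
      utils::read.table(inp$tf_scores, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    }
    pwms <- if (!is.null(inp$motifs)) {
      lapply(parse_jaspar_pfm(inp$motifs), pfm_to_pwm,
             threshold_frac = config$threshold_frac)
    } else {
      stop("pipeline stage 'load_motifs' failed: no motif file given",
           call. = FALSE)
    }
    logf("loaded real inputs from config")
  }

  ## ---- consensus ----
  consensus <- .stage("consensus", consensus_peaks(open_sets))
  # one pre-merged input set: keep its region names for traceability
  if (length(open_sets) == 1 && nrow(consensus) == nrow(open_sets[[1]]) &&
      all(consensus$start == open_sets[[1]]$start) &&
      all(consensus$end == open_sets[[1]]$end)) {
    consensus$name <- open_sets[[1]]$name
  }
  logf("consensus: %d regions from %d sample(s)", nrow(consensus),
       length(open_sets))

  ## ---- annotation ----
  ann_chip <- .stage("annotate", annotate_peaks(chip_peaks, genes,
                                                config$promoter_window,
                                                config$tts_window))

  ## ---- differential genes ----
  degsets <- .stage("classify_deg", classify_deg(deg, config$alpha))
  deg_genes <- union(degsets$up, degsets$down)
  logf("DEG: %d up, %d down at alpha %.3g", length(degsets$up),
       length(degsets$down), config$alpha)

  ## ---- differential regions x DEG overlap + permutation ----
  sig <- diff_regions[diff_regions$padj < config$alpha, , drop = FALSE]
  diff_genes <- unique(stats::na.omit(sig$annotated_gene))
  ovl <- .stage("overlap", overlap_fraction(diff_genes, deg_genes))
  perm <- .stage("permutation_test",
                 permutation_overlap_test(diff_genes, deg_genes,
                                          universe = genes$gene_id,
                                          n_permutations =
                                            config$n_permutations,
                                          seed = config$seed + 101L))
  logf("overlap: %d/%d differential-region genes in DEG set (p = %.4g)",
       ovl$n_overlap, ovl$n_a, perm$permutation_p)

  ## ---- active targets ----
  targets <- .stage("active_targets",
                    active_target_classification(chip_peaks, consensus,
                                                 ann_chip, degsets$up,
                                                 degsets$down))

  ## ---- annotation summary of ChIP peaks in open chromatin ----
  chip_open_ann <- ann_chip[ann_chip$name %in% targets$chip_open_peaks, ,
                            drop = FALSE]
  ann_summary <- .stage("annotation_summary",
                        summarize_annotation(chip_open_ann))

  ## ---- motif scan of ChIP-supported differential regions ----
  sig_set <- interval_set(sig$chrom, sig$start, sig$end,
                          name = sig$region_name)
  ov_sig <- intersect_sets(sig_set, chip_peaks)
  scan_set <- sig_set[sort(unique(ov_sig$a_idx)), , drop = FALSE]
  fam_a <- intersect(config$family_a, names(pwms))
  fam_b <- intersect(config$family_b, names(pwms))
  if (length(fam_a) == 0 || length(fam_b) == 0) {
    stop("pipeline stage 'scan_motifs' failed: motif families not in PWM set",
         call. = FALSE)
  }
  scan_fam <- function(ids) {
    do.call(rbind, lapply(pwms[ids], function(p)
      scan_sequences(genome, scan_set, p)))
  }
  hits_a <- .stage("scan_motifs", scan_fam(fam_a))
  hits_b <- .stage("scan_motifs", scan_fam(fam_b))
  ann_scan <- .stage("annotate", annotate_peaks(scan_set, genes,
                                                config$promoter_window,
                                                config$tts_window))

  ## ---- co-occurrence ----
  cooc <- .stage("cooccurrence",
                 cooccurrence_pairs(scan_set, hits_a, hits_b,
                                    annotations = ann_scan,
                                    distance_cutoff =
                                      config$distance_cutoff_bp))
  logf("co-occurrence: %d/%d scanned regions with both families, %d pairs",
       cooc$summary$n_regions_with_both, cooc$summary$n_regions,
       cooc$summary$n_pairs)

  ## ---- motif enrichment of bound vs unbound open regions ----
  ov_all <- intersect_sets(consensus, chip_peaks)
  fg_idx <- sort(unique(ov_all$a_idx))
  bg_idx <- setdiff(seq_len(nrow(consensus)), fg_idx)
  enr <- .stage("enrichment", {
    motif_enrichment(consensus[fg_idx, , drop = FALSE],
                     consensus[bg_idx, , drop = FALSE], genome, pwms)
  })

  ## ---- top-quantile TF selection ----
  top_tf <- if (!is.null(tf_scores)) {
    .stage("select_top_tf", select_top_tf_motifs(tf_scores))
  } else {
    character()
  }

  ## ---- report ----
  report <- structure(list(
    tool = "tfscope",
    version = as.character(utils::packageVersion("tfscope")),
    seed = config$seed,
    parameters = list(alpha = config$alpha,
                      promoter_window = config$promoter_window,
                      tts_window = config$tts_window,
                      n_permutations = config$n_permutations,
                      motif_threshold_frac_of_max = config$threshold_frac,
                      distance_cutoff_bp = config$distance_cutoff_bp,
                      note = paste("motif hit threshold is 80% of each",
                                   "PWM's maximum log-odds score unless",
                                   "configured otherwise")),
    deg = list(n_up = length(degsets$up), n_down = length(degsets$down),
               n_table = nrow(deg)),
    annotation = list(
      n_peaks = ann_summary$n_peaks,
      class_counts = as.list(ann_summary$class_counts),
      class_fractions = as.list(ann_summary$class_fractions),
      intragenic_fraction = ann_summary$intragenic_fraction,
      intergenic_fraction = ann_summary$intergenic_fraction,
      protein_coding_fraction = ann_summary$protein_coding_fraction),
    overlap = list(
      n_diff_region_genes = ovl$n_a,
      n_deg_genes = ovl$n_b,
      n_overlap = ovl$n_overlap,
      fraction_of_diff_region_genes = ovl$fraction,
      permutation_p = perm$permutation_p,
      permutation_null_mean = perm$null_mean,
      universe_size = perm$universe_size,
      n_permutations = perm$n_permutations),
    targets = list(
      n_chip_peaks = targets$n_chip_peaks,
      n_chip_open_peaks = targets$n_chip_open_peaks,
      n_chip_open_genes = targets$n_chip_open_genes,
      n_up_genes = length(targets$up_genes),
      n_down_genes = length(targets$down_genes),
      n_activated = length(targets$activated),
      n_repressed = length(targets$repressed),
      pct_up_explained = targets$pct_up_explained,
      pct_down_explained = targets$pct_down_explained,
      pct_chip_active = targets$pct_chip_active),
    cooccurrence = c(list(n_scanned_regions = cooc$summary$n_regions,
                          scanned_regions_are =
                            "differential regions overlapping a ChIP peak"),
                     cooc$summary[c("n_regions_with_a", "n_regions_with_b",
                                    "n_regions_with_both", "n_pairs",
                                    "distance_cutoff_bp",
                                    "frac_pairs_below_cutoff")],
                     list(pairs_per_class =
                            as.list(cooc$summary$pairs_per_class),
                          pairs_per_b_motif = cooc$summary$pairs_per_b_motif)),
    enrichment = enr,
    top_tf = list(selected = top_tf,
                  n_table = if (is.null(tf_scores)) 0 else nrow(tf_scores)),
    config = {
      # out_dir is run-local provenance, not part of the analysis identity
      cf <- unclass(config)
      cf$out_dir <- NULL
      cf
    }
  ), class = "integration_report")

  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(cooc$pairs, file.path(out_dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_annotation(ann_chip, file.path(out_dir, "chip_annotation.tsv"))
  status <- data.frame(
    gene_id = targets$chip_open_genes,
    status = ifelse(targets$chip_open_genes %in% targets$activated,
                    "activated",
                    ifelse(targets$chip_open_genes %in% targets$repressed,
                           "repressed", "bound_no_change")),
    stringsAsFactors = FALSE)
  utils::write.table(status, file.path(out_dir, "target_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("report written to %s", out_dir)
  writeLines(log_lines, file.path(out_dir, "log.txt"))

  attr(report, "out_dir") <- out_dir
  attr(report, "sim") <- sim
  report
}

#' @export
print.integration_report <- function(x, ...) {
  cat(sprintf("tfscope integration report (seed %d)\n", x$seed))
  cat(sprintf("  ChIP peaks in open chromatin: %d/%d -> %d unique genes\n",
              x$targets$n_chip_open_peaks, x$targets$n_chip_peaks,
              x$targets$n_chip_open_genes))
  cat(sprintf("  explained: %.2f%% of up, %.2f%% of down genes; %.2f%% of bound genes active\n",
              100 * x$targets$pct_up_explained,
              100 * x$targets$pct_down_explained,
              100 * x$targets$pct_chip_active))
  cat(sprintf("  diff-region genes in DEG set: %d/%d (%.2f%%), permutation p = %.4g\n",
              x$overlap$n_overlap, x$overlap$n_diff_region_genes,
              100 * x$overlap$fraction_of_diff_region_genes,
              x$overlap$permutation_p))
  cat(sprintf("  co-occurrence: %d/%d scanned regions with both motif families, %d pairs (%.0f%% < %d bp)\n",
              x$cooccurrence$n_regions_with_both,
              x$cooccurrence$n_scanned_regions, x$cooccurrence$n_pairs,
              100 * x$cooccurrence$frac_pairs_below_cutoff,
              x$cooccurrence$distance_cutoff_bp))
  cat(sprintf("  top enriched motif: %s (p = %.3g)\n",
              x$enrichment$motif_id[1], x$enrichment$p_value[1]))
  invisible(x)
}
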