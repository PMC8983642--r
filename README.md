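# tfscope

Multi-omics classification of direct transcription-factor targets.

A transcription factor like AHR (the aryl hydrocarbon receptor) binds far
more genomic sites than it regulates genes. `tfscope` is for analysts who
have three processed datasets on the same system — TF ChIP-seq peaks,
ATAC-seq open-chromatin regions, and a differential RNA-seq table — and
want the standard integration answers:

* which binding events sit in **open chromatin**, and which genes do they
  target (nearest-TSS annotation with HOMER-style promoter / exon /
  intron / TTS / intergenic classes);
* which of those genes actually **respond transcriptionally** — the
  factor's *active targets*, split into activated (bound + up) and
  repressed (bound + down), with the three headline fractions
  |activated|/|up|, |repressed|/|down| and
  |activated ∪ repressed|/|bound-open genes|;
* whether the overlap between differentially accessible genes and
  differentially expressed genes is **bigger than chance**, via a
  permutation null (draw |B| genes from the universe, `p = (1 + #{null ≥
  observed}) / (1 + n_perm)`);
* where two motif families (e.g. Ahr and Tead) **co-occur inside the same
  accessible region**: PWM log-odds scanning on both strands with
  whole-motif containment, all A×B pairs per region with motif-midpoint
  distances, the fraction of pairs closer than 1 kb, and per-class
  counts;
* a region-level Fisher **motif enrichment** of bound vs unbound regions,
  and the **top-5% selection rule** for TF differential-binding score
  tables (score below the 5% or above the 95% quantile, or −log10 p above
  its 95% quantile; linear-interpolation quantiles, strict inequalities).

Everything is exercised end to end on a seeded synthetic-data generator
that plants ground truth (target genes, explained fractions, motif
positions and pair distances), so the whole pipeline is testable without
any external download.

## Worked example

```r
library(tfscope)

cfg <- default_pipeline_config(seed = 1)   # packaged simulated study
report <- run_pipeline(cfg)
print(report)
#> tfscope integration report (seed 1)
#>   ChIP peaks in open chromatin: 217/257 -> 197 unique genes
#>   explained: 21.43% of up, 19.64% of down genes; 13.20% of bound genes active
#>   diff-region genes in DEG set: 26/116 (22.41%), permutation p = 9.999e-05
#>   co-occurrence: 40/116 scanned regions with both motif families, 40 pairs (100% < 1000 bp)
#>   top enriched motif: AHR_SYN (p = 3.23e-07)
```

Reading the output: of 257 ChIP peaks, 217 overlap an open region and
annotate to 197 unique genes; 21.43% of upregulated and 19.64% of
downregulated genes are explained by binding in open chromatin, which
covers 13.20% of the bound-open genes; the 26/116 overlap between
differentially accessible genes and the DEG set is far beyond the
permutation null (p ≈ 1e-4, the minimum at 10,000 permutations); all 40
planted Ahr–Tead motif pairs are recovered inside co-accessible regions,
all closer than 1 kb; and the planted AHR motif is the top enrichment
hit. Under the default noise-free generator every one of these numbers
equals the generator's ground truth exactly.

For real data, point a YAML config's `inputs:` block at your own
BED/FASTA/tab files (see `?load_config`); `inst/scripts/tfscope.R` is a
thin command-line wrapper (`run` / `simulate` subcommands).

Key tunables (all in the config): DEG/region cutoff `alpha` (0.05),
promoter window −1000/+100 bp, TTS window −100/+1000 bp, motif hit
threshold 80% of each PWM's maximum score, permutations (10,000). The
methods vignette (`vignettes/multiomics-target-integration.Rmd`)
motivates each default and records the numerical conventions.

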