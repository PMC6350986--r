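# poolAssoc

Association mapping from pooled resequencing (pool-seq) of phenotypically
contrasted insect pools — the design used to map insecticide-resistance loci
in *Aedes aegypti*: per collection, two replicate pools of 25 resistant and
two of 25 susceptible females are sequenced after exome capture, and allele
frequencies are estimated from per-site nucleotide read counts rather than
genotypes.

The package implements the full analysis as composable, tested stages:

1. **Site filters** — per-library minimum coverage (default 15×, so every
   tested site has ≥ 60× total over four libraries) and exclusion of
   monomorphic / no-data sites, with full accounting.
2. **Per-SNP test** — reads are summed across replicates within phenotype
   and each site's 2 × k nucleotide table is tested with the Pearson
   contingency χ² (df = k − 1, upper tail), giving the per-SNP score
   −log₁₀(p); per-phenotype expected heterozygosity 1 − Σpᵢ² is reported
   alongside.
3. **Gene scores** — each gene (UTRs + introns + exons interval) is scored
   by the *mean of the top 5%* of its site scores,
   m = max(1, ⌈0.05·n⌉); a gene is *high-association* iff it carries a
   Benjamini–Hochberg-rejected site (α = 0.01, across the collection's
   tested sites) **and** its score is ≥ 4.0.
4. **Cross-collection intersection** — Venn region counts, the common
   high-association set (non-coding genes removed and counted), the extreme
   subset (strictly above the nearest-rank 90th-percentile score in every
   collection), and positional summaries relative to chromosomes, arms and
   a focal locus such as the voltage-gated sodium channel (VGSC).
5. **Category enrichment** — upper-tail hypergeometric P(X ≥ k) of each
   functional category (13-code vocabulary, MIT and ReDox merged) in the
   common set against the coding-gene background.
6. **Synthetic data** — a seeded generator (`simulateStudy()`) that
   reproduces the study design with planted causal genes (allele-frequency
   differential δ between phenotype classes), finite-pool binomial
   resampling, sequencing error, shared per-site capture efficiencies, and
   a ground-truth table; an `ideal` mode without pool resampling serves as
   the calibration control for the χ².

Data live in Bioconductor containers: counts in a `PoolCounts`
(a `RangedSummarizedExperiment` with A/C/G/T assays), gene models in a
`GRanges`, results in `DataFrame`s/TSVs. `runPipeline()` orchestrates all
stages with a plain-text log of parameters and input checksums.

## Worked example

Simulate the default three-collection study (100 genes on 3 chromosomes,
20 shared causal genes at δ = 0.35, 2+2 pools of 25, mean total coverage
150×) and run the pipeline:

```r
library(poolAssoc)
cfg   <- simulationConfig(seed = 1)
study <- simulateStudy(cfg, dir = "sim")
res   <- runPipeline(pipelineConfig(
    counts     = study$paths$counts,
    genes      = study$paths$genes,
    categories = study$paths$categories,
    outDir     = "out"))
lengths(res$high_sets)
length(res$common$common)
head(res$enrichment, 3)
```

which prints

```
C1 C2 C3
23 24 26

[1] 20

 category_code k  n K  N     fold      p_upper
           TRP 7 20 7 81 4.050000 2.229369e-05
          PROT 3 20 4 81 3.037500 4.470951e-02
           MET 2 20 7 81 1.157143 5.551677e-01
```

Each collection's high-association set holds 23–26 genes; 20 coding genes
are common to all three — exactly the 20 planted causal genes
(`study$truth_genes` confirms) — and the planted transport category (all 7
of its coding genes causal, 4.05-fold enriched) tops the enrichment at
p ≈ 2 × 10⁻⁵. Per-site and per-gene TSVs, Venn region counts, the extreme
set with its per-collection thresholds, a positional summary and a
Manhattan-style PNG per collection are written under `out/`. At this small
scale the strict joint top-decile criterion often leaves the extreme subset
empty; with genome-scale inputs it isolates the handful of genes extreme in
every collection.

## Documentation

The methods vignette (`vignettes/pool-seq-association.Rmd`) describes the
model, every tunable parameter with its default and rationale, the
synthetic generator's assumptions, numerical conventions, and what the
simulation-based tests do and do not demonstrate about real data.
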