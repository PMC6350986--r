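---
title: "Pool-seq association mapping with poolAssoc: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq association mapping with poolAssoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolAssoc)
```

## The experimental design this package analyses

poolAssoc maps a binary phenotype — the motivating case is pyrethroid
resistance in *Aedes aegypti* — from pooled resequencing of phenotypically
contrasted pools. In the emulated design, each field collection contributes
two replicate pools of 25 resistant females and two replicate pools of 25
susceptible females; each pool is sequenced as one library after exome
capture, and reads are reduced to a per-site table of nucleotide read counts
per library. Allele frequencies are therefore estimated from read counts,
never from individual genotypes. Three independent collections allow the
association signal to be required in all of them, which is the main guard
against collection-specific artifacts.

## Site-level model

At a genomic site, let the read counts of the $k$ nucleotides with nonzero
total count be $r_1,\dots,r_k$ summed over the resistant libraries and
$s_1,\dots,s_k$ over the susceptible libraries. `testSites()` forms the
$2 \times k$ contingency table and computes the Pearson statistic

$$X^2 = \sum_{i,j} \frac{(O_{ij} - E_{ij})^2}{E_{ij}}, \qquad
  E_{ij} = \frac{O_{i\cdot}\,O_{\cdot j}}{O_{\cdot\cdot}},$$

with $\mathrm{df} = k - 1$ and the per-SNP association score
$-\log_{10} p$ from the upper tail of the $\chi^2$ law. Replicate libraries
are summed within phenotype before testing: the hypothesis is
resistant-versus-susceptible, and replicate disagreement is instead exposed
by the separate diagnostic `replicateHeterogeneityChisq()` (a replicates
$\times$ alleles table within one phenotype), which does not gate any
result.

Two conventions needed a decision:

* **Degrees of freedom.** A literal "number of alternate nucleotides minus
  one" rule gives df = 0 at a biallelic site, which admits no test. The
  default is the standard contingency df $= k - 1$ over the *observed*
  alleles; `dfRule = "alternate"` applies $k - 2$ for $k \ge 3$ (falling
  back to 1 when $k = 2$) for users who want the stricter multiallelic
  convention. Both give identical statistics, only the reference law
  changes.
* **Numerical tail.** $-\log_{10} p$ is computed from the log tail
  probability and capped (default 320, the double-precision underflow
  bound), so fixed differences at high coverage produce a large finite
  score rather than an infinity that would poison gene averaging. Reported
  p-values are floored at the smallest positive double. Nucleotides with
  zero total count are dropped from the table, so no expectation is zero.

Per-phenotype expected heterozygosity at a tested site is
$H_{exp} = 1 - \sum_i p_i^2$ over that phenotype's read frequencies, bounded
by $1 - 1/k$ (0.75 for four nucleotides); it is undefined (NA), not zero,
for a phenotype with no reads.

### Site filters

Sites enter testing only if every library has depth at least 15
(`filterSites()`); the rule is per library, matching a per-sample
minimum-coverage option in an mpileup-to-readcounts conversion, so with four
libraries every tested site has total depth $\ge 60$. Sites where a single
nucleotide carries all reads are monomorphic and are excluded and counted
separately from sites with no reads at all (`flagMonomorphic()`); the two
filters commute. Base-quality filtering is considered an upstream concern:
count tables are assumed post-quality-filter.

## Gene-level score

Genes are intervals spanning UTRs, exons and introns; a site belongs to
every gene interval containing it (`assignSitesToGenes()`, 1-based
inclusive). The gene score is the **mean of the top 5%** of the gene's site
scores, $m_{top} = \max(1, \lceil 0.05\,n \rceil)$
(`geneScore()`): selection under truncation concentrates on the few
localized SNPs that carry a selection signal while ignoring the bulk of
near-zero sites along the gene. Ties at the $m_{top}$ boundary are broken
deterministically (value descending, then position ascending); since
selected values are averaged, ties cannot change the score, only make the
selected set reproducible.

A gene enters the **high-association set** iff both printed criteria hold:

1. at least one of its sites is rejected by Benjamini–Hochberg FDR at
   $\alpha = 0.01$, applied across all tested site p-values of the
   collection, and
2. its gene score is at least the cutoff 4.0 (inclusive).

Where FDR should be applied (site level or gene level) is genuinely open;
site-level was chosen because the $\chi^2$ p-values are site-level objects
and the adjustment is described as preceding the gene-average analysis.
`fdrLevel = "gene"` applies BH across genes to each gene's minimum site
p-value as a sensitivity analysis. `bhFdr()` delegates to
`stats::p.adjust(method = "BH")`; the test suite checks it against an
independently coded step-up.

## Across collections

`intersectCollections()` reports the genes present in every collection's
high-association set together with all Venn region counts, optionally
removing non-coding genes from the common set (with a count). The
**extreme subset** (`extremeSubset()`) takes, per collection, the empirical
90th percentile of the common-set scores under the nearest-rank convention
and keeps genes *strictly* above the threshold in every collection — the
joint-criterion reading, consistent with one extreme group reported with a
per-collection floor value. Strict exceedance means a degenerate constant
score vector yields an empty extreme set rather than the whole set.
`positionalSummary()` counts genes per chromosome and (if arm intervals are
supplied — assembly centromere positions are configuration, not built-in)
per arm, and reports the signed distance from each gene's midpoint to a
focal locus such as the voltage-gated sodium channel, 0 when the gene
overlaps it.

## Functional-category enrichment

Categories come from a fixed 13-code vocabulary (`categoryCodes()`); the
mitochondrial and redox codes are merged (`MIT/ReDox`) before testing
because key redox enzymes are mitochondrially localized. For each category,
`enrichAll()` computes the upper-tail hypergeometric probability
$P(X \ge k)$ of observing $k$ category members in the $n$-gene
high-association set drawn from $N$ coding background genes of which $K$
are in the category — inclusive tail, the standard over-representation
reading. p-values are reported raw across categories (a BH option exists
but is off by default, matching common practice of reporting raw
hypergeometric probabilities with the counts). Genes missing a category are
counted as `UNK` with a warning.

## The synthetic generator

`simulateStudy()` emulates the study design so every stage can be tested
against a known truth. One *landscape* — gene intervals on 3 chromosomes,
functional categories, causal genes, per-site population allele
frequencies, per-site capture efficiencies — is drawn once and shared by
all collections, then each collection's pools and reads are sampled
independently.

* **Gene landscape.** 100 genes (log-normal lengths, median 2 kb),
  non-overlapping within a chromosome; Poisson(40) variant sites per gene
  (an exome-density scale-down); 19% of genes marked non-coding (the
  genome-wide coding fraction of the emulated annotation) and excluded from
  the enrichment background and from causality.
* **Allele frequencies.** The alternate allele frequency is
  Uniform(0.05, 0.5) and shared by both phenotypes at non-causal sites. In
  each causal gene, a quarter of sites (at least one) add `delta` = 0.35 to
  the resistant-population alternate frequency — association signal
  localized within the gene, as selection on a few coding sites would
  produce. A frequency pushed outside [0, 1] is a hard error naming the
  site, never a silent clip. 2% of sites carry a third allele to exercise
  the multiallelic df rule.
* **Causal-category planting.** The transport category (TRP) is planted
  over-represented among causal genes: it contributes
  $\min(K, \mathrm{round}(5 \cdot K/N \cdot n_{causal}))$ causal genes,
  a *realized* (not merely expected) over-representation, so tests of the
  enrichment stage measure the method rather than planting noise.
* **Pooling and reads.** In `pooled` mode each replicate pool draws
  $2 \times 25$ chromosomes binomially from its phenotype's population
  frequency, and reads are multinomial draws from the realized pool
  frequency — the finite-pool resampling that makes read-level tests
  overdispersed in real pool-seq. `ideal` mode skips pool resampling and is
  the calibration control: with `delta = 0` the read-level $\chi^2$ must be
  nominal there, and the suite checks the fraction of null p-values below
  0.05 lies in [0.043, 0.057] over $>10^4$ biallelic sites. Sequencing
  error (default 0.001 per read) redistributes mass uniformly over the
  other three nucleotides — the simplest symmetric miscall model.
* **Coverage.** Each site has a capture efficiency drawn from a
  Gamma(2, 2) (mean 1), shared by every library and collection because one
  probe set serves the whole study; library depth is Poisson(37.5 ×
  efficiency), i.e. marginally negative binomial with mean 37.5 and size 2
  per library, a mean **total** coverage of 150 across a collection's four
  libraries. Coverage semantics follow the convention of reporting totals
  across replicates; 150 is about half the emulated study's total, a
  deliberate reduced scale. The shared efficiency is what reproduces the
  realistic heavy-tailed spread of per-site total coverage (independent
  per-library draws would average it away) and implies that low-efficiency
  sites fail the 15× filter in every collection alike, as real capture
  dropouts do. It also keeps the read:chromosome ratio below one, the
  regime in which the read-level $\chi^2$ with the 4.0 gene-score cutoff is
  selective; at several reads per pooled chromosome, finite-pool
  overdispersion alone pushes null gene scores past any fixed cutoff, and
  no threshold choice can rescue specificity.
* **Determinism.** All randomness flows from one integer seed; identical
  configuration and seed give byte-identical output files.

**Problem sizes used in the tests** (package choices): single collections of
100–600 genes for unit and calibration checks; the parameter-recovery
surface uses the full default design (3 collections × 4 libraries, 100
genes, 20 shared causal genes, `delta` 0.35) once at a fixed seed for
recall and over 20 seeds for the planted-category property.

### What the simulations do and do not show

Passing tests demonstrate that the statistics are computed correctly (they
match independent oracles), that the test is calibrated when its sampling
assumptions hold, and that under the planted design the pipeline recovers
≥80% of causal genes with the planted category ranking first in ~95% of
runs. They do **not** show performance on real data: the generator draws
sites independently (no linkage disequilibrium, so no selective-sweep
shadowing of neighbours — precisely the effect that makes a VGSC-proximal
cluster hard to interpret in reality), assumes equal population structure
between phenotype classes (no kinship or admixture confounding), uses a
symmetric error model with no mapping bias or indels, and models capture
dropout only through smooth per-site efficiency.

## Known limitations

* Read counts are treated as the unit of evidence; the $\chi^2$ assumes
  independent reads, which finite pools violate. The `ideal` mode exists to
  verify the nominal case; on real pooled data the p-values are
  anticonservative and the gene-score cutoff plus cross-collection
  intersection carry the burden of specificity.
* No LD-aware or haplotype-aware aggregation; gene scores treat sites
  exchangeably.
* Indel alleles and base-quality handling are out of scope; inputs are
  assumed post-quality-filter nucleotide counts.
* The hypergeometric background requires category sizes in the background
  annotation; enrichment p-values are only as good as that annotation.

## A worked run

```{r, eval = FALSE}
cfg <- simulationConfig(seed = 1)
study <- simulateStudy(cfg, dir = "sim")
res <- runPipeline(pipelineConfig(
    counts = study$paths$counts,
    genes = study$paths$genes,
    categories = study$paths$categories,
    outDir = "out"))
head(res$enrichment)
```

See the README for a complete worked example with its printed output.
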