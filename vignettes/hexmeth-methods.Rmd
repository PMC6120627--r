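---
title: "Methylation diversity analysis for hexaploid wheat panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation diversity analysis for hexaploid wheat panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hexmeth` analyses DNA methylation diversity across panels of allohexaploid
bread wheat accessions profiled by targeted bisulfite sequencing. The
pipeline starts from per-cytosine count tables (Bismark CX-report dialect)
and per-accession SNP calls; read alignment and methylation extraction are
upstream of it. Its stages are:

1. **genotype** — homozygous SNP selection, accession-specific reference
   correction, strand-aware cytosine context derivation;
2. **methcall** — per-cytosine methylation levels, three-way status calls,
   chloroplast-based bisulfite conversion rate;
3. **smp** — panel-wide single methylation polymorphisms (SMPs), epiallele
   coding, conservation profiling, gene/family aggregation;
4. **subgenome** — indel-aware homoeolog coordinate translation and
   uni-/bi-/tri-genome methylation classification;
5. **dmr** — windowed differential methylation with context-specific rules
   and gene/promoter association;
6. **evolution** — deamination enrichment at ancestrally methylated
   cytosines and ancestor-descendant conservation;
7. **structure** — distance matrices, complete-linkage clustering,
   multiscale-bootstrap (AU) support, Mantel and runs tests, geographic
   concordance;
8. **expression** — replicate-based differential expression, triad
   allelic-balance normalisation, DMR-DE overlap;
9. **te** — transposable-element family abundance against a reference
   accession;
10. **simpanel** — a fully specified synthetic panel generator with
    recorded ground truth, used to validate every stage.

The numbered scripts under `analysis/` run these stages as a workflow over
a simulated panel and write compact tables under `results/`.

# Calling model and thresholds

A cytosine site is one cytosine on one strand; CpG sites are never merged
across strands, because every downstream definition scores cytosine
residues individually. The methylation level is the percentage of reads
methylated at the site. Status calls use the standard thresholds for
enriched, gene-rich wheat data:

* CpG: methylated at level >= 75%;
* CHG/CHH: methylated at level >= 10%;
* any context: unmethylated at level < 1%;
* otherwise intermediate — retained in outputs but excluded from the
  methylated/unmethylated classes (intermediate methylation is plausibly
  tissue-specific and is not modelled here);
* coverage below the floor (default 10x for SMP/DMR analyses, 5x for
  genotype-supporting summaries) gives `uncovered`.

The bisulfite conversion rate is estimated from the chloroplast genome,
which is unmethylated, as the pooled percentage of converted chloroplast
cytosine reads.

## SMPs

An SMP is a site that is covered >= 10x in *every* accession, has an
intact sequence context in every accession (no homozygous SNP at the C or
in the two bases downstream on its strand — the operational form of "no
SNP altering the cytosine context"), and is called methylated (code 100)
in at least two accessions and unmethylated (code 0) in at least two.
Intermediate accessions are coded 50. A gene counts as methylated in an
accession when at least one CpG in its body is called methylated; this is
the simplest rule consistent with gene-level tallies, and it is
configurable. Gene conservation groups scale the 90- and 40-accession cut
points proportionally with panel size.

## Subgenome methylation classes

A-subgenome coordinates anchor the homoeolog map; A-B and A-D maps are
composed for B-D. Translation is bijective inside aligned blocks and
undefined outside them, with indel offsets applied exactly. For each
covered homoeologous triple, pairwise two-sided Fisher exact tests on
(methylated, unmethylated) read counts are corrected by Benjamini-Hochberg
across all pairwise tests in the batch; a contrast is significant at
q < 0.01 with a methylation difference >= 50 percentage points. A site is
`tri` when all three subgenomes are methylated, `uni`/`bi` when exactly
one/two are methylated *and* the corresponding contrasts are significant,
and `unclassified` otherwise — inconsistent contrasts are never forced
into a class. The regional-count q-value method differs from methylKit's
SLIM; BH was chosen as the standard reproducible alternative and is
recorded in output metadata.

## DMRs

Methylation is pooled per context across non-overlapping 100-bp windows
anchored at coordinate 0 of each chromosome (deterministic tiling; the
trailing partial window is kept when it qualifies). Only cytosines covered
>= 10x in both samples contribute, and a window needs at least five such
cytosines. The window test is a two-sided Fisher exact test on the pooled
counts — regional counting, not per-cytosine averaging. Calling rules:
CpG/CHG windows need |difference| >= 50 points and q < 0.01; CHH windows
need |difference| >= 15 points, the lower sample at <= 5% (applied to the
window mean per sample), and q < 0.01. Feature association uses half-open
interval overlap; when no promoter track is supplied, promoters default to
2 kb upstream of the annotated gene start.

## Deamination enrichment

5-methylcytosine deaminates to thymine, so ancestrally methylated
cytosines should more often carry a divergent allele in the descendant
panel, biased to C-to-T (G-to-A for minus-strand cytosines, pooled as one
class). Ancestor cytosines are stratified by their called status using the
same thresholds as the panel; per accession the divergent fraction
(homozygous alternate alleles only, matching the genotype pipeline) and
the C-to-T fraction are computed per stratum, and strata are contrasted by
paired two-sided t-tests across accessions. The headline fold is the ratio
of across-accession mean divergence fractions.

One caveat the validation surfaced: in panel data the segregating sites
are *shared* across accessions, so per-accession divergence fractions are
positively correlated and the paired t-test is anticonservative with
respect to the site-sampling noise. Its type-I error is therefore
calibrated under the exchangeable null it assumes (equal mutation rates,
independent per-accession draws); on real panels the t statistic should be
read as descriptive strength of the contrast, not as a calibrated
site-level test.

## Population structure

Clustering uses Euclidean distances over accession profiles — SMP
epiallele codes {0, 50, 100} used directly as numeric features, or SNP
allele indicators — with complete linkage and `cutree`-style cutting; k is
an explicit argument everywhere (published analyses cut comparable trees
into eight or nine groups; no hidden default is imposed). AU support
reimplements the multiscale bootstrap: columns are resampled at scales
0.5-1.4 x p, and per clade the weighted regression
`qnorm(1 - BP) = v*sqrt(r) + c/sqrt(r)` gives `AU = 1 - pnorm(v - c)`,
with at least 10,000 total replicates by default. The Mantel test (Pearson
statistic, one-sided permutation p with 999 permutations by default) runs
through vegan. The Wald-Wolfowitz runs test uses its closed-form moments;
the ordering of the label sequence is the caller's responsibility, since
merged-dendrogram orderings are analysis-specific.

## Expression and TEs

Differential expression between two accessions uses a Welch t-test on
log2(x + 1) with the additional requirement that the fold-change direction
agrees in every replicate-versus-replicate comparison; this preserves the
"all replicates support the call" acceptance logic without reproducing
Ballgown's model, which is out of scope. Triad allelic balance normalises
the A/B/D expression of each homoeolog triad to 100% per replicate and
averages; the uni-methylated contrast compares the methylated genome's
share against the other two genomes' shares by Welch t. TE-family
base-space is normalised to a fixed 50,000,000 bp total per accession
before subtracting the reference profile, which removes sequencing-depth
differences exactly.

# The synthetic panel generator

`sim_config()` fixes the study conditions; a seed fixes every output
byte-for-byte. Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `n_accessions` | 20 | desk-scale stand-in for a ~105-line landrace panel |
| `n_populations` | 2 | the panel's two main ancestral groups |
| `subgenome_length` | 20,000 bp | smallest size with stable per-context statistics |
| `ancestor_divergence` | 0.02 /bp | subgenome divergence producing realistic homoeologous SNP density |
| `indel_rate` | 0.001 /bp | exercises indel-aware translation without fragmenting blocks |
| `panel_snp_rate` | 0.02 /bp | implied by ~89% of well-covered cytosines sharing context across the panel |
| `epiallele_rate` | 0.3 /cytosine | makes SMPs abundant enough to cluster on |
| `conversion_rate` | 0.987 | the reported panel-average conversion |
| `mean_coverage` | 30x | capture-like depth; Poisson per site |
| `deamination_fold` | 4 | the reported ~fourfold divergence elevation |
| `cpg_meth_high` | 0.9 | upper mode of bimodal CpG levels |
| `chh_meth_mean` | 0.25 | read-level mean of methylated CHH sites |
| `te_families` | 20 | enough families for class aggregates |

Internal constants (per-context methylation prevalences CpG 0.5 / CHG 0.2 /
CHH 0.08, CHG read level 0.6, C-to-T bias 0.9 of deamination mutations,
Balding-Nichols Fst 0.2, geography kernel range 0.2, population scatter
0.04, het rate 0.02) are fixed in `sim_const` and documented here; they
were chosen once as field-plausible values.

Generator mechanics worth knowing:

* **Geography.** Accessions live on a unit square around their population
  centre. Each epiallele has a focal point and a single uniform draw `u`;
  an accession's state flips when `exp(-distance/range) > u`. This makes
  epiallele state a deterministic function of position given the draw, so
  at `pop_scatter = 0` within-population epiallele variance is exactly
  zero (the separable limit used by the clustering recovery checks), while
  the default scatter yields the graded geography-linked structure the
  concordance tests need.
* **Regional epialleles.** By default every epiallele cytosine switches
  independently — the minimal model, and the one the SMP-level analyses
  assume. Site-independent flips essentially never move a 100-bp window
  mean by 50 points, so the workflow demo passes
  `epi_block_bp = 200` to flip coherent blocks and give DMR calling real
  regional signal. DMR power and false-positive criteria are always
  checked on constructed windows with known rates.
* **Deamination.** Every position segregates with probability
  `panel_snp_rate`, elevated `deamination_fold`-fold at ancestrally
  methylated cytosines, where the mutant allele is T (A on minus strand)
  with probability 0.9. Homozygous carriers of a mutation at a C lose
  that site from their methylation-callable set (the cytosine no longer
  exists). A small (~2-4%) downward attenuation of the recovered fold is
  expected because conversion-noise miscalls admit baseline-rate sites
  into the methylated stratum.
* **Promoter classes.** Each gene triad is planted as balanced, uni- or
  tri-promoter-methylated, and promoter CpG states are overridden
  panel-wide to match, so expression analyses can be validated against
  the same truth. Uni-methylated triads express the methylated homoeolog
  at a 28.82% share against 35.59% for each of the other two, matching
  the reported promoter-methylation expression contrast.
* **Chloroplast.** Fully unmethylated; its reports contain only
  conversion failures, which is what the conversion-rate estimator
  assumes.

What the generator does **not** emulate: read-level FASTQ data, sequencing
error beyond conversion failure, recombination/LD, within-accession
heterogeneity (single seedlings; methylation state is binary per accession
per site), correlated methylation between homoeologs, and capture
overdispersion beyond Poisson coverage. Tests passing on this generator
show the estimators are correct under the stated sampling model, not that
the model captures every property of real capture data.

# Numerical choices

* Fisher exact p-values are computed by direct hypergeometric summation
  over the table support with the conventional 1e-7 relative tie
  tolerance; the vectorised routine matches `stats::fisher.test` to
  ~1e-12 and exhaustive enumeration over all tables with totals <= 40.
* BH adjustment is `stats::p.adjust(method = "BH")`.
* Complete-linkage merges inherit `stats::hclust` tie-breaking; trees are
  deterministic given the input order.
* AU regression uses only scales with 0 < BP < 1; clades recovered in
  (almost) all or no replicates get support 1 or 0 directly.
* Window tiling is anchored at coordinate 0; shifting positions by one
  window width shifts window ids by one and leaves aggregates unchanged.
* Degenerate inputs error early and specifically: zero coverage at level
  computation, zero-total samples in window tests, missing values in
  distance matrices, single-label runs-test sequences, empty conservation
  strata.

# Validation scales

The test suite and `scripts/acceptance.R` run everything at fixed sizes
chosen to keep a complete run in minutes: Fisher enumeration over all
tables with totals <= 40; 1000 null + 200 planted windows at pooled depth
100; a 20-accession, 3 x 8 kb noise-free panel for SMP exactness; a
20-accession, 3 x 160 kb panel (~74k ancestor-informative cytosines) for
deamination fold recovery — sized so the Monte Carlo width of the fold
estimator stays well inside the +/-20% acceptance band at any seed;
30,000 translation round-trips; 500-1000 replicates for Mantel null
calibration; 300 triads for allelic balance.

# Known limitations

* The paired deamination t-test is anticonservative on shared panels (see
  above); the fold estimate itself is unbiased.
* Intermediate-methylation biology (tissue specificity) is out of scope;
  the <1% unmethylated rule is applied uniformly and configurably.
* methylKit's SLIM correction is replaced by BH; q-values are therefore
  conservative relative to SLIM on the same p-values.
* The gene-level methylation rule (>= 1 methylated CpG in the body) is a
  configurable convention; published gene tallies may use another.
* Heterozygous SNPs are not applied during reference correction, matching
  the homozygous-only correction pipeline.
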