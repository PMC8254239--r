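---
title: "Mapping a recessive locus by pooled-sequencing bulked-segregant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus by pooled-sequencing bulked-segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

## The mapping model

`bsamapr` maps a single fully recessive locus from bulked-segregant analysis
of pooled whole-genome sequencing (BSA-seq) of an F2 population. Two inbred
parents — one carrying the recessive mutant allele, one wild type — are
crossed; the selfed F1 yields an F2 in which the mutant phenotype segregates
3 wild : 1 mutant. DNA from mutant-phenotype individuals (the Y bulk) and
from wild-phenotype individuals (the G bulk) is pooled and sequenced.

At a biallelic site, the **SNP-index** of a bulk is the proportion of reads
carrying the variant allele, `alt / (ref + alt)`. With indices polarised on
the mutant-parent allele:

* in the Y bulk, every individual is homozygous mutant at the causal locus,
  so the expected SNP-index is 1 there;
* in the G bulk the wild-phenotype class is 1 AA : 2 Aa, so the expected
  mutant-allele frequency at the causal locus is 1/3;
* at unlinked loci both bulks are random draws from a 1:2:1 population and
  both indices hover around 1/2.

The **delta SNP-index**, defined here as Y-bulk minus G-bulk, is therefore
≈ 0 genome-wide and rises towards 2/3 at the causal locus, decaying with
recombination distance. Mapping reduces to finding where the smoothed delta
exceeds what bulk sampling plus finite read depth could produce by chance.

### Polarity

Indices are computed on the mutant-parent allele (the count table's `alt`
column is assumed to be the mutant-parent allele; when mapping from a VCF
called against a reference, polarise with the parental genotypes first).
This makes the causal peak positive by construction and the sign of delta
interpretable; a negative delta dip of the same magnitude would indicate
mispolarised input.

## Pipeline stages and their parameters

1. **Depth blocks** (`aggregate_blocks()`, `min_block_depth = 20` reads).
   Scanning each chromosome left to right, consecutive sites are pooled
   until the summed depth of *both* bulks reaches the minimum; a single
   deep site is its own block. Block indices are depth-weighted
   (summed alt over summed depth), so a block is equivalent to one site
   sequenced to the combined depth. The minimum is applied per bulk rather
   than to the combined depth because the noisier bulk limits the precision
   of delta. A trailing run that never reaches the depth is kept but
   flagged `complete = FALSE`.

2. **Sliding windows** (`window_profile()`, `window_bp = 1e6`,
   `step_bp = 1e4`). Windows start at 1, 1 + step, ... up to the chromosome
   end (terminal windows truncated and flagged); a unit belongs to a window
   when its start position lies inside. Member indices are averaged
   *unweighted*: blocks already equalise information content, and an
   unweighted mean keeps the window statistic insensitive to residual depth
   fluctuations. Windows with fewer than `min_units = 3` informative units
   report missing means, which suppresses single-block artifacts in sparse
   regions.

3. **Delta** (`delta_profile()`): Y mean minus G mean; missing if either
   side is missing. Missingness propagates — it also breaks region runs.

4. **Significance threshold** (`null_threshold()`, `alpha = 0.05`,
   `n_sim = 10000`). The null hypothesis is "no causal linkage": each
   bulk's true allele frequency at a site is the mean of pool-size
   independent draws from {0, 1/2, 1} with probabilities 1:2:1 —
   equivalently Binomial(2·pool, 1/2)/(2·pool) — and read counts are
   Binomial(depth, frequency). The threshold is the empirical (1 − alpha)
   quantile of the simulated delta. `add_thresholds()` matches the
   threshold to each window's median unit depth (a unit's depth taken as
   the mean of the two bulks' summed depths) and caches thresholds per
   unique rounded depth. A fixed user threshold is accepted instead via
   `threshold =`. Because the per-unit null quantile is applied to a
   window *mean* of many positively correlated units, the resulting test
   is conservative at the window level; we prefer that to modelling the
   within-window correlation, which depends on unknown linkage structure.

5. **Region calling** (`call_regions()`, `min_windows = 3`). Maximal runs
   of consecutive windows with delta above threshold become candidate
   regions with their peak delta and peak position; runs shorter than
   `min_windows` are dropped as isolated exceedances.

Coordinates are 1-based inclusive internally and in the count table; BED
exports use the 0-based half-open convention.

## The synthetic-data generator

`f2_sim_config()` / `simulate_bsa_dataset()` emulate the full study design:

* **Meiosis.** Each F2 individual is two independent F1 gametes; each
  gamete lays crossovers down as a Poisson process (no interference) at
  `recomb_rate` cM/Mb — 1 cM/Mb by default, a typical genome-wide average
  for a large plant genome, since no genetic map is assumed. Between two
  markers this reproduces the Haldane map function, which the tests verify
  against 10,000 simulated gametes.
* **Phenotype.** Fully penetrant recessive: yellow iff homozygous mutant at
  the causal locus. An optional `misclass_prob` (default 0) flips recorded
  phenotypes; the default reflects a cleanly scorable leaf-colour trait
  segregating exactly 3:1.
* **Bulks.** Random subsets of each phenotype class — 40 and 40 by default,
  the stated minimum number of pooled individuals per bulk in the study
  design the package targets. Bulk allele frequencies are the exact allele
  counts of the sampled individuals.
* **Sequencing.** Per site and bulk, depth ~ Poisson(`mean_depth`, default
  30 — a routine pooled-WGS budget; a fixed-depth mode exists for
  deterministic unit tests) and alt reads ~ Binomial(depth,
  f(1−e) + (1−f)e) with per-read error `e = 0.005`, the order of magnitude
  of post-filter Illumina error.
* **Defaults** otherwise mirror the targeted study: 967 F2 individuals, one
  60 Mb chromosome with an informative marker every 10 kb, causal locus at
  3.3 Mb.

The generator does **not** emulate read-level artifacts (mapping bias,
indels, duplicated or homoeologous regions of a polyploid genome,
multi-allelic sites) or segregation distortion. Passing the recovery tests
therefore shows the statistic behaves correctly under its own sampling
model, not that it is robust to alignment artifacts in real data — on real
data, upstream variant filtering carries that burden.

All randomness flows from the single config seed: each stage (gametes,
phenotype, bulk sampling, read sampling, thresholds) derives its own seed
from it by a fixed offset, so a stage can be re-run in isolation and
reproduce, and the whole count table is bit-identical across runs. Truth
and counts are written to separate files so the mapping stages never see
the truth.

## Segregation testing

`chi_square_segregation()` is the plain Pearson goodness-of-fit statistic
Σ(obs − exp)²/exp with **no continuity correction** — the conventional
choice for Mendelian ratio tests at F2 sample sizes, where Yates'
correction is needlessly conservative. The critical value is computed from
the chi-square distribution (`qchisq`), never hard-coded, and any number of
classes is supported (3:1, 9:3:3:1, ...).

## Candidate triage under the recessive model

After intersecting candidate regions with gene models
(`genes_in_regions()`, ≥ 1 bp overlap, via GenomicRanges), candidate
regulatory SNPs are annotated (`classify_snp()`) and filtered
(`triage_snps()`) by two rules:

* **R1** — a SNP heterozygous in the mutant-phenotype bulk is excluded: a
  recessive causal variant must be homozygous in affected individuals.
* **R2** — a SNP upstream of two or more genes whose expression moves in
  *discordant* directions (one up, one down) is excluded: a single shared
  cis element cannot drive opposite changes. Non-significant (`ns`) genes
  never trigger R2, and concordant directions retain the SNP.

Every excluded SNP carries machine-readable reason codes, and triage is
row-wise, hence order-independent.

Supporting choices: the upstream window defaults to 1000 bp (the
promoter-proximal span usually screened for regulatory variants); zygosity
from pooled counts is called homozygous at alt fraction ≥ 0.9 or ≤ 0.1
with depth ≥ 10, heterozygous otherwise, `NA` below that depth — a simple
declared rule, configurable where a study has its own caller. When no
transcription start is known, the interval between gene start and start
codon stands in for the 5′-UTR, and without exon structures the gene body
at/after the start codon counts as exonic; both fallbacks are stated in
the function documentation.

## Expression and pigment assays

`ddct_fold_change()` implements 2^−ΔΔCt: per replicate
ΔCt = Ct(target) − Ct(reference); ΔΔCt is the difference of group means of
per-replicate ΔCt (replicate-level aggregation keeps the replicate
variance available for testing); fold change = 2^−ΔΔCt, satisfying
reciprocity exactly. Significance is a two-sided Student's t-test on the
replicate ΔCt values — equal-variance by default, matching the classic
"Student's t" description, Welch by flag. No multiple-testing correction
is applied across genes by default; the significance level is a per-run
parameter because screening and confirmation stages legitimately use
different alphas.

`chlorophyll_content()` and `precursor_content()` evaluate the standard
spectrophotometric linear forms exactly:

* Chl-a = (12.7·A663 − 2.69·A645) · V / (1000·W), Chl-b =
  (22.9·A645 − 4.68·A663) · V / (1000·W), in mg per g fresh weight with
  extract volume V in mL (default 1 mL, the usual homogenisation volume)
  and fresh weight W in g;
* Mg-protoporphyrin IX = 0.06077·A590 − 0.01937·A575 − 0.003423·A628 and
  protochlorophyllide = 0.03563·A628 + 0.007225·A590 − 0.02955·A575,
  reported in equation units since these forms carry no volume/weight
  normalisation.

Pathological absorbance combinations can produce negative pigment values;
they are returned as computed rather than clamped, so the caller can flag
the measurement.

## Numerical choices and degenerate inputs

* Window means use prefix sums over position-sorted units (O(n + windows));
  the accumulated rounding (~1e−16) is clamped back into [0, 1].
* Zero-depth sites/blocks give `NA` indices and are excluded from window
  means and from `n_units`.
* Zygosity tail comparisons are written as two `>=` tests so 1/10 against a
  0.9 threshold does not fall to floating-point subtraction.
* Constant-by-group expression data bypass `t.test` (p = 1 for equal
  means, p = 0 otherwise).
* Empty count tables run the whole pipeline and produce empty outputs with
  a warning rather than failing.

## Validation problem sizes

The package validates itself on simulations at the study design: 20 seeded
replicates of 967 individuals on a 60 Mb chromosome (≈ 6000 markers) for
causal-locus recovery and another 20 null replicates for false-positive
calibration; brute-force reference implementations check windowing and
region calling exactly on 100 random small instances. At these sizes the
full suite runs in well under a minute per batch.

## Known limitations

* Single recessive biallelic locus, two bulks; no multi-locus or
  quantitative-trait extension, no composite-interval or likelihood-based
  mapping.
* SNP sites only; indel-based mapping is out of scope.
* The null threshold ignores within-window linkage correlation
  (conservative) and assumes the 1:2:1 F2 genotype distribution; other
  population designs need a different null.
* The simulator draws marker alleles fully informative between parents;
  partially informative or mispolarised markers must be filtered upstream.
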