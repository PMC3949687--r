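---
title: "Panel diagnostics for Usher syndrome type 1: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel diagnostics for Usher syndrome type 1: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The diagnostic problem

Usher syndrome type 1 (USH1) is an autosomal recessive disorder combining
congenital profound hearing loss, absent vestibular function and
prepubertal-onset retinitis pigmentosa (RP). Nine Usher genes are screened
on a targeted amplicon panel — the five USH1 genes (*MYO7A*, *USH1C*,
*CDH23*, *PCDH15*, *USH1G*) plus the USH2/USH3 genes — and each patient's
variant calls must be turned into a genotype-level diagnosis: biallelic
(homozygous or compound heterozygous in one gene), digenic (one
heterozygous pathogenic variant in each of two genes, in trans),
monoallelic, or unsolved. Because many genes are sequenced at once, the
screen also surfaces *disease modifier* candidates: rare damaging missense
variants in a second USH1 gene carried on top of a complete biallelic
genotype, associated with earlier RP onset.

`usherpanel` implements this chain as composable stages: QC filtering,
annotation, diagnosis, cohort reporting, plus a cohort simulator that
provides planted ground truth.

## QC filtering and zygosity bands

Amplicon callers emit, per site, a read depth, a mean base quality and an
alternate-allele fraction. The filter retains a call iff

* depth ≥ 10,
* mean base quality ≥ 25 (Phred), and
* allele fraction within the heterozygous band [0.40, 0.60] or the
  homozygous band [0.80, 1.00].

All bounds are inclusive: the source protocol states closed ranges
(40–60%, 80–100%), and we read them literally; the bands are configurable
through `filter_thresholds()`. Fractions between 0.60 and 0.80 are
rejected rather than flagged as mosaic — the two bands are exhaustive for
accepted calls. Calls that arrive without measurements (e.g.
transcriptions of published tables, which are post-QC) pass the missing
predicate and must instead state their zygosity. Each removed call is
logged with the *first* failing predicate in the fixed order depth,
quality, zygosity band (then, at the annotation stage, consequence class
and rarity), so rejection logs are deterministic.

## Annotation: consequence, rarity, tier

Consequence classification works from HGVS strings alone; no genome
coordinates are stored, and variant identity is gene + normalized coding
change. The supported HGVS grammar is deliberately small — substitutions
(including intronic offsets), del/dup/ins with or without ranges — and
anything outside it raises an error naming the token rather than
guessing. Splice is restricted to the canonical ±2 dinucleotide
positions; frameshift covers `fs` protein changes and length changes not
divisible by three; a substitution whose protein change ends in a stop is
nonsense; identical flanking residues (synonymous) fall to `other`.

The rarity rule requires frequency < 1% in each of three sources —
1000 Genomes, the 5400-exome set, and an in-house control panel of 384
alleles — with unknown frequencies passing (novel variants are absent
from every catalog). The open question of allele vs genotype frequency
for the in-house panel is resolved as allele frequency.

Tiering is categorical: truncating and canonical splice variants are
`pathogenic`; missense variants are `probable_pathogenic` iff damaging
under the predictor rule, else `uncertain`; a missense variant is never
`pathogenic`. The damaging rule is a disjunction, SIFT ≤ 0.05 **or**
PolyPhen-2 ≥ 0.5. The source study reports scores but no cutoffs; the
disjunction with these conventional defaults reproduces every published
probable-pathogenic missense call, including two variants with tolerated
SIFT scores (0.09, 0.19) rescued by near-1 PolyPhen scores. Both
thresholds are configurable via `missense_policy()`.

## Diagnosis

The decision ladder, applied per patient to filtered, annotated variants:

1. **Biallelic** — a gene carries a homozygous causal variant
   (pathogenic/probable_pathogenic after rarity filtering), or two
   heterozygous ones whose phase is trans or undetermined. Compound
   heterozygotes without family data are called biallelic with
   `segregation_status = "assumed"`, matching how sporadic cases are
   reported in practice.
2. **Digenic** — exactly one causal heterozygous variant in each of two
   genes. When a pedigree exists the pair must segregate in trans; a cis
   pair is downgraded to independent monoallelic findings.
3. **Monoallelic** — a single reported heterozygous variant. A variant of
   uncertain tier (e.g. a missense change without predictor scores) still
   counts here: the published cohort lists such a patient as a mutation
   carrier.
4. **Unsolved** otherwise.

Phase is established by `check_segregation()`: trans iff exactly one
variant is carried by the mother and the other by the father; cis iff
both trace to one parent; undetermined when a parent is missing or both
parents carry a variant. Mendelian consistency of every genotyped family
member is checked alongside.

Modifier candidates attach to biallelic patients only: damaging missense
variants in a *different* USH1 gene. Candidacy uses predictor damage
only; rarity is reported but does not gate, because the published
modifier set includes a variant at 26% control frequency. The modifier
gene set defaults to the five USH1 genes and is configurable.

Patients left monoallelic or unsolved form the Sanger fallback list —
the set sent for full orthogonal re-sequencing, which in the source
cohort rescued two variants the platform cannot see (one outside the
amplicon design, one frameshift in a homopolymer tract).

## Cohort report and the onset comparison

`summarize_cohort()` reports diagnostic yield (patients with ≥ 1 reported
variant), per-gene biallelic frequencies over the whole cohort, patients
with two pathogenic mutations (biallelic + digenic), and — over the
distinct primary disease alleles — variant, novelty and
platform-detectability counts. Percentages round half away from zero to
one decimal (16/17 → 94.1, 7/17 → 41.2), the convention of clinical
yield tables; base R's `round()` would give banker's rounding.

The modifier-vs-onset comparison groups biallelic patients carrying a
modifier candidate against biallelic patients without one, excluding
unknown onsets. The source study names no test; Welch's unequal-variance
t (statistic and Welch–Satterthwaite degrees of freedom implemented from
the formulas, cross-checked against `stats::t.test` in the suite)
reproduces its printed p ≈ 0.007 on the published onsets {5, 5, 6} vs
{13, 6, 12, 8, 13, 10}, and an exact permutation test over all
`choose(9, 3) = 84` assignments ships alongside as the assumption-free
alternative (p = 4/84 ≈ 0.048 on the same data; the two agree within an
order of magnitude, which is what a 9-observation comparison supports).
The digenic patient is excluded from the comparison group by default —
the published case list for the test omits them — but
`include_digenic = TRUE` restores them.

## The simulator: a stated world

`simulate_cohort()` emulates the statistical structure of the study's
amplicon run so every stage has a ground-truth recovery test without any
external download:

* **Depth** ~ negative binomial with mean 314.2 (the study's mean target
  depth) and size 10. The study reports only a mean; amplicon depth is
  overdispersed in practice, and size 10 (CV ≈ 0.32) is typical of
  per-amplicon variation.
* **Allele fraction**: alternate reads ~ Binomial(depth, p), p = 0.5 for
  heterozygotes and 1 − ε for homozygotes, matching the het ≈ 40–60% /
  hom ≈ 80–100% bands the filter assumes. The per-base error ε defaults
  to 0.01, a typical semiconductor-sequencing substitution regime; the
  study states none.
* **Mean base quality** ~ N(30, 3) truncated at 1 — inside the
  minimum-25 regime.
* **Dropout**: each planted variant is lost with probability
  1 − 0.97 (outside the amplicon design, the study's exon coverage), and
  homopolymer-tract indels are additionally lost with probability 0.5 —
  the study's one such variant was missed (1 of 1), so the rate is a
  mid-range choice, not an estimate. Misses are modeled as absent calls,
  not miscalls, which is the platform's observed failure mode.
* **Diagnosis mix** defaults to the observed cohort: 8/17 biallelic,
  4/17 biallelic-with-modifier, 1/17 digenic, 3/17 monoallelic, 1/17
  unsolved; biallelic genotypes are homozygous with probability 0.75
  (9 of 12 observed). Planted variants are drawn from the packaged
  variant catalog.
* **Background**: ~Poisson(3) common polymorphisms per patient with
  population frequency ≥ 5%, benign predictor scores — exercising the
  rarity and predictor filters. A handful of common coding variants per
  small panel is realistic.
* **Pedigrees**: trios are emitted for compound-heterozygous and digenic
  patients with parental genotypes consistent with the planted trans
  phase.

Randomness is governed by one master seed; each patient uses a child
stream derived deterministically from it, so patient *i*'s data do not
depend on how many variants earlier patients drew, and cohorts are
byte-identical under a fixed seed.

What the simulator does **not** model: read-level data (no FASTQ,
flow-space signal or alignment), mapping artifacts, strand bias, sample
contamination, CNVs/large rearrangements, and miscalls (errors appear
only through allele-fraction noise and dropout). A green recovery test
therefore establishes that the *decision logic* is correct given calls
with this statistical structure — not that the upstream caller is.

## Numerical and degenerate-input choices

* Band bounds inclusive at both ends; ties at 0.40/0.60/0.80/1.00 are
  accepted.
* Depth draws of zero are floored to one read so a fraction is defined.
* Unknown database frequencies pass the rarity filter; unknown predictor
  scores make a missense variant non-damaging (uncertain), never
  damaging.
* When several genes could claim a biallelic call, genes are visited in
  variant-key order, making the diagnosis invariant to input row order.
* The permutation p-value uses a 1e-12 tolerance when comparing mean
  differences, avoiding float-equality misses at the observed statistic.

## Known limitations

* HGVS strings are structured labels; no projection onto genomic
  coordinates, so variants described against different transcripts of
  the same gene would not unify.
* The pathogenicity model is the study's categorical rule, not a scored
  framework (no ACMG-style evidence combination).
* Segregation uses genotypes at the two query variants only; it does not
  build full haplotypes, and a variant carried by both parents leaves
  phase undetermined rather than probabilistically resolved.
* The onset comparison treats onset as a single integer; no censoring or
  progression modeling.
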