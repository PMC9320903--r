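---
title: "trioscan: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trioscan: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented by `trioscan`: the model
behind each pipeline stage, the thresholds that matter and why they default
to the values they do, what the synthetic cohort generator emulates, the
numerical choices, and the known limitations. It states no empirical result
that the package's tests or acceptance script do not themselves compute.

## The analytical setting

The package targets cohorts of parent-offspring trios ascertained for
isolated congenital heart defects, jointly genotyped with a pool of
unrelated controls (typically patients sequenced for unrelated Mendelian
indications). Proband DNA may come from cardiac tissue, which makes
tissue-restricted somatic mosaicism detectable; parental DNA comes from
blood. Three genetic hypotheses are interrogated: somatic mosaic variants
in the developing heart, rare de novo or inherited protein-damaging
germline variants in cardiac-relevant genes, and distributed rare-variant
signal detectable only in aggregate (transmission distortion, case/control
burden).

## Thresholds

All cutoffs live in `pipeline_thresholds()` and can be overridden per run:

| parameter | default | role |
|---|---|---|
| `qual_snv` | 300 | site QUAL an SNV must *exceed* (strict `>`) |
| `qual_indel` | 1000 | site QUAL an indel must exceed (strict `>`) |
| `gq` | 30 | parental genotype quality for certifying de novo (inclusive `>=`) |
| `af_rare` | 0.001 | gnomAD AF cutoff defining "rare" (inclusive) |
| `cohort_freq` | 0.01 | combined case+control allele frequency guard for the AT |
| `cadd_damaging` | 25 | phred CADD making a missense variant damaging (inclusive) |
| `oe_upper` | 0.35 | constraint: oe confidence-interval upper bound (strict `<`) |
| `tpm` | 2 | embryonic cardiac expression threshold (inclusive) |
| `vaf_window` | [0.10, 0.40] | mosaic VAF window, closed at both ends |
| `parental_alt_reads` | 2 | max alt reads per parent at a mosaic site |
| `recurrence` | 2 | max case probands carrying an HQ variant |
| `gate` | 5 | minimum allele count for a TDT/AT unit to be tested |
| `fdr` | 0.05 | BH significance level |

Strict vs inclusive inequalities follow the wording of the printed
criteria ("QUAL > 300", "GQ ≥ 30", "CADD ≥ 25", "< 0.35", "two TPM" read
inclusively, VAF "0.10–0.40" read as a closed interval). Missing gnomAD AF
is treated as 0: a variant absent from the population database is rarer
than any listed variant.

## Trio classification

A site enters as one record per alternate allele (multi-allelic records
are decomposed at ingest; a sample's alt count for allele *k* counts only
*k* alleles, so decomposition conserves non-ref allele counts). Half-called
genotypes ("0/.") are conservatively treated as missing, and a missing
parental genotype can never certify a de novo event. De novo and inherited
classification are mutually exclusive by construction: the first requires
both parents hom-ref, the second at least one carrier parent. No GQ
condition is placed on the carrying parent of an inherited variant — the
quality concern specific to de novo calls is a false-negative parental
genotype, which GQ guards against.

Inframe indels are removed before any tally (high false-positive risk for
this variant type in exome data). Adjacent same-proband, same-category
calls at consecutive positions are merged into one multi-nucleotide
variant; the group carries the maximum CADD and minimum AF of its members
and counts once everywhere. Adjacency is strictly a position difference of
1 with no phasing check — the model carries no phase information, and
cis-co-occurrence within one proband at adjacent bases is overwhelmingly a
single mutational event.

Cohort report means are totals divided by the number of probands (empty
probands count); the dispersion is the sample standard deviation (n − 1)
by default, switchable to the population form. Percentages round half-up
to one decimal, matching the usual printed style.

## TDT

The parental variant set consists of heterozygous rare (AF ≤ 0.1%)
LOF/missense alleles in case parents at quality-passing sites in
embryonically expressed genes. Transmission is resolved at the allele
level under a presence rule: for a (variant, trio) group with *h*
heterozygous parents and child alt count *a*, b += min(a, h) and
c += h − min(a, h). A het child of two het parents contributes one
transmission and one non-transmission; a hom-alt child two transmissions.
When one parent is hom-alt and the other het, the child always carries the
allele and the het parent's allele counts as transmitted — a haplotype-
level resolution is impossible without phase, and this matches the
presence-in-callset rule. Missing child genotypes are uninformative.

Units with b + c < 5 are not tested. Two test statistics are provided:
the exact two-sided binomial test with success probability 0.5 (default —
appropriate at the small counts the gate admits, conservative due to
discreteness) and the classical χ² statistic (b − c)²/(b + c) (asymptotic;
reasonable from roughly 20 alleles). BH correction is applied within each
(level, class) family, mirroring separate LOF and missense testing;
a pooled family is available by argument. Genetic-map positions are not
used: single-marker TDT requires none.

## Burden association test

Relatedness is pruned first: the genetic relationship matrix uses the
standardized estimator G(j,k) = mean over variants of
(g_j − 2p)(g_k − 2p) / (2p(1 − p)) with sample allele frequencies and
per-variant mean imputation. Any sample with an off-diagonal relationship
larger than the smallest self-relationship on the diagonal is excluded
(both members of a pair). Note the strict inequality: a duplicate pair
whose shared self-relationship happens to be the cohort minimum would
evade the rule; this is a property of the rule as stated, not of the
implementation. Because sample allele frequencies center the genotypes,
off-diagonals of an unrelated cohort concentrate around −1/(n − 1), not 0.

PC1 is the leading principal component of the standardized common-variant
genotype matrix (MAF ≥ 0.05, missingness ≤ 10%, mean-imputed), sign-fixed
so the largest-magnitude loading is positive. This is a functional
stand-in for specialised PCA tools, which additionally apply outlier
removal and eigenvalue normalisations; only PC1 enters the model, as in
the published linear predictor.

Per sample and unit, VF = Σ VAC·(CADD/10) over selected variants
(LOF/missense, gnomAD AF ≤ 0.1%, combined cohort allele frequency ≤ 1%,
expressed gene). The cohort-frequency guard exists to remove recurrent
technical artifacts and common variants that escape a lifted-over
population database; "frequency" is read as allele frequency. The model
logit(p) = β₀ + β₁·VF + β₂·PC1 is fitted by maximum likelihood (IRLS,
relative tolerance 1e−8, 100 iterations) against the reduced model without
VF; the LRT statistic 2·Δloglik (clamped at 0) is referred to χ²₁.
Complete separation and non-convergence are flagged and the unit reported
untested with a reason, keeping the estimator exactly the stated model
rather than switching silently to a penalised fit. Units are gated at 5
alt alleles summed over cases and controls.

## The synthetic cohort

`simulate_cohort()` draws, under one seed (identical seeds give
byte-identical fixture bundles):

* **Gene universe & references**: genes on 22 chromosomes; a fraction
  (default 20%) below 2 TPM at every embryonic stage; a fraction (default
  20%) constrained (oe upper bound < 0.35); a CHD panel, a transcription
  factor panel and GO-style panels as random gene subsets.
* **Rare inherited variants**: allele frequencies from a truncated power
  law on [1e−6, 1e−3]. The exponent is α = 1 (log-uniform): steeper
  exome-realistic spectra (α ≈ 2) leave a scaled-down gene universe with
  essentially no carriers, flatter ones make "rare" variants common;
  log-uniform keeps both tails represented. Parents and controls are drawn
  from Hardy–Weinberg at these frequencies; children inherit by Mendelian
  transmission with per-gene probability τ (0.5 unless the gene is listed
  in `distortion_genes`).
* **De novo variants**: Poisson per proband (default 5, emulating the HQ
  de novo rate per trio exome), heterozygous in one proband with hom-ref,
  GQ-certifiable parents. Controls receive private variants at the same
  per-sample rate — every individual carries de novo variation, it is
  merely unidentifiable without parents; omitting this would bias the
  case/control burden comparison away from the null by construction.
  Deliberately sub-threshold injections (`n_bad_denovos`) cycle through
  low-QUAL SNV, low-QUAL indel, low parental GQ and recurrence > 2 failure
  modes, and `quality_noise` degrades a random fraction of calls.
* **Mosaic candidates**: a per-proband Poisson volume of candidate rows
  emulating a mosaic caller's output, with posteriors, true VAFs, binomial
  read counts at the configured depth (so observed VAF straddles the
  filter window on both sides), parental background reads, and a slice of
  decoys placed on cohort-recurrent germline sites. The truth table
  records the expected filter outcome judged on the *observed* quantities.
* **Population structure**: common SNPs under a Balding–Nichols model
  (default two blocks, Fst 0.05) for GRM/PCA; families share a block.
* **Burden effects**: for genes in `burden_genes`, father+child carrier
  pairs are injected with probability proportional to β₁ (Mendelian-
  consistent, case-restricted), so the case/control VF gap grows
  monotonically with the effect size. Strong effects can push carrier
  counts over the 1% cohort-frequency guard, which then removes those
  variants from the AT — the guard doing its job.
* **Related pairs**: duplicated control genotype vectors.

What the generator does **not** emulate: read-level data (no FASTQ/BAM;
QUAL/GQ/AD are drawn, not computed from reads), linkage disequilibrium
between sites, per-site VQSR behaviour, annotation errors, batch effects
between case and control sequencing protocols, and X-chromosome
inheritance. A green test therefore establishes the correctness of the
filtering and statistics on honestly structured genotype data, not robustness
to alignment or calling artifacts.

## Numerical and design notes

* BH step-up is implemented natively (q_(i) = min over j ≥ i of
  m·p_(j)/j, capped at 1), is permutation-invariant and NA-tolerant; the
  test oracle is a nested-loop enumeration of the definition.
* The exact binomial TDT p-value doubles the smaller tail (capped at 1),
  which for a symmetric null equals the usual minimum-likelihood
  two-sided construction.
* Variant identity is (chrom, pos, ref, alt) with 1-based coordinates.
* Gene identity is by symbol string; no alias resolution is attempted.
* The embryonic window is an ordered stage-label list
  (`EMBRYONIC_STAGES`, 4wpc…8wpc); datasets with intermediate labels can
  widen it by argument.
* Percentages round half-up (base R rounds half to even).

## Known limitations

* **Sparse LRT calibration.** The χ²₁ reference for the burden LRT is
  asymptotic. At the allele counts the ≥ 5 gate admits (5–20), the test
  is miscalibrated at conventional levels and the global-null probability
  that *some* unit in *some* BH family reaches q < 0.05 is approximately
  the per-family α times the number of testable families. The package's
  acceptance suite measures this honestly: component-level calibration
  (TDT type-I, LRT null uniformity at n = 400, confounding control)
  passes, while the end-to-end "no discovery in ≥ 95% of null runs"
  criterion does not — and cannot for any faithful implementation of
  glm + LRT + per-family BH. Exact or penalised small-sample tests would
  fix this but would no longer be the stated model.
* The TDT presence rule cannot distinguish which parent transmitted when
  one parent is hom-alt; allele-level resolution is documented above.
* The GRM/PCA stand-in omits outlier iteration; on strongly structured
  real cohorts PC1 may differ from specialised tools.
* No ACMG-style clinical classification, literature mining or liftover.
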