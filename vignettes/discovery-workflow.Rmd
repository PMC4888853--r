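---
title: "Pedigree-aware rare-variant discovery for a dominant trait: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware rare-variant discovery for a dominant trait: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segburden)
```

## The scientific problem

Self-limited delayed puberty (DP) — pubertal onset two or more standard
deviations later than the population mean, followed by otherwise normal
spontaneous puberty — clusters strongly in families, most often in an
autosomal-dominant pattern. Gene discovery in such cohorts proceeds by
exome sequencing of extended pedigrees followed by a cascade of filters
that whittle millions of called variants down to a handful of candidate
genes, and a per-gene rare-variant burden test that asks whether damaging
alleles in a gene are enriched in the cohort's probands relative to an
ethnically matched population reference. Because DP is the tail of a
normally distributed trait, causal alleles are expected to be *present* in
population panels at low frequency — absence from a database cannot be an
exclusion criterion, which is why the frequency comparison, not a
novelty requirement, carries the inference.

`segburden` implements that discovery machinery as reusable, tested code:
a synthetic-cohort generator that stands in for the (undeposited) raw
sequencing data, readers for the five on-disk formats, the filter cascade,
the burden test, and the auxological analytics used to phenotype carriers.

## The trait and simulation model

The generator (`simulateCohort()` with a `SimParam` configuration)
produces multi-generation pedigrees in which one planted causal gene
segregates dominantly:

* **Founders** draw background genotypes per variant as
  Binomial(2, MAF) at the reference-panel frequency; one first-generation
  founder per family carries exactly one heterozygous causal allele
  (dominant traits discovered this way are carried heterozygously).
* **Transmission** is Mendelian with fair allele choice: each child
  receives one allele from each parent with probability equal to half the
  parent's allele count, independently per variant.
* **Phenotype** is affected with probability `penetrance` for carriers of
  at least one causal allele, and otherwise with probability
  `max(phenocopyRate, baselineRate)`. Phenocopies matter: the filter
  cascade's segregation rule was designed around real families in which
  one affected member does not carry the family variant.
* **Unknowns**: a configurable fraction of youngest-generation members is
  masked to "unknown" phenotype, mimicking children too young to
  diagnose; the segregation filter must ignore them.
* **Cohort controls** are unrelated screening subjects selected for being
  unaffected, so their causal genotypes are drawn *conditional on the
  unaffected phenotype* (by rejection sampling). Under full penetrance
  this correctly empties the control pool of causal alleles; at
  intermediate penetrance it reproduces the depletion seen when a
  population-frequency variant appears in at most one of a few hundred
  unaffected controls.

All randomness flows from a single stream keyed by `seed`; the same
configuration always yields a byte-identical cohort and fixture files,
which the test suite asserts via checksums.

### Default study conditions

The defaults encode the discovery-cohort conditions rather than abstract
placeholders, chosen once and not tuned afterwards: 18 three-generation
families and 210 unrelated controls; penetrance 0.9 (segregation in the
real families was nearly perfect, with incomplete penetrance in one);
phenocopy rate 0.05 (about one affected non-carrier per cohort, kept
slightly high so the `n − 1` tolerance is exercised); baseline non-carrier
trait risk 0.025 (the trait is defined as the >2 SD tail, so ~2.3% of the
unselected population qualifies); causal panel MAF 0.01 (the published
discovery variants sit at 0.4–2.0% in reference panels); reference allele
number 6,000 per site (an ExAC-Finnish-scale panel). Background-variant
panel MAFs come from a rare/common mixture (70% uniform on 0.1–2%, 30%
uniform on 2–35%) so that the MAF filter has real work to do.

What the generator deliberately does **not** emulate: linkage
disequilibrium and haplotype structure, sequencing error and genotype
uncertainty beyond independent GQ/DP draws, relatedness between families,
population stratification, de-novo mutation, and recessive or X-linked
architectures. Passing tests therefore demonstrate the correctness of the
filtering and testing logic under the stated generative model, not the
calibration of the burden test against real exome data.

## The filter cascade

`runFilterCascade()` applies, in order: quality control → consequence →
MAF → segregation → multi-family → (optional gene allowlist) → control
screen → predictor consensus, recording an attrition trace. The first
three stages and the consensus are per-variant predicates, so any
permutation of them yields the same final set (a property the tests check
on random cohorts); the published order is kept for the trace's sake.

* **Quality control** retains a variant when at least one *carrier* call
  passes GQ ≥ 20 and DP ≥ 8. The original analysis names the threshold
  kinds but not values; these defaults are this package's choice, and
  calls with missing GQ/DP pass (no evidence against them).
* **Consequence** retains nonsense, missense, splice-site, structural,
  promoter and microRNA-deleterious classes, plus frameshift as loss of
  function; everything else (synonymous, deep intronic…) is removed.
* **MAF** requires frequency `< 0.025` in *every* reference panel in
  which the variant has been seen — the source rule lists its four
  databases conjunctively — and passes variants seen in none ("not
  seen").
* **Segregation** (per family): with `n` genotyped affected members, the
  variant must be carried by at least `n − 1` of them and by at most one
  unaffected member; unknown phenotypes and missing genotypes count in
  neither tally. A variant absent from the family trivially fails. The
  global rule is "segregates in at least one family", feeding the next
  stage; whether segregation must hold in *every* carrier family is not
  specified by the source analysis, and this interpretation is the more
  permissive one that the multi-family stage then disciplines.
* **Multi-family** keeps a variant when its gene has segregating variants
  in ≥ 2 distinct families — the same variant recurring, or different
  variants in the same gene.
* **Control screen** tolerates at most one carrier among the cohort
  controls; counting is on carriers, not alleles, because the trait
  alleles here are heterozygous. The screen is applied to the full
  control pool.
* **Predictor consensus** requires at least 3 of 5 tools (SIFT,
  PolyPhen-2 — "possibly damaging" counts —, LRT, MutationTaster, FATHMM)
  to call a missense variant damaging. Loss-of-function classes pass
  outright: missense predictors are undefined for truncating alleles.
* The **biological relevance** stage of the original pipeline (GWAS/LD
  prioritization) is reduced to an optional gene allowlist, off by
  default; its machinery is out of scope here.

## The burden test

`burdenTest()` compares, per gene, qualifying-allele counts in probands
(one per family — the familial correlation would otherwise inflate the
test) against a reference panel. A variant qualifies when its panel MAF
(AC/AN when available) is below 0.025 and SIFT calls it deleterious and
PolyPhen-2 at least possibly damaging.

The 2×2 table counts alleles: `a` = qualifying alternate alleles among
probands, `b = 2·probands − a`, `c` = summed panel AC over qualifying
variants, `d = AN − c` with AN the largest allele number among the gene's
qualifying variants (the simulated panel holds AN constant per site).
The source analysis says "prevalence" without fixing alleles versus
carriers; allele counting is the default because the comparison is to
population allele frequencies, and `countBy = "carrier"` switches the
convention.

The two-sided p-value is computed by full hypergeometric enumeration:
with margins fixed, every attainable table whose point probability does
not exceed that of the observed table (relative tolerance `1e-7` on the
comparison, guarding against floating-point inclusion errors) contributes
its probability. This is the point-probability convention of standard
exact-test implementations, and the suite checks equality with an
independent implementation to `1e-10` on a thousand random tables. A
table with an empty margin admits a single configuration and has p = 1.

P-values across genes are adjusted by the Benjamini–Hochberg step-up rule
(`bhAdjust()`, again checked against an independent implementation), genes
are ranked by adjusted then raw p then symbol (deterministic ties), and
significance is flagged at adjusted p < 0.025, the threshold of the
original analysis. `carrierPrevalence()` reports carrier percentages
rounded half-up to one decimal, the convention of the clinical summaries.

## Growth analytics

Records arrive already expressed in height SDS against a national
reference; converting raw heights is out of scope. The operations are:

* **Target height**: `TH = 0.791·x − 0.147` (girls), `0.886·x − 0.071`
  (boys), with `x` the mean parental height SDS.
* **Distance to target**: `TH − HSDS`, oriented so that a child shorter
  than the mid-parental expectation has a *positive* distance — the
  orientation that reproduces the published proband table, whose verbal
  definition alone is direction-ambiguous.
* **ΔHSDS**: `HSDS(8/9 y) − HSDS(4 y)`.
* **Normal limits** (from a national reference of > 70,000 children):
  ΔHSDS 1.21, distance to target 1.76 at 4 y, 1.72 at 8/9 y, 1.44 at
  adult height. Distance metrics are flagged on the *signed* value (only
  short-for-target is abnormal); ΔHSDS on its magnitude, since the
  screening limit is a magnitude bound. Values *at* the limit are
  abnormal ("< limit" is normal). Missing inputs yield a "not evaluable"
  `NA`, never an error.
* **Diagnosis**: probands are affected when Tanner stage 2 arrives
  strictly after 13.5 y (boys) / 13.0 y (girls); relatives when any one
  of growth-spurt takeoff (> 12.9 / 11.3 y), peak height velocity
  (> 14.8 / 12.8 y) or adult-height attainment (> 18 / 16 y) is late.

## Worked example

```{r example}
param <- SimParam(nFamilies = 8L, penetrance = 1, phenocopyRate = 0,
                  baselineRate = 0, nBackgroundGenes = 10L,
                  nCohortControls = 50L, seed = 2L)
cohort <- simulateCohort(param)
cohort

cascade <- runFilterCascade(cohort)
cascade$trace
cascade$candidateGenes

burden <- burdenTest(cohort, candidateKeys = cascade$candidates$variant_key)
head(burden, 3)
```

The planted gene survives every stage and ranks first. The published
proband growth table ships with the package and every derivable cell is
reproduced exactly:

```{r growth}
g <- probandGrowthData()
all(roundHalfUp(deltaHSDS(g$hsds_4, g$hsds_8or9), 1) ==
        g$delta_hsds_printed)
cls <- classifyGrowth(transform(g, sample_id = case))
cls$case[cls$dist_th_adult_outside]
```

## Numerical choices and degenerate inputs

* Half-up rounding (`roundHalfUp()`) is used wherever a value is compared
  to a printed one-decimal quantity; R's default half-to-even would
  disagree on exact halves.
* The Fisher enumeration uses `dhyper()` point masses; the `1e-7`
  relative tolerance on the "at least as extreme" comparison prevents
  ties from being dropped through floating-point noise.
* Empty inputs propagate as empty outputs: a header-only VCF parses to a
  zero-variant cohort, an empty cohort runs through the cascade with an
  all-zero trace, and a gene with no qualifying variants gets p = 1.
* Multi-allelic VCF sites are split into one biallelic record per ALT
  with counts recomputed per ALT, conserving each sample's total
  non-reference count at the site.
* PED files carry no proband column; the writer places each family's
  proband as the first affected member, and the reader designates the
  first affected member of a multi-member family as proband. Controls are
  singleton families.

## Problem sizes used by the checks

The bundled benchmarks run at desk scale, chosen as the smallest sizes at
which the properties are statistically meaningful: planted-gene recovery
uses 50 seeded cohorts of 20 families and 100 background genes (the
causal gene must survive the cascade and rank first in ≥ 95% of
replicates); null calibration uses 20 cohorts with no planted gene
(fraction of raw p < 0.05 stays at or below 0.05 plus two standard
errors — Fisher's test is conservative at these counts); the exact-test
and BH implementations are compared with independent reference
implementations on 1,000 random inputs each; and the segregation rule is
checked against brute-force evaluation over *all* carrier configurations
of pedigrees up to eight members.

## Known limitations

The headline numbers of the original study that depend on its raw
sequencing data — the post-QC variant count in the millions, per-variant
cohort frequencies, and the causal gene's adjusted burden p of 0.020
computed against ExAC-era counts — cannot be recomputed from what was
deposited, and this package does not pretend to: its claims are about the
correctness and power of the *procedure* under a transparent generative
model. The burden test implements the classic collapsing 2×2 design only
(no SKAT-style variance-component tests, covariates, or stratification
correction), the segregation model is strictly autosomal dominant, and
the growth module consumes SDS values rather than raw measurements.
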