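# segburden

Pedigree-aware rare-variant filtering, gene-based burden testing and
growth-pattern analytics for dominantly inherited self-limited delayed
puberty (DP) — the discovery workflow of family-based exome studies,
packaged as tested, reusable R code for statistical geneticists and
pediatric endocrinologists.

## What it implements

Family cohorts segregating DP in an autosomal-dominant pattern are
analyzed in three stages, all implemented here:

1. **Filter cascade.** Called variants are reduced to candidates by
   quality control (GQ ≥ 20, DP ≥ 8 on at least one carrier call),
   consequence-class prioritization, population minor allele frequency
   (MAF < 2.5 % in every reference panel where the variant has been
   seen), pedigree segregation — in a family with *n* genotyped affected
   members the variant must be carried by ≥ *n* − 1 of them and ≤ 1
   unaffected member — multi-family recurrence (the gene must harbour
   segregating variants in ≥ 2 families), a cohort-control screen (≤ 1
   carrier control), and a predictor consensus (≥ 3 of SIFT, PolyPhen-2,
   LRT, MutationTaster, FATHMM call the missense variant damaging).
2. **Burden test.** Per gene, qualifying alleles (panel MAF < 2.5 %,
   SIFT deleterious, PolyPhen-2 at least possibly damaging) are counted
   in probands (one per family) and compared with reference-panel allele
   counts in a 2×2 table:

   |            | qualifying | non-qualifying |
   |------------|-----------:|---------------:|
   | probands   | a          | 2·N − a        |
   | reference  | AC         | AN − AC        |

   The two-sided p-value is an exact Fisher test computed by full
   hypergeometric enumeration (point-probability rule), the gene set is
   adjusted by Benjamini–Hochberg, and genes are ranked with significance
   flagged at adjusted p < 0.025.
3. **Growth analytics.** Target height SDS from mean parental height SDS
   (0.791·x − 0.147 girls, 0.886·x − 0.071 boys), distance to target
   (TH − HSDS), ΔHSDS between ages 4 and 8/9, screening against published
   normal limits (1.21 / 1.76 / 1.72 / 1.44), and the DP diagnostic
   criteria for probands (Tanner 2 after 13.5 y boys / 13.0 y girls) and
   relatives (late takeoff, peak height velocity, or adult-height
   attainment).

Because the raw sequencing data of such studies are typically not
deposited, the package ships a first-class synthetic-cohort generator
(`simulateCohort()`): multi-generation pedigrees with Mendelian
transmission, one planted causal gene with configurable penetrance and
phenocopy rate, panel-frequency background variants, unaffected-screened
controls, annotations and growth records — deterministic under a seed and
written/read through standard formats (VCF v4.2, PED, TSV, CSV, JSON).

## Worked example

```r
library(segburden)

param <- SimParam(nFamilies = 8L, penetrance = 1, phenocopyRate = 0,
                  baselineRate = 0, nBackgroundGenes = 10L,
                  nCohortControls = 50L, seed = 2L)
cohort <- simulateCohort(param)
cohort
#> DPCohort: 122 samples (8 families, 50 controls), 54 variants in 11 genes
#>   phenotypes: 19 affected / 100 unaffected / 3 unknown; 8 probands
#>   simulated truth: causal gene GENE_CAUSAL, 4 causal variants, 20 carriers

cascade <- runFilterCascade(cohort)
cascade$trace
#>                 stage variants_in variants_out
#> 1     quality_control          54           45
#> 2         consequence          45           31
#> 3                 maf          31           22
#> 4         segregation          22            5
#> 5         multifamily           5            4
#> 6      control_screen           4            4
#> 7 predictor_consensus           4            4

burden <- burdenTest(cohort, candidateKeys = cascade$candidates$variant_key)
head(burden, 3)
#>          gene n_qualifying a  b   c    d odds_ratio    p_raw    p_adj rank significant
#> 1 GENE_CAUSAL            4 8  8 240 5760         24 7.21e-08 7.93e-07    1        TRUE
#> 2  GENE_BG001            0 0 16   0    0         NA 1.00e+00 1.00e+00    2       FALSE
#> 3  GENE_BG002            0 0 16   0    0         NA 1.00e+00 1.00e+00    3       FALSE
```

The attrition trace mirrors the discovery flowchart: 54 simulated
variants drop to the 4 planted causal variants, whose gene then ranks
first in the burden test with 8 of 16 proband alleles qualifying against
240 / 6,000 reference alleles (odds ratio 24, adjusted p ≈ 8 × 10⁻⁷).

The published proband growth table ships with the package; every
derivable cell is reproduced exactly, and applying the adult normal limit
flags exactly the two known outliers:

```r
g <- probandGrowthData()
cls <- classifyGrowth(transform(g, sample_id = case))
cls$case[cls$dist_th_adult_outside]
#> [1] "3.III.2" "6.II.1"
carrierPrevalence(c(lof = 5, missense = 29), 334)
#> [1] 10.2
```

Growth CSV schema (used by `readGrowthCSV()` / `simulateCohort()`):
columns `sample_id`, `sex` (M/F), and optionally `hsds_4`, `hsds_8or9`,
`adult_hsds`, `midparental_hsds`, `th_sds`, `age_onset`, `age_takeoff`,
`age_phv`, `age_adult_height` (ages in years; blanks allowed).

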