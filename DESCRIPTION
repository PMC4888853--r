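Package: segburden
Title: Pedigree-Aware Rare-Variant Filtering and Gene Burden Testing for
    Dominantly Inherited Delayed Puberty
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-usable implementation of a family-based rare-variant
    discovery analysis for an autosomal-dominant trait (self-limited
    delayed puberty): simulation of multi-generation pedigrees
    segregating a planted causal gene with incomplete penetrance and
    phenocopies; a variant filter cascade (genotype quality control,
    consequence class, population minor allele frequency, pedigree
    segregation, multi-family recurrence, control screening and a
    five-tool predictor consensus); per-gene rare-variant burden testing
    against a population reference panel by a two-sided Fisher's exact
    test computed by hypergeometric enumeration, with Benjamini-Hochberg
    false-discovery-rate adjustment and gene ranking; and auxological
    growth-pattern analytics (sex-specific target height from
    mid-parental height SDS, height-SDS trajectories, distance to target
    height, and diagnostic classification of delayed puberty in probands
    and relatives).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
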