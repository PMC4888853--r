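test_that("simulation is deterministic given config and seed", {
    p <- SimParam(nFamilies = 4L, nBackgroundGenes = 8L,
                  nCohortControls = 30L, seed = 99L)
    a <- simulateCohort(p)
    b <- simulateCohort(p)
    expect_identical(genotypes(a), genotypes(b))
    expect_identical(cohortSamples(a), cohortSamples(b))
    expect_identical(growthRecords(a), growthRecords(b))
    expect_identical(cohortTruth(a), cohortTruth(b))
    ## and fixture files are byte-identical
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    m1 <- writeFixtureSet(a, d1)
    m2 <- writeFixtureSet(b, d2)
    expect_identical(m1$md5, m2$md5)
})

test_that("degenerate trait model makes affected and carriers coincide", {
    p <- SimParam(nFamilies = 8L, penetrance = 1, phenocopyRate = 0,
                  baselineRate = 0, unknownFraction = 0,
                  nBackgroundGenes = 5L, nCohortControls = 30L, seed = 5L)
    co <- simulateCohort(p)
    smp <- cohortSamples(co)
    affected <- smp$sample_id[smp$phenotype == "affected"]
    expect_setequal(affected, cohortTruth(co)$carriers)
    expect_gt(length(affected), 0L)
})

test_that("carrier-affected concordance sits in the binomial 99% CI of the penetrance", {
    p <- SimParam(nFamilies = 20L, penetrance = 0.9, phenocopyRate = 0,
                  baselineRate = 0, unknownFraction = 0,
                  nBackgroundGenes = 5L, nCohortControls = 50L, seed = 17L)
    co <- simulateCohort(p)
    smp <- cohortSamples(co)
    carriers <- setdiff(cohortTruth(co)$carriers,
                        smp$sample_id[smp$is_control])
    k <- length(carriers)
    x <- sum(smp$phenotype[match(carriers, smp$sample_id)] == "affected")
    ci <- stats::qbinom(c(0.005, 0.995), k, 0.9)
    expect_gte(x, ci[1L])
    expect_lte(x, ci[2L])
})

test_that("transmission is Mendelian in every trio", {
    for (seed in c(1L, 23L, 77L)) {
        co <- simulateCohort(SimParam(nFamilies = 5L, nBackgroundGenes = 6L,
                                      nCohortControls = 10L, seed = seed))
        expect_identical(nrow(checkMendelian(co)), 0L)
    }
})

test_that("founder allele frequencies recover the panel MAF", {
    p <- SimParam(nFamilies = 15L, nBackgroundGenes = 20L,
                  backgroundVariantsPerGene = 3L, nCohortControls = 220L,
                  seed = 31L)
    co <- simulateCohort(p)
    smp <- cohortSamples(co)
    founders <- smp$sample_id[(is.na(smp$father_id) & is.na(smp$mother_id))]
    expect_gte(2L * length(founders), 500L)
    g <- genotypes(co)[, founders, drop = FALSE]
    panel <- panelAF(co)
    bg <- setdiff(rownames(g), cohortTruth(co)$causal_variants)
    m <- panel$maf_all[match(bg, panel$variant_key)]
    obs <- rowSums(g[bg, , drop = FALSE]) / (2L * length(founders))
    tol <- 4 * sqrt(m * (1 - m) / (2L * length(founders)))
    expect_true(all(abs(obs - m) <= tol))
})

test_that("unknown phenotypes are confined to the youngest generation", {
    co <- simulateCohort(SimParam(nFamilies = 10L, unknownFraction = 0.5,
                                  nBackgroundGenes = 3L,
                                  nCohortControls = 10L, seed = 8L))
    smp <- cohortSamples(co)
    unknown <- smp[smp$phenotype == "unknown", ]
    expect_gt(nrow(unknown), 0L)
    ## unknowns are never founders or controls (they are undiagnosable minors)
    expect_true(all(!unknown$is_control))
    expect_true(all(!is.na(unknown$father_id)))
})

test_that("invalid simulation configurations are rejected", {
    expect_error(SimParam(nFamilies = 0L), "nFamilies")
    expect_error(SimParam(nCausalVariants = 0L, nBackgroundGenes = 0L),
                 "at least one gene")
    expect_error(SimParam(causalPanelMAF = 0.03), "MAF filter")
    expect_error(SimParam(penetrance = 1.2), "\\[0, 1\\]")
    expect_error(SimParam(frobnicate = 1), "unknown")
})

test_that("truth record matches the genotype matrix", {
    co <- simulateCohort(SimParam(nFamilies = 6L, nBackgroundGenes = 4L,
                                  nCohortControls = 25L, seed = 12L))
    tr <- cohortTruth(co)
    g <- genotypes(co)
    carr <- colnames(g)[colSums(g[tr$causal_variants, , drop = FALSE] >= 1,
                                na.rm = TRUE) > 0]
    expect_setequal(carr, tr$carriers)
    ## causal variants are planted heterozygous in families
    smp <- cohortSamples(co)
    fam <- smp$sample_id[!smp$is_control]
    expect_true(all(g[tr$causal_variants, fam] <= 1L))
})
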