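test_that("QC keeps a variant when any carrier call passes GQ/DP", {
    counts <- c(A = 1L, B = 1L, C = 0L)
    co <- oneVariantCohort(counts, phenotype = c("affected", "affected",
                                                 "unaffected"),
                           gq = 45, dp = 30)
    ## both carriers good
    expect_true(qcFilter(co)[[1]])
    ## only carrier has GQ 10 < 20
    co2 <- oneVariantCohort(c(A = 1L, B = 0L), phenotype = "affected",
                            gq = c(10, 99), dp = 30)
    expect_false(qcFilter(co2)[[1]])
    ## mixed carriers GQ {10, 45}: retained through the good call
    co3 <- oneVariantCohort(c(A = 1L, B = 1L), phenotype = "affected",
                            gq = c(10, 45), dp = 30)
    expect_true(qcFilter(co3)[[1]])
    ## missing GQ/DP matrices: everything passes QC
    co4 <- oneVariantCohort(c(A = 1L), phenotype = "affected")
    expect_true(qcFilter(co4)[[1]])
    ## no carrier calls at all
    co5 <- oneVariantCohort(c(A = 0L, B = 0L), phenotype = "affected")
    expect_false(qcFilter(co5)[[1]])
})

test_that("consequence filter prioritizes the damaging classes", {
    co <- oneVariantCohort(c(A = 1L), phenotype = "affected",
                           consequence = "missense")
    expect_true(consequenceFilter(co)[[1]])
    co <- oneVariantCohort(c(A = 1L), phenotype = "affected",
                           consequence = "other")
    expect_false(consequenceFilter(co)[[1]])
    ## frameshift insertions are retained as loss of function
    co <- oneVariantCohort(c(A = 1L), phenotype = "affected",
                           consequence = "frameshift")
    expect_true(consequenceFilter(co)[[1]])
})

test_that("MAF filter requires < threshold in every panel where seen", {
    ## SISu 2.0% < 2.5%: retained
    co <- oneVariantCohort(c(A = 1L), phenotype = "affected", maf = 0.020)
    expect_true(mafFilter(co)[[1]])
    ## any panel at 3%: removed
    co2 <- oneVariantCohort(c(A = 1L), phenotype = "affected", maf = 0.020)
    co2@panel$maf_eur <- 0.03
    expect_false(mafFilter(co2)[[1]])
    ## not seen in any panel: retained
    co3 <- oneVariantCohort(c(A = 1L), phenotype = "affected")
    co3@panel$maf_all <- NA_real_
    expect_true(mafFilter(co3)[[1]])
    ## absent from the panel table entirely: retained
    co4 <- oneVariantCohort(c(A = 1L), phenotype = "affected")
    co4@panel <- co4@panel[0, ]
    expect_true(mafFilter(co4)[[1]])
})

test_that("published discovery-variant panel rows pass the MAF filter", {
    panel <- discoveryVariantPanel()
    ann <- discoveryVariantAnnotations()
    geno <- matrix(1L, nrow(ann), 1,
                   dimnames = list(ann$variant_key, "P1"))
    co <- makeCohort(geno, family_id = "FAM1", phenotype = "affected")
    co@annotations <- ann
    co@panel <- panel
    co@variants$gene <- ann$gene
    expect_true(all(mafFilter(co)))
})

test_that("segregation tolerates one affected non-carrier and one unaffected carrier", {
    ## n = 4 affected, 3 affected carriers + 1 unaffected carrier: retained
    counts <- c(A1 = 1L, A2 = 1L, A3 = 1L, A4 = 0L, U1 = 1L, U2 = 0L)
    co <- oneVariantCohort(counts, phenotype = c(rep("affected", 4),
                                                 rep("unaffected", 2)))
    d <- segregationFilter(co, "1:100:A:G")
    expect_true(d$segregates)
    expect_identical(d$n_affected, 4L)
    ## n = 3 affected carriers but 2 unaffected carriers: removed
    counts <- c(A1 = 1L, A2 = 1L, A3 = 1L, U1 = 1L, U2 = 1L)
    co <- oneVariantCohort(counts, phenotype = c(rep("affected", 3),
                                                 rep("unaffected", 2)))
    d <- segregationFilter(co, "1:100:A:G")
    expect_false(d$segregates)
    expect_identical(d$reason, "unaffected_carriers")
    ## absent variant: not segregating, reason "absent"
    co <- oneVariantCohort(c(A1 = 0L, A2 = 0L),
                           phenotype = c("affected", "affected"))
    d <- segregationFilter(co, "1:100:A:G")
    expect_false(d$segregates)
    expect_identical(d$reason, "absent")
    ## unknown phenotype and missing genotypes are excluded from counts
    counts <- c(A1 = 1L, A2 = NA, K1 = 1L, U1 = 0L)
    co <- oneVariantCohort(counts, phenotype = c("affected", "affected",
                                                 "unknown", "unaffected"))
    d <- segregationFilter(co, "1:100:A:G")
    expect_identical(d$n_affected, 1L)   # A2 not genotyped
    expect_true(d$segregates)
})

test_that("segregation decisions equal brute force over all carrier configurations", {
    for (layout in segregationLayouts) {
        m <- length(layout)
        ids <- sprintf("I%d", seq_len(m))
        for (mask in 0:(2^m - 1)) {
            counts <- as.integer(bitwAnd(bitwShiftR(mask, seq_len(m) - 1L),
                                         1L))
            names(counts) <- ids
            co <- oneVariantCohort(counts, phenotype = layout)
            got <- segregationFilter(co, "1:100:A:G")$segregates
            expect_identical(got, segregationOracle(counts, layout),
                             info = paste(paste(layout, collapse = ","),
                                          "mask", mask))
        }
    }
})

test_that("multi-family filter retains shared variants and shared genes", {
    geneOf <- c(v1 = "G1", v2 = "G1", v3 = "G2")
    ## same variant in two families
    segs <- list(v1 = c("A", "B"), v2 = character(0), v3 = "A")
    keep <- multifamilyFilter(segs, geneOf)
    expect_true(keep[["v1"]])
    expect_false(keep[["v2"]])   # does not itself segregate anywhere
    expect_false(keep[["v3"]])   # singleton variant in singleton gene
    ## different variants of the same gene in different families
    segs <- list(v1 = "A", v2 = "B", v3 = "A")
    keep <- multifamilyFilter(segs, geneOf)
    expect_true(keep[["v1"]])
    expect_true(keep[["v2"]])
    expect_false(keep[["v3"]])
})

test_that("control screen tolerates at most one carrier control", {
    mk <- function(ctrlCounts) {
        counts <- c(A1 = 1L, ctrlCounts)
        oneVariantCohort(counts,
                         phenotype = c("affected",
                                       rep("unaffected", length(ctrlCounts))),
                         family_id = c("FAM1", names(ctrlCounts)))
    }
    expect_true(controlScreen(mk(c(C1 = 0L, C2 = 0L)))[[1]])
    expect_true(controlScreen(mk(c(C1 = 1L, C2 = 0L)))[[1]])
    expect_false(controlScreen(mk(c(C1 = 1L, C2 = 1L)))[[1]])
})

test_that("predictor consensus counts the published discovery profiles", {
    ann <- discoveryVariantAnnotations()
    geno <- matrix(1L, nrow(ann), 1,
                   dimnames = list(ann$variant_key, "P1"))
    co <- makeCohort(geno, family_id = "FAM1", phenotype = "affected")
    co@annotations <- ann
    pc <- predictorConsensus(co)
    counts <- setNames(pc$damaging_tools, ann$aa_change)
    expect_identical(counts[["p.Arg156Leu"]], 4L)
    expect_identical(counts[["p.Glu161Lys"]], 4L)
    expect_identical(counts[["p.Glu2264Gly"]], 3L)
    expect_identical(counts[["p.Asp2614Asn"]], 4L)
    expect_true(all(pc$pass))
    ## all-tolerated missense fails
    co2 <- oneVariantCohort(c(A = 1L), phenotype = "affected",
                            sift = "T", polyphen = "B", lrt = "N",
                            mutation_taster = "N", fathmm = "T")
    pc2 <- predictorConsensus(co2)
    expect_identical(pc2$damaging_tools, 0L)
    expect_false(pc2$pass)
    ## loss-of-function classes pass regardless of the missense tools
    co3 <- oneVariantCohort(c(A = 1L), phenotype = "affected",
                            consequence = "frameshift",
                            sift = "T", polyphen = "B", lrt = "N",
                            mutation_taster = "N", fathmm = "T")
    expect_true(predictorConsensus(co3)$pass)
})

test_that("cascade trace is monotone and empty input yields empty output", {
    co <- simulateCohort(SimParam(nFamilies = 5L, nBackgroundGenes = 10L,
                                  nCohortControls = 40L, seed = 14L))
    res <- runFilterCascade(co)
    tr <- res$trace
    expect_true(all(tr$variants_out <= tr$variants_in))
    expect_identical(tr$variants_in[-1L], tr$variants_out[-nrow(tr)])
    expect_identical(tr$stage,
                     c("quality_control", "consequence", "maf",
                       "segregation", "multifamily", "control_screen",
                       "predictor_consensus"))
    ## final candidates are a subset of every stage's survivors
    expect_true(all(res$candidates$variant_key %in%
                    cohortVariants(co)$variant_key))
    ## empty cohort
    empty <- DPCohort(samples = cohortSamples(co)[0, ],
                      variants = cohortVariants(co)[0, ],
                      geno = genotypes(co)[0, 0, drop = FALSE])
    res0 <- runFilterCascade(empty)
    expect_identical(nrow(res0$candidates), 0L)
    expect_identical(res0$candidateGenes, character(0))
    expect_true(all(res0$trace$variants_in == 0L))
})

test_that("per-variant predicate stages commute", {
    co <- simulateCohort(SimParam(nFamilies = 4L, nBackgroundGenes = 15L,
                                  nCohortControls = 30L, seed = 27L))
    keys <- cohortVariants(co)$variant_key
    preds <- list(qc = qcFilter(co, keys),
                  cons = consequenceFilter(co, keys),
                  maf = mafFilter(co, keys),
                  consensus = setNames(predictorConsensus(co, keys)$pass,
                                       keys))
    base <- keys[Reduce(`&`, preds)]
    for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 2, 4))) {
        surv <- keys
        for (p in preds[perm]) surv <- surv[p[surv]]
        expect_setequal(surv, base)
    }
})

test_that("planted causal variants survive the cascade under full penetrance", {
    for (seed in c(2L, 9L, 41L)) {
        p <- SimParam(nFamilies = 8L, penetrance = 1, phenocopyRate = 0,
                      baselineRate = 0, nBackgroundGenes = 10L,
                      nCohortControls = 50L, seed = seed)
        co <- simulateCohort(p)
        res <- runFilterCascade(co)
        expect_true(cohortTruth(co)$causal_gene %in% res$candidateGenes)
    }
})

test_that("gene allowlist stage restricts candidates when enabled", {
    co <- simulateCohort(SimParam(nFamilies = 6L, penetrance = 1,
                                  phenocopyRate = 0, baselineRate = 0,
                                  nBackgroundGenes = 10L,
                                  nCohortControls = 30L, seed = 4L))
    withList <- runFilterCascade(co, FilterParam(geneAllowlist = "NOPE"))
    expect_identical(nrow(withList$candidates), 0L)
    expect_true("gene_allowlist" %in% withList$trace$stage)
})
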