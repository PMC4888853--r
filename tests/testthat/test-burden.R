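test_that("Fisher enumeration reproduces hand-enumerated and degenerate tables", {
    ## C(4,k) C(4,4-k) / C(8,4): 1,16,36,16,1 over 70; tables at least as
    ## extreme as (3,1,1,3) carry 1+16+16+1 = 34
    expect_equal(fisherExactTwoSided(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
    ## empty qualifying margin: a single attainable table
    expect_identical(fisherExactTwoSided(0, 5, 0, 9), 1)
    expect_identical(fisherExactTwoSided(0, 0, 0, 0), 1)
    ## invalid cells
    expect_error(fisherExactTwoSided(-1, 2, 3, 4), "non-negative")
    expect_error(fisherExactTwoSided(c(1, 2, 3)), "four")
})

test_that("Fisher p is symmetric under transposition and bounded", {
    set.seed(42)
    for (i in 1:50) {
        x <- rpois(4, 6)
        p1 <- fisherExactTwoSided(x[1], x[2], x[3], x[4])
        p2 <- fisherExactTwoSided(x[1], x[3], x[2], x[4])   # transpose
        expect_equal(p1, p2, tolerance = 1e-12)
        expect_gte(p1, 0); expect_lte(p1, 1)
    }
})

test_that("Fisher enumeration agrees with the reference implementation", {
    set.seed(7)
    for (i in 1:250) {
        x <- matrix(sample(0:25, 4, replace = TRUE), 2)
        p <- fisherExactTwoSided(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
        expect_equal(p, stats::fisher.test(x)$p.value, tolerance = 1e-10)
    }
})

test_that("BH step-up matches the formula and the reference implementation", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)                  # single p unchanged
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))  # constant list
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    set.seed(11)
    for (i in 1:250) {
        p <- runif(sample(1:40, 1))
        adj <- bhAdjust(p)
        expect_equal(adj, stats::p.adjust(p, method = "BH"),
                     tolerance = 1e-12)
        expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
        ## monotone: adjusted values preserve the p ordering
        expect_true(all(diff(adj[order(p)]) >= -1e-12))
    }
})

test_that("contingency tables count proband alleles against panel counts", {
    ## 10 probands, 4 heterozygous qualifying carriers: a = 4, b = 16
    ids <- sprintf("P%02d", 1:10)
    counts <- setNames(c(rep(1L, 4), rep(0L, 6)), ids)
    co <- oneVariantCohort(counts, phenotype = "affected",
                           family_id = sprintf("FAM%02d", 1:10),
                           ac = 30, an = 6000)
    q <- selectQualifying(co, "GENE_1")
    expect_identical(q, "1:100:A:G")
    tab <- buildContingencyTable(co, "GENE_1", q)
    expect_identical(tab, c(a = 4L, b = 16L, c = 30L, d = 5970L))
    ## no qualifying variants: a = 0
    tab0 <- buildContingencyTable(co, "GENE_1", character(0))
    expect_identical(tab0[["a"]], 0L)
    expect_identical(tab0[["b"]], 20L)
    ## carrier-based counting halves the reference
    tabC <- buildContingencyTable(co, "GENE_1", q,
                                  BurdenParam(countBy = "carrier"))
    expect_identical(tabC, c(a = 4L, b = 6L, c = 15L, d = 2985L))
})

test_that("qualifying selection enforces MAF and predictor requirements", {
    co <- oneVariantCohort(c(P1 = 1L), phenotype = "affected", maf = 0.01)
    expect_length(selectQualifying(co, "GENE_1"), 1L)
    co@annotations$sift <- "T"
    expect_length(selectQualifying(co, "GENE_1"), 0L)
    co@annotations$sift <- "D"
    co@annotations$polyphen <- "B"
    expect_length(selectQualifying(co, "GENE_1"), 0L)
    co@annotations$polyphen <- "P"    # possibly damaging still qualifies
    expect_length(selectQualifying(co, "GENE_1"), 1L)
    co@panel$maf_all <- 0.03
    expect_length(selectQualifying(co, "GENE_1"), 0L)
    co@panel$maf_all <- NA_real_      # not seen: qualifies
    expect_length(selectQualifying(co, "GENE_1"), 1L)
})

test_that("burden tables match a brute-force recount from raw genotypes", {
    co <- simulateCohort(SimParam(nFamilies = 10L, nBackgroundGenes = 12L,
                                  nCohortControls = 60L, seed = 33L))
    res <- burdenTest(co)
    smp <- cohortSamples(co)
    ann <- annotations(co)
    panel <- panelAF(co)
    probands <- smp$sample_id[smp$is_proband]
    g <- genotypes(co)
    for (i in sample(nrow(res), 5)) {
        gene <- res$gene[i]
        keys <- ann$variant_key[ann$gene == gene]
        hit <- match(keys, panel$variant_key)
        qual <- keys[ann$sift[match(keys, ann$variant_key)] == "D" &
                     ann$polyphen[match(keys, ann$variant_key)] %in%
                         c("D", "P") &
                     panel$ac[hit] / panel$an[hit] < 0.025]
        a <- sum(g[qual, probands, drop = FALSE])
        expect_identical(res$a[i], as.integer(a))
        expect_identical(res$b[i], 2L * length(probands) - as.integer(a))
        expect_identical(res$c[i],
                         as.integer(sum(panel$ac[match(qual,
                                                       panel$variant_key)])))
    }
})

test_that("gene ranking is deterministic with lexicographic tie-breaks", {
    res <- data.frame(gene = c("B", "A", "C"),
                      p_raw = c(0.5, 0.5, 0.01),
                      p_adj = c(0.75, 0.75, 0.03))
    r <- rankGenes(res)
    expect_identical(r$gene, c("C", "A", "B"))
    expect_identical(r$rank, 1:3)
    expect_identical(r$significant, c(FALSE, FALSE, FALSE))
    r2 <- rankGenes(res, significanceLevel = 0.05)
    expect_identical(r2$significant, c(TRUE, FALSE, FALSE))
})

test_that("burden p-values satisfy the empty-margin and adjustment invariants", {
    co <- simulateCohort(SimParam(nFamilies = 8L, nBackgroundGenes = 10L,
                                  nCohortControls = 40L, seed = 19L))
    res <- burdenTest(co)
    expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
    expect_true(all(res$p_adj >= res$p_raw - 1e-12))
    expect_true(all(res$p_raw[res$a == 0 & res$c == 0] == 1))
    expect_identical(sort(res$rank), seq_len(nrow(res)))
})

test_that("carrier prevalence uses half-up rounding to one decimal", {
    expect_identical(carrierPrevalence(c(lof = 5, missense = 29), 334), 10.2)
    expect_identical(carrierPrevalence(c(0, 0), 100), 0)
    expect_identical(carrierPrevalence(100, 100), 100)
    expect_identical(carrierPrevalence(1, 400), 0.3)   # 0.25 rounds up
    expect_error(carrierPrevalence(10, 5), "exceed")
})
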