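## In-code fixture builders shared by the unit and acceptance tests.

## Build a DPCohort from a genotype matrix (variants x samples) and a
## minimal sample description; annotation defaults describe a damaging
## missense variant, panel defaults a rare (0.1%) allele.
makeCohort <- function(geno, family_id, phenotype,
                       father = NA_character_, mother = NA_character_,
                       sex = "M", is_proband = NULL, is_control = NULL,
                       consequence = "missense", sift = "D", polyphen = "D",
                       lrt = "D", mutation_taster = "D", fathmm = "D",
                       maf = 0.001, ac = NULL, an = NULL,
                       gq = NULL, dp = NULL) {
    storage.mode(geno) <- "integer"
    keys <- rownames(geno)
    ids <- colnames(geno)
    n <- length(ids)
    rec <- function(x) rep_len(x, n)
    if (is.null(is_control)) is_control <- rec(family_id) == ids
    if (is.null(is_proband)) {
        is_proband <- rep(FALSE, n)
        for (fid in unique(family_id[!is_control])) {
            i <- which(rec(family_id) == fid & rec(phenotype) == "affected")
            if (length(i)) is_proband[i[1L]] <- TRUE
        }
    }
    smp <- data.frame(sample_id = ids, family_id = rec(family_id),
                      father_id = rec(father), mother_id = rec(mother),
                      sex = rec(sex), phenotype = rec(phenotype),
                      is_proband = is_proband, is_control = is_control,
                      stringsAsFactors = FALSE)
    parts <- strsplit(keys, ":", fixed = TRUE)
    variants <- data.frame(
        variant_key = keys,
        chrom = vapply(parts, `[`, "", 1L),
        pos = as.integer(vapply(parts, `[`, "", 2L)),
        ref = vapply(parts, `[`, "", 3L),
        alt = vapply(parts, `[`, "", 4L),
        gene = paste0("GENE_", vapply(parts, `[`, "", 1L)),
        stringsAsFactors = FALSE)
    v <- length(keys)
    vrec <- function(x) rep_len(x, v)
    ann <- data.frame(variant_key = keys, gene = variants$gene,
                      consequence = vrec(consequence), sift = vrec(sift),
                      polyphen = vrec(polyphen), lrt = vrec(lrt),
                      mutation_taster = vrec(mutation_taster),
                      fathmm = vrec(fathmm), phylop_class = "C", gerp = 5,
                      stringsAsFactors = FALSE)
    panel <- data.frame(variant_key = keys, maf_all = vrec(maf),
                        stringsAsFactors = FALSE)
    if (!is.null(ac)) { panel$ac <- vrec(ac); panel$an <- vrec(an) }
    mkmat <- function(x) if (is.null(x)) matrix(numeric(0), 0, 0) else {
        m <- matrix(rep_len(x, v * n), v, dimnames = dimnames(geno))
        m
    }
    DPCohort(samples = smp, variants = variants, geno = geno,
             gq = mkmat(gq), dp = mkmat(dp), annotations = ann,
             panel = panel)
}

## Single-variant cohort for one family plus optional controls; genotype
## given as a named vector of allele counts.
oneVariantCohort <- function(counts, phenotype, family_id = "FAM1", ...) {
    geno <- matrix(counts, nrow = 1,
                   dimnames = list("1:100:A:G", names(counts)))
    makeCohort(geno, family_id = family_id, phenotype = phenotype, ...)
}

## Brute-force evaluation of the printed segregation rule, written directly
## from its statement and independent of segregationFilter(): among
## genotyped members, with n = genotyped affected, retain iff the variant is
## present, carriers include >= n - 1 affected, and <= 1 unaffected.
segregationOracle <- function(counts, phenotype) {
    genotyped <- !is.na(counts)
    aff <- phenotype == "affected" & genotyped
    una <- phenotype == "unaffected" & genotyped
    n <- sum(aff)
    present <- any(counts[genotyped] >= 1)
    present && n >= 1 && sum(counts[aff] >= 1) >= n - 1 &&
        sum(counts[una] >= 1) <= 1
}

## Pedigree phenotype layouts (<= 8 members) used for exhaustive
## segregation checks; each entry is a phenotype vector.
segregationLayouts <- list(
    trio = c("affected", "unaffected", "affected"),
    quartet = c("affected", "affected", "unaffected", "unknown"),
    sextet = c("affected", "affected", "affected", "unaffected",
               "unaffected", "unknown"),
    octet = c("affected", "affected", "affected", "affected",
              "unaffected", "unaffected", "unknown", "unaffected"),
    all_affected = c("affected", "affected", "affected", "affected"),
    no_affected_informative = c("unaffected", "unaffected", "unknown"))

## The published study conditions for planted-gene recovery benchmarks.
recoveryParam <- function(seed, ...) {
    SimParam(nFamilies = 20L, penetrance = 1, phenocopyRate = 0,
             causalPanelMAF = 0.005, nBackgroundGenes = 100L,
             backgroundVariantsPerGene = 5L, seed = as.integer(seed), ...)
}
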