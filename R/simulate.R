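## synthetic cohort generator: pedigrees, Mendelian transmission with a
## planted dominant causal gene, annotations, panel frequencies, growth.

#' Simulate a complete cohort
#'
#' Generates a desk-scale cohort with the statistical structure the
#' downstream filtering and burden analysis assume: multi-generation
#' families segregating an autosomal-dominant trait driven by one planted
#' causal gene (one heterozygous causal founder allele per family),
#' background variants drawn at reference-panel frequencies, an unrelated
#' cohort-control pool, per-variant functional annotations, and per-sample
#' growth records. Phenotype is affected with probability `penetrance` for
#' carriers of at least one causal allele, otherwise with probability
#' `max(phenocopyRate, baselineRate)`. All randomness comes from a single
#' stream keyed by `seed`, so a given [SimParam-class] always yields an
#' identical cohort.
#'
#' @param param a [SimParam-class] configuration.
#' @return a [DPCohort-class] whose `cohortTruth()` names the causal gene,
#'   its variant keys and the carrier samples.
#' @export
#' @examples
#' cohort <- simulateCohort(SimParam(nFamilies = 3L, nBackgroundGenes = 5L,
#'                                   nCohortControls = 20L, seed = 42L))
#' cohort
simulateCohort <- function(param) {
    validObject(param)
    set.seed(param@seed)

    vt <- simVariantTable(param)
    ped <- simPedigrees(param)
    controls <- simControlSheet(param)
    smp <- rbind(ped, controls)

    geno <- simGenotypes(param, vt, smp)
    smp <- assignPhenotypes(param, vt, smp, geno)
    cc <- conditionControlsUnaffected(param, vt, smp, geno)
    smp <- cc$smp; geno <- cc$geno
    smp <- assignProbands(smp)
    growth <- simGrowth(param, smp)
    smp <- smp[c("sample_id", "family_id", "father_id", "mother_id", "sex",
                 "phenotype", "is_proband", "is_control")]

    nCall <- nrow(vt) * nrow(smp)
    gq <- matrix(pmax(0, pmin(99, round(stats::rnorm(nCall, 60, 15)))),
                 nrow(vt), dimnames = dimnames(geno))
    dp <- matrix(stats::rpois(nCall, 30), nrow(vt), dimnames = dimnames(geno))

    ann <- simAnnotations(param, vt)
    panel <- simPanel(param, vt)

    causalKeys <- vt$variant_key[vt$gene == param@causalGene]
    carriers <- if (length(causalKeys))
        colnames(geno)[colSums(geno[causalKeys, , drop = FALSE] >= 1,
                               na.rm = TRUE) > 0] else character(0)
    truth <- list(causal_gene = if (param@nCausalVariants > 0L)
                      param@causalGene else NA_character_,
                  causal_variants = causalKeys, carriers = carriers)

    DPCohort(samples = smp,
             variants = vt[c("variant_key", "chrom", "pos", "ref", "alt",
                             "gene")],
             geno = geno, gq = gq, dp = dp,
             annotations = ann, panel = panel, growth = growth, truth = truth)
}

## variant table -------------------------------------------------------------

simVariantTable <- function(param) {
    bases <- c("A", "C", "G", "T")
    rows <- list()
    if (param@nCausalVariants > 0L) {
        n <- param@nCausalVariants
        ref <- sample(bases, n, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
        rows[[1L]] <- data.frame(
            chrom = "3", pos = 1e6L + seq_len(n) * 97L, ref = ref, alt = alt,
            gene = param@causalGene, stringsAsFactors = FALSE)
    }
    if (param@nBackgroundGenes > 0L && param@backgroundVariantsPerGene > 0L) {
        for (gi in seq_len(param@nBackgroundGenes)) {
            n <- param@backgroundVariantsPerGene
            ref <- sample(bases, n, replace = TRUE)
            alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = as.character((gi - 1L) %% 22L + 1L),
                pos = 2e6L + gi * 100000L + seq_len(n) * 53L,
                ref = ref, alt = alt,
                gene = sprintf("GENE_BG%03d", gi), stringsAsFactors = FALSE)
        }
    }
    vt <- do.call(rbind, rows)
    vt$variant_key <- variantKey(vt$chrom, vt$pos, vt$ref, vt$alt)
    ## background panel MAFs: rare/common mixture (kept internally for the
    ## founder draws; exported through the panel table)
    isCausal <- vt$gene == param@causalGene
    maf <- numeric(nrow(vt))
    maf[isCausal] <- param@causalPanelMAF
    nb <- sum(!isCausal)
    if (nb) {
        rare <- stats::runif(nb) < param@rareWeight
        m <- numeric(nb)
        m[rare] <- stats::runif(sum(rare), param@rareRange[1], param@rareRange[2])
        m[!rare] <- stats::runif(sum(!rare), param@commonRange[1],
                                 param@commonRange[2])
        maf[!isCausal] <- m
    }
    vt$panel_maf <- maf
    vt[c("variant_key", "chrom", "pos", "ref", "alt", "gene", "panel_maf")]
}

## pedigree structure --------------------------------------------------------

simPedigrees <- function(param) {
    fams <- list()
    for (fi in seq_len(param@nFamilies)) {
        fid <- sprintf("FAM%02d", fi)
        mid <- function(k) sprintf("%s_%02d", fid, k)
        k <- 0L
        nextId <- function() { k <<- k + 1L; mid(k) }
        rows <- list()
        addRow <- function(id, fa, mo, sex, gen, founder) {
            rows[[length(rows) + 1L]] <<- data.frame(
                sample_id = id, family_id = fid,
                father_id = fa %||% NA_character_,
                mother_id = mo %||% NA_character_,
                sex = sex, generation = gen, is_founder = founder,
                stringsAsFactors = FALSE)
        }
        f1 <- nextId(); addRow(f1, NULL, NULL, "M", 1L, TRUE)
        f2 <- nextId(); addRow(f2, NULL, NULL, "F", 1L, TRUE)
        nKids <- 1L + stats::rpois(1L, max(0, param@meanChildren - 1))
        gen2 <- character(0)
        for (ci in seq_len(nKids)) {
            id <- nextId()
            addRow(id, f1, f2, sample(SEX_LEVELS, 1L), 2L, FALSE)
            gen2 <- c(gen2, id)
        }
        if (param@familyGenerations >= 3L) {
            for (id in gen2) {
                if (stats::runif(1) >= param@marryProb) next
                childSex <- rows[[match(id, vapply(rows, `[[`, "",
                                                   "sample_id"))]]$sex
                sp <- nextId()
                addRow(sp, NULL, NULL, if (childSex == "M") "F" else "M",
                       2L, TRUE)
                fa <- if (childSex == "M") id else sp
                mo <- if (childSex == "M") sp else id
                nG3 <- 1L + stats::rpois(1L, max(0, param@meanChildren - 1))
                for (gi in seq_len(nG3))
                    addRow(nextId(), fa, mo, sample(SEX_LEVELS, 1L), 3L, FALSE)
            }
        }
        fams[[fi]] <- do.call(rbind, rows)
    }
    do.call(rbind, fams)
}

simControlSheet <- function(param) {
    n <- param@nCohortControls
    if (n == 0L)
        return(data.frame(sample_id = character(0), family_id = character(0),
                          father_id = character(0), mother_id = character(0),
                          sex = character(0), generation = integer(0),
                          is_founder = logical(0)))
    ids <- sprintf("CTRL%03d", seq_len(n))
    data.frame(sample_id = ids, family_id = ids,
               father_id = NA_character_, mother_id = NA_character_,
               sex = sample(SEX_LEVELS, n, replace = TRUE),
               generation = 1L, is_founder = TRUE, stringsAsFactors = FALSE)
}

## genotypes -----------------------------------------------------------------

simGenotypes <- function(param, vt, smp) {
    V <- nrow(vt)
    geno <- matrix(NA_integer_, V, nrow(smp),
                   dimnames = list(vt$variant_key, smp$sample_id))
    causalIdx <- which(vt$gene == param@causalGene)
    ## founders (family founders + controls): binomial draws at panel MAF,
    ## except causal variants which are absent unless explicitly planted
    founders <- smp$sample_id[smp$is_founder]
    for (id in founders) {
        g <- stats::rbinom(V, 2L, vt$panel_maf)
        g[causalIdx] <- 0L
        geno[, id] <- g
    }
    ## controls (singleton families) carry causal alleles at panel frequency
    ctrl <- smp$sample_id[smp$family_id == smp$sample_id]
    for (id in ctrl)
        geno[causalIdx, id] <- stats::rbinom(length(causalIdx), 2L,
                                             param@causalPanelMAF)
    ## plant exactly one heterozygous causal allele per family in one founder
    if (length(causalIdx)) {
        famIds <- unique(smp$family_id[smp$family_id != smp$sample_id])
        for (fi in seq_along(famIds)) {
            vck <- causalIdx[(fi - 1L) %% length(causalIdx) + 1L]
            g1 <- smp$sample_id[smp$family_id == famIds[fi] &
                                smp$generation == 1L & smp$is_founder]
            carrier <- g1[sample.int(length(g1), 1L)]
            geno[vck, carrier] <- 1L
        }
    }
    ## Mendelian transmission down the generations (parents precede children
    ## in generation order, so fill by increasing generation)
    fams <- smp[smp$family_id != smp$sample_id, ]
    for (gen in sort(unique(fams$generation[!fams$is_founder]))) {
        kids <- fams[!fams$is_founder & fams$generation == gen, ]
        for (i in seq_len(nrow(kids))) {
            fa <- geno[, kids$father_id[i]]
            mo <- geno[, kids$mother_id[i]]
            geno[, kids$sample_id[i]] <-
                stats::rbinom(V, 1L, fa / 2) + stats::rbinom(V, 1L, mo / 2)
        }
    }
    geno
}

assignPhenotypes <- function(param, vt, smp, geno) {
    causalKeys <- vt$variant_key[vt$gene == param@causalGene]
    carrier <- if (length(causalKeys))
        colSums(geno[causalKeys, smp$sample_id, drop = FALSE] >= 1,
                na.rm = TRUE) > 0 else rep(FALSE, nrow(smp))
    pAff <- ifelse(carrier, param@penetrance,
                   max(param@phenocopyRate, param@baselineRate))
    affected <- stats::runif(nrow(smp)) < pAff
    smp$phenotype <- ifelse(affected, "affected", "unaffected")
    smp$is_control <- smp$family_id == smp$sample_id
    ## mask a fraction of youngest-generation family members as unknown
    ## (too young to diagnose) to exercise the segregation filter
    young <- !smp$is_control & smp$generation == max(smp$generation) &
        !smp$is_founder
    mask <- young & stats::runif(nrow(smp)) < param@unknownFraction
    smp$phenotype[mask] <- "unknown"
    smp
}

## Cohort controls are screening subjects selected for being unaffected, so
## their genotype/phenotype pair is drawn conditional on "unaffected":
## affected draws are rejected and the causal genotypes redrawn. Under full
## penetrance this correctly depletes the control pool of causal alleles.
conditionControlsUnaffected <- function(param, vt, smp, geno) {
    causalIdx <- which(vt$gene == param@causalGene)
    redo <- which(smp$is_control & smp$phenotype == "affected")
    baseRisk <- max(param@phenocopyRate, param@baselineRate)
    for (i in redo) {
        if (!length(causalIdx)) break
        id <- smp$sample_id[i]
        repeat {
            g <- stats::rbinom(length(causalIdx), 2L, param@causalPanelMAF)
            pAff <- if (any(g >= 1L)) param@penetrance else baseRisk
            if (stats::runif(1) >= pAff) {
                geno[causalIdx, id] <- g
                break
            }
        }
    }
    smp$phenotype[smp$is_control] <- "unaffected"
    list(smp = smp, geno = geno)
}

assignProbands <- function(smp) {
    smp$is_proband <- FALSE
    for (fid in unique(smp$family_id[!smp$is_control])) {
        idx <- which(smp$family_id == fid & smp$phenotype == "affected")
        if (!length(idx)) next
        ## ascertainment is through a clinic-referred child: pick the
        ## youngest-generation affected member (first in order on ties)
        pick <- idx[order(-smp$generation[idx])][1L]
        smp$is_proband[pick] <- TRUE
    }
    smp
}

## annotations and panel -----------------------------------------------------

simAnnotations <- function(param, vt) {
    n <- nrow(vt)
    isCausal <- vt$gene == param@causalGene
    consequence <- character(n)
    ## causal variants mimic the discovery profile: heterozygous missense
    ## calls flagged damaging by SIFT, PolyPhen and LRT (>= 3/5 by design)
    consequence[isCausal] <- "missense"
    nb <- sum(!isCausal)
    if (nb)
        consequence[!isCausal] <- sample(
            CONSEQUENCE_LEVELS, nb, replace = TRUE,
            prob = c(0.02, 0.45, 0.04, 0.02, 0.05, 0.02, 0.02, 0.38))
    draw <- function(codes, pDamaging) {
        out <- sample(codes[-1L], n, replace = TRUE)
        dmg <- stats::runif(n) < pDamaging
        out[dmg] <- codes[1L]
        out
    }
    ann <- data.frame(
        variant_key = vt$variant_key, gene = vt$gene,
        consequence = consequence,
        sift = draw(c("D", "T"), 0.25),
        polyphen = ifelse(stats::runif(n) < 0.2, "D",
                          ifelse(stats::runif(n) < 0.15, "P", "B")),
        lrt = draw(c("D", "N", "U"), 0.2),
        mutation_taster = draw(c("D", "N"), 0.3),
        fathmm = draw(c("D", "T"), 0.2),
        phylop_class = draw(c("C", "N"), 0.5),
        gerp = round(stats::runif(n, -2, 6), 2),
        stringsAsFactors = FALSE)
    ann$sift[isCausal] <- "D"
    ann$polyphen[isCausal] <- "D"
    ann$lrt[isCausal] <- "D"
    ann$phylop_class[isCausal] <- "C"
    ann$gerp[isCausal] <- round(stats::runif(sum(isCausal), 4, 6), 2)
    ann
}

simPanel <- function(param, vt) {
    an <- param@referenceAN
    data.frame(
        variant_key = vt$variant_key,
        maf_fin = vt$panel_maf,
        maf_all = vt$panel_maf,
        ac = as.integer(round(an * vt$panel_maf)),
        an = an,
        stringsAsFactors = FALSE)
}

## growth records ------------------------------------------------------------

## Milestone-age means (years): affected values straddle the diagnostic
## cut-offs from above, unaffected from below.
GROWTH_MILESTONES <- list(
    M = list(aff = c(onset = 15.5, takeoff = 15.5, phv = 16.3, adult = 18.8),
             una = c(onset = 12.0, takeoff = 11.5, phv = 13.5, adult = 17.2)),
    F = list(aff = c(onset = 14.0, takeoff = 13.5, phv = 14.5, adult = 16.8),
             una = c(onset = 11.0, takeoff = 10.5, phv = 12.0, adult = 15.2)))

simGrowth <- function(param, smp) {
    n <- nrow(smp)
    if (!n)
        return(data.frame(sample_id = character(0), sex = character(0),
                          hsds_4 = numeric(0), hsds_8or9 = numeric(0),
                          adult_hsds = numeric(0),
                          midparental_hsds = numeric(0),
                          age_onset = numeric(0), age_takeoff = numeric(0),
                          age_phv = numeric(0), age_adult_height = numeric(0)))
    aff <- smp$phenotype == "affected"
    mp <- round(stats::rnorm(n, 0, 0.7), 1)
    h4 <- round(stats::rnorm(n, ifelse(aff, -0.7, 0), 1), 1)
    h89 <- round(h4 + ifelse(aff, param@affectedHsdsShift, 0) +
                 stats::rnorm(n, 0, 0.3), 1)
    adult <- round(stats::rnorm(n, ifelse(aff, -0.5, 0), 0.8), 1)
    ms <- function(which) {
        m <- vapply(seq_len(n), function(i) {
            GROWTH_MILESTONES[[smp$sex[i]]][[if (aff[i]) "aff" else "una"]][which]
        }, 0)
        round(m + stats::rnorm(n, 0, 0.5), 2)
    }
    data.frame(sample_id = smp$sample_id, sex = smp$sex,
               hsds_4 = h4, hsds_8or9 = h89, adult_hsds = adult,
               midparental_hsds = mp,
               age_onset = ms("onset"), age_takeoff = ms("takeoff"),
               age_phv = ms("phv"), age_adult_height = ms("adult"),
               stringsAsFactors = FALSE)
}
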