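#' @import methods
NULL

## ---------------------------------------------------------------------------
## SimParam: configuration of the synthetic-cohort generator
## ---------------------------------------------------------------------------

#' Synthetic-cohort simulation parameters
#'
#' `SimParam` holds every knob of the cohort generator: the pedigree
#' structure, the planted causal gene, panel allele frequencies of causal and
#' background variants, the trait model (penetrance, phenocopy rate,
#' population baseline prevalence), and the growth-record model. The defaults
#' describe the study conditions the downstream analysis was designed for: an
#' exome-sequenced discovery cohort of 18 extended Finnish-style pedigrees
#' segregating an autosomal-dominant delayed-puberty trait, with a pool of
#' 210 unrelated cohort controls.
#'
#' @slot nFamilies number of multi-generation families.
#' @slot familyGenerations generations per family (2 or 3).
#' @slot meanChildren mean number of children per couple (>= 1).
#' @slot marryProb probability that a second-generation child founds a
#'   third-generation nuclear family.
#' @slot causalGene symbol of the planted causal gene.
#' @slot nCausalVariants number of distinct causal variants; families are
#'   assigned causal variants round-robin, so several families can share a
#'   variant (the multi-family filter relies on this).
#' @slot causalPanelMAF reference-panel minor allele frequency of each causal
#'   variant; must be below 0.025 so planted variants survive the MAF filter
#'   by construction.
#' @slot penetrance probability that a causal-allele carrier is affected.
#' @slot phenocopyRate probability that a non-carrier is affected for
#'   non-genetic reasons (lean phenocopies and the like).
#' @slot baselineRate population prevalence of the trait among non-carriers;
#'   the effective non-carrier risk is `max(phenocopyRate, baselineRate)`.
#' @slot unknownFraction fraction of youngest-generation members whose
#'   phenotype is masked to "unknown" (too young to diagnose).
#' @slot nBackgroundGenes number of non-causal genes.
#' @slot backgroundVariantsPerGene variants simulated per background gene.
#' @slot rareWeight,rareRange,commonRange background panel MAFs are drawn
#'   from a two-component mixture: with probability `rareWeight` uniform on
#'   `rareRange`, otherwise uniform on `commonRange`.
#' @slot nCohortControls number of unrelated cohort controls.
#' @slot referenceAN reference-panel allele number (total alleles genotyped
#'   per site, ExAC-like) used to derive AC = round(AN * MAF).
#' @slot affectedHsdsShift additive shift of height SDS between ages 4 and
#'   8/9 for affected individuals (the prepubertal ``drift'' of the trait).
#' @slot seed integer seed; the whole cohort is generated from one stream.
#' @export
setClass("SimParam", representation(
    nFamilies = "integer",
    familyGenerations = "integer",
    meanChildren = "numeric",
    marryProb = "numeric",
    causalGene = "character",
    nCausalVariants = "integer",
    causalPanelMAF = "numeric",
    penetrance = "numeric",
    phenocopyRate = "numeric",
    baselineRate = "numeric",
    unknownFraction = "numeric",
    nBackgroundGenes = "integer",
    backgroundVariantsPerGene = "integer",
    rareWeight = "numeric",
    rareRange = "numeric",
    commonRange = "numeric",
    nCohortControls = "integer",
    referenceAN = "integer",
    affectedHsdsShift = "numeric",
    seed = "integer"
))

setValidity("SimParam", function(object) {
    msg <- character(0)
    if (object@nFamilies < 1L)
        msg <- c(msg, "nFamilies must be >= 1")
    if (!(object@familyGenerations %in% 2:3))
        msg <- c(msg, "familyGenerations must be 2 or 3")
    if (object@meanChildren < 1)
        msg <- c(msg, "meanChildren must be >= 1")
    if (object@nCausalVariants < 0L || object@nBackgroundGenes < 0L ||
        object@backgroundVariantsPerGene < 0L || object@nCohortControls < 0L)
        msg <- c(msg, "counts must be >= 0")
    if (object@nCausalVariants + object@nBackgroundGenes *
        object@backgroundVariantsPerGene < 1L)
        msg <- c(msg, "cohort must contain at least one gene with variants")
    fr <- c(penetrance = object@penetrance, phenocopy = object@phenocopyRate,
            baseline = object@baselineRate, unknown = object@unknownFraction,
            marry = object@marryProb, rareWeight = object@rareWeight)
    if (any(fr < 0 | fr > 1))
        msg <- c(msg, "all rate/fraction parameters must lie in [0, 1]")
    if (object@nCausalVariants > 0L &&
        !(object@causalPanelMAF > 0 && object@causalPanelMAF < 0.025))
        msg <- c(msg, "causalPanelMAF must lie in (0, 0.025) so planted variants pass the MAF filter")
    if (length(object@rareRange) != 2L || length(object@commonRange) != 2L ||
        any(c(object@rareRange, object@commonRange) < 0) ||
        any(c(object@rareRange, object@commonRange) > 0.5))
        msg <- c(msg, "MAF mixture ranges must be length-2 within [0, 0.5]")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimParam-class Constructor with study-condition defaults.
#' @param ... slot values overriding the defaults (see slots).
#' @return a validated `SimParam` object.
#' @export
#' @examples
#' SimParam(nFamilies = 4L, nBackgroundGenes = 10L, seed = 7L)
SimParam <- function(...) {
    args <- list(...)
    defaults <- list(
        nFamilies = 18L, familyGenerations = 3L, meanChildren = 2.5,
        marryProb = 0.7, causalGene = "GENE_CAUSAL", nCausalVariants = 4L,
        causalPanelMAF = 0.01, penetrance = 0.9, phenocopyRate = 0.05,
        baselineRate = 0.025, unknownFraction = 0.1,
        nBackgroundGenes = 50L, backgroundVariantsPerGene = 5L,
        rareWeight = 0.7, rareRange = c(0.001, 0.02),
        commonRange = c(0.02, 0.35), nCohortControls = 210L,
        referenceAN = 6000L, affectedHsdsShift = -0.3, seed = 1L
    )
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
        stopf("unknown SimParam field(s): %s", paste(unknown, collapse = ", "))
    vals <- modifyList(defaults, args)
    for (f in c("nFamilies", "familyGenerations", "nCausalVariants",
                "nBackgroundGenes", "backgroundVariantsPerGene",
                "nCohortControls", "referenceAN", "seed"))
        vals[[f]] <- as.integer(vals[[f]])
    do.call(new, c(list(Class = "SimParam"), vals))
}

## ---------------------------------------------------------------------------
## FilterParam: the filter-cascade configuration
## ---------------------------------------------------------------------------

#' Filter-cascade parameters
#'
#' Thresholds for the candidate-variant cascade: genotype quality control,
#' consequence-class prioritization, population MAF, pedigree segregation,
#' multi-family recurrence, cohort-control screening, and the five-tool
#' predictor consensus. The numeric QC thresholds (GQ 20, DP 8) are this
#' package's defaults; the remaining defaults implement the published rules
#' (MAF < 2.5\%, carriers in >= n-1 affected and <= 1 unaffected family
#' members, variants or genes recurring in >= 2 families, <= 1 cohort-control
#' carrier, >= 3 of 5 tools calling a missense variant damaging).
#'
#' @slot minGQ minimum genotype quality (phred) for a carrier call to count
#'   toward QC survival; missing GQ passes.
#' @slot minDepth minimum read depth for a carrier call; missing DP passes.
#' @slot allowedConsequences consequence classes retained by the functional
#'   annotation filter.
#' @slot mafThreshold MAF ceiling; a variant survives only if its frequency
#'   is below this in every reference panel where it has been seen.
#' @slot maxUnaffectedCarriers maximum unaffected carriers tolerated within
#'   a family for the variant still to segregate there.
#' @slot multifamilyMinFamilies minimum number of distinct families in which
#'   a gene must harbour segregating variants.
#' @slot maxControlCarriers maximum carriers among cohort controls.
#' @slot consensusMinTools minimum number of the five prediction tools that
#'   must call a missense variant damaging.
#' @slot geneAllowlist optional gene allowlist standing in for the
#'   biological-relevance stage; empty means the stage is skipped.
#' @export
setClass("FilterParam", representation(
    minGQ = "numeric", minDepth = "numeric",
    allowedConsequences = "character", mafThreshold = "numeric",
    maxUnaffectedCarriers = "integer", multifamilyMinFamilies = "integer",
    maxControlCarriers = "integer", consensusMinTools = "integer",
    geneAllowlist = "character"
))

setValidity("FilterParam", function(object) {
    msg <- character(0)
    if (object@minGQ < 0 || object@minDepth < 0)
        msg <- c(msg, "QC thresholds must be >= 0")
    if (!(object@mafThreshold > 0 && object@mafThreshold < 1))
        msg <- c(msg, "mafThreshold must lie in (0, 1)")
    if (!all(object@allowedConsequences %in% CONSEQUENCE_LEVELS))
        msg <- c(msg, "unknown consequence class in allowedConsequences")
    if (object@maxUnaffectedCarriers < 0L || object@maxControlCarriers < 0L ||
        object@multifamilyMinFamilies < 1L)
        msg <- c(msg, "carrier/family thresholds out of range")
    if (object@consensusMinTools < 0L || object@consensusMinTools > 5L)
        msg <- c(msg, "consensusMinTools must lie in 0..5")
    if (length(msg)) msg else TRUE
})

#' @describeIn FilterParam-class Constructor with published-rule defaults.
#' @param ... slot values overriding the defaults.
#' @return a validated `FilterParam` object.
#' @export
FilterParam <- function(...) {
    args <- list(...)
    defaults <- list(
        minGQ = 20, minDepth = 8,
        allowedConsequences = setdiff(CONSEQUENCE_LEVELS, "other"),
        mafThreshold = 0.025,
        maxUnaffectedCarriers = 1L, multifamilyMinFamilies = 2L,
        maxControlCarriers = 1L, consensusMinTools = 3L,
        geneAllowlist = character(0)
    )
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
        stopf("unknown FilterParam field(s): %s",
              paste(unknown, collapse = ", "))
    vals <- modifyList(defaults, args)
    for (f in c("maxUnaffectedCarriers", "multifamilyMinFamilies",
                "maxControlCarriers", "consensusMinTools"))
        vals[[f]] <- as.integer(vals[[f]])
    do.call(new, c(list(Class = "FilterParam"), vals))
}

## ---------------------------------------------------------------------------
## BurdenParam: qualifying-variant rule for burden testing
## ---------------------------------------------------------------------------

#' Burden-test qualifying rule
#'
#' A variant qualifies for the per-gene burden test when its reference-panel
#' MAF is below `mafThreshold` (absence from the panel qualifies) and its
#' predicted effect is damaging: SIFT "D" and PolyPhen-2 "D" or "P" when the
#' corresponding flags are set. Counting is on alleles by default (cohort
#' alleles = 2 x probands, reference alleles = panel AN); set
#' `countBy = "carrier"` to count carriers instead.
#'
#' @slot mafThreshold qualifying MAF ceiling.
#' @slot requireSift require SIFT = "D".
#' @slot requirePolyphen require PolyPhen-2 in \{"D", "P"\}.
#' @slot countBy "allele" or "carrier".
#' @slot significanceLevel adjusted-p threshold used to flag significance.
#' @export
setClass("BurdenParam", representation(
    mafThreshold = "numeric", requireSift = "logical",
    requirePolyphen = "logical", countBy = "character",
    significanceLevel = "numeric"
))

setValidity("BurdenParam", function(object) {
    msg <- character(0)
    if (!(object@mafThreshold > 0 && object@mafThreshold < 1))
        msg <- c(msg, "mafThreshold must lie in (0, 1)")
    if (!(object@countBy %in% c("allele", "carrier")))
        msg <- c(msg, "countBy must be 'allele' or 'carrier'")
    if (!(object@significanceLevel > 0 && object@significanceLevel < 1))
        msg <- c(msg, "significanceLevel must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn BurdenParam-class Constructor.
#' @param ... slot values overriding the defaults.
#' @return a validated `BurdenParam` object.
#' @export
BurdenParam <- function(...) {
    args <- list(...)
    defaults <- list(mafThreshold = 0.025, requireSift = TRUE,
                     requirePolyphen = TRUE, countBy = "allele",
                     significanceLevel = 0.025)
    unknown <- setdiff(names(args), names(defaults))
    if (length(unknown))
        stopf("unknown BurdenParam field(s): %s",
              paste(unknown, collapse = ", "))
    vals <- modifyList(defaults, args)
    do.call(new, c(list(Class = "BurdenParam"), vals))
}

## ---------------------------------------------------------------------------
## DPCohort: the central cohort container
## ---------------------------------------------------------------------------

#' Cohort container
#'
#' `DPCohort` bundles everything the analysis consumes: the sample sheet
#' (pedigree membership, sex, phenotype, proband and control flags), the
#' variant table, the genotype allele-count matrix (variants x samples,
#' values 0/1/2 or NA for missing calls) with optional per-call genotype
#' quality and depth matrices, the annotation table, the reference-panel
#' frequency table, growth records, and - for simulated cohorts - a truth
#' record naming the causal gene, its variants and their carriers.
#'
#' Use the accessors (`cohortSamples`, `cohortVariants`, `genotypes`,
#' `genotypeGQ`, `genotypeDepth`, `annotations`, `panelAF`, `growthRecords`,
#' `cohortTruth`) rather than reaching into slots.
#'
#' @slot samples data.frame: sample_id, family_id, father_id, mother_id,
#'   sex ("M"/"F"), phenotype ("affected"/"unaffected"/"unknown"),
#'   is_proband, is_control.
#' @slot variants data.frame: variant_key, chrom, pos, ref, alt, gene.
#' @slot geno integer matrix of alternate-allele counts, variants in rows.
#' @slot gq,dp numeric matrices aligned with `geno` (may be 0 x 0 when the
#'   source carried no per-call quality information).
#' @slot annotations data.frame with the mandatory annotation columns.
#' @slot panel data.frame: variant_key, one or more `maf_*` columns, and
#'   optional `ac`/`an` reference allele counts.
#' @slot growth data.frame of growth records (may be empty).
#' @slot truth list with elements `causal_gene`, `causal_variants`,
#'   `carriers` (empty list for real cohorts).
#' @export
setClass("DPCohort", representation(
    samples = "data.frame", variants = "data.frame", geno = "matrix",
    gq = "matrix", dp = "matrix", annotations = "data.frame",
    panel = "data.frame", growth = "data.frame", truth = "list"
))

setValidity("DPCohort", function(object) {
    msg <- character(0)
    smp <- object@samples
    var <- object@variants
    g <- object@geno
    needS <- c("sample_id", "family_id", "father_id", "mother_id", "sex",
               "phenotype", "is_proband", "is_control")
    if (!all(needS %in% names(smp)))
        msg <- c(msg, "samples is missing mandatory columns")
    needV <- c("variant_key", "chrom", "pos", "ref", "alt", "gene")
    if (!all(needV %in% names(var)))
        msg <- c(msg, "variants is missing mandatory columns")
    if (nrow(var) != nrow(g) || nrow(smp) != ncol(g))
        msg <- c(msg, "genotype matrix dimensions do not match samples/variants")
    if (nrow(g) > 0 && !identical(rownames(g), var$variant_key))
        msg <- c(msg, "genotype rownames must equal variants$variant_key")
    if (ncol(g) > 0 && !identical(colnames(g), smp$sample_id))
        msg <- c(msg, "genotype colnames must equal samples$sample_id")
    if (length(g) && !all(g[!is.na(g)] %in% 0:2))
        msg <- c(msg, "allele counts must be 0, 1, 2 or NA")
    if (nrow(smp) && anyDuplicated(smp$sample_id))
        msg <- c(msg, "duplicate sample_id")
    if (nrow(smp) && !all(smp$phenotype %in% PHENOTYPE_LEVELS))
        msg <- c(msg, "phenotype must be affected/unaffected/unknown")
    if (nrow(smp) && any(smp$is_proband & smp$phenotype != "affected"))
        msg <- c(msg, "probands must be affected")
    for (mat in c("gq", "dp")) {
        m <- slot(object, mat)
        if (length(m) && !identical(dim(m), dim(g)))
            msg <- c(msg, sprintf("%s matrix dimensions differ from genotypes", mat))
    }
    if (length(object@truth) && length(object@truth$causal_variants)) {
        keys <- intersect(object@truth$causal_variants, rownames(g))
        if (length(keys)) {
            carr <- colnames(g)[colSums(g[keys, , drop = FALSE] >= 1,
                                        na.rm = TRUE) > 0]
            if (!setequal(carr, object@truth$carriers))
                msg <- c(msg, "truth carrier list disagrees with genotypes at causal variants")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn DPCohort-class Constructor.
#' @param samples,variants,geno,gq,dp,annotations,panel,growth,truth see slots.
#' @return a validated `DPCohort`.
#' @export
DPCohort <- function(samples, variants, geno,
                     gq = matrix(numeric(0), 0, 0),
                     dp = matrix(numeric(0), 0, 0),
                     annotations = emptyAnnotationTable(),
                     panel = emptyPanelTable(),
                     growth = data.frame(), truth = list()) {
    storage.mode(geno) <- "integer"
    new("DPCohort", samples = samples, variants = variants, geno = geno,
        gq = gq, dp = dp, annotations = annotations, panel = panel,
        growth = growth, truth = truth)
}

emptyAnnotationTable <- function() {
    out <- as.data.frame(setNames(rep(list(character(0)),
                                      length(ANNOTATION_COLUMNS)),
                                  ANNOTATION_COLUMNS))
    out$gerp <- numeric(0)
    out
}

emptyPanelTable <- function() {
    data.frame(variant_key = character(0), maf_all = numeric(0),
               ac = numeric(0), an = numeric(0))
}

setMethod("show", "DPCohort", function(object) {
    smp <- object@samples
    cat(sprintf("DPCohort: %d samples (%d families, %d controls), %d variants in %d genes\n",
                nrow(smp),
                length(unique(smp$family_id[!smp$is_control])),
                sum(smp$is_control),
                nrow(object@variants),
                length(unique(object@variants$gene))))
    cat(sprintf("  phenotypes: %d affected / %d unaffected / %d unknown; %d probands\n",
                sum(smp$phenotype == "affected"),
                sum(smp$phenotype == "unaffected"),
                sum(smp$phenotype == "unknown"),
                sum(smp$is_proband)))
    if (length(object@truth) && !is.null(object@truth$causal_gene))
        cat(sprintf("  simulated truth: causal gene %s, %d causal variants, %d carriers\n",
                    object@truth$causal_gene,
                    length(object@truth$causal_variants),
                    length(object@truth$carriers)))
    invisible(NULL)
})

## Accessors -----------------------------------------------------------------

#' @describeIn DPCohort-class Sample sheet.
#' @param x a `DPCohort`.
#' @export
cohortSamples <- function(x) x@samples

#' @describeIn DPCohort-class Variant table.
#' @export
cohortVariants <- function(x) x@variants

#' @describeIn DPCohort-class Allele-count matrix (variants x samples).
#' @export
genotypes <- function(x) x@geno

#' @describeIn DPCohort-class Genotype-quality matrix (may be empty).
#' @export
genotypeGQ <- function(x) x@gq

#' @describeIn DPCohort-class Read-depth matrix (may be empty).
#' @export
genotypeDepth <- function(x) x@dp

#' @describeIn DPCohort-class Annotation table.
#' @export
annotations <- function(x) x@annotations

#' @describeIn DPCohort-class Reference-panel frequency table.
#' @export
panelAF <- function(x) x@panel

#' @describeIn DPCohort-class Growth records.
#' @export
growthRecords <- function(x) x@growth

#' @describeIn DPCohort-class Simulation truth record (empty for real data).
#' @export
cohortTruth <- function(x) x@truth

#' Check Mendelian consistency of a cohort
#'
#' For every child whose two parents are genotyped, each of the child's
#' alternate alleles must be traceable to a parent: a child allele count of
#' one or more requires at least one parent carrying the allele, and a
#' homozygous child requires both.
#'
#' @param cohort a [DPCohort-class] object.
#' @return invisibly, a data.frame of violations (zero rows when consistent)
#'   with columns sample_id, variant_key, child, father, mother.
#' @export
checkMendelian <- function(cohort) {
    smp <- cohortSamples(cohort)
    g <- genotypes(cohort)
    out <- list()
    kids <- smp[!is.na(smp$father_id) & !is.na(smp$mother_id), ]
    for (i in seq_len(nrow(kids))) {
        kid <- kids$sample_id[i]
        fa <- kids$father_id[i]; mo <- kids$mother_id[i]
        if (!(fa %in% colnames(g)) || !(mo %in% colnames(g))) next
        ck <- g[, kid]; fk <- g[, fa]; mk <- g[, mo]
        ## ck == 1 needs >= 1 carrier parent; ck == 2 needs both
        viol <- !is.na(ck) & !is.na(fk) & !is.na(mk) &
            ((ck >= 1 & fk == 0 & mk == 0) |
             (ck == 2 & (fk == 0 | mk == 0)))
        bad <- which(viol)
        if (length(bad))
            out[[length(out) + 1L]] <- data.frame(
                sample_id = kid, variant_key = rownames(g)[bad],
                child = ck[bad], father = fk[bad], mother = mk[bad])
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(sample_id = character(0), variant_key = character(0),
                   child = integer(0), father = integer(0), mother = integer(0))
    rownames(res) <- NULL
    invisible(res)
}
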