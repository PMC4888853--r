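## The candidate-variant filter cascade: QC -> consequence -> MAF ->
## segregation -> multi-family -> (optional allowlist) -> control screen ->
## predictor consensus, with a full attrition trace.

#' Genotype quality-control filter
#'
#' A variant survives QC when at least one carrier call (allele count >= 1)
#' passes both the genotype-quality and read-depth thresholds. Calls with
#' missing GQ or DP are treated as passing (no numeric evidence against
#' them).
#'
#' @param cohort a [DPCohort-class].
#' @param keys variant keys to evaluate (default: all).
#' @param param a [FilterParam-class].
#' @return logical vector named by variant key: `TRUE` = retained.
#' @export
qcFilter <- function(cohort, keys = cohortVariants(cohort)$variant_key,
                     param = FilterParam()) {
    g <- genotypes(cohort)[keys, , drop = FALSE]
    gq <- genotypeGQ(cohort)
    dp <- genotypeDepth(cohort)
    carrier <- !is.na(g) & g >= 1
    pass <- carrier
    if (length(gq))
        pass <- pass & (is.na(gq[keys, , drop = FALSE]) |
                        gq[keys, , drop = FALSE] >= param@minGQ)
    if (length(dp))
        pass <- pass & (is.na(dp[keys, , drop = FALSE]) |
                        dp[keys, , drop = FALSE] >= param@minDepth)
    out <- rowSums(pass) > 0
    names(out) <- keys
    out
}

#' Functional-consequence filter
#'
#' Retains the prioritized consequence classes (by default nonsense,
#' missense, splice-site, structural, promoter, microRNA-deleterious and
#' frameshift; synonymous/other calls are removed). Every evaluated variant
#' must be annotated.
#'
#' @inheritParams qcFilter
#' @return named logical vector.
#' @export
consequenceFilter <- function(cohort,
                              keys = cohortVariants(cohort)$variant_key,
                              param = FilterParam()) {
    ann <- annotations(cohort)
    hit <- match(keys, ann$variant_key)
    if (anyNA(hit))
        stopf("variant '%s' has no annotation record", keys[which(is.na(hit))[1L]])
    out <- ann$consequence[hit] %in% param@allowedConsequences
    names(out) <- keys
    out
}

#' Population minor-allele-frequency filter
#'
#' A variant survives when its MAF is below the threshold in every
#' reference panel in which it has been seen; absence from all panels
#' ("not seen") also passes, since novel variants cannot be excluded on
#' frequency grounds.
#'
#' @inheritParams qcFilter
#' @return named logical vector.
#' @export
mafFilter <- function(cohort, keys = cohortVariants(cohort)$variant_key,
                      param = FilterParam()) {
    panel <- panelAF(cohort)
    mafCols <- grep("^maf_", names(panel), value = TRUE)
    hit <- match(keys, panel$variant_key)
    out <- vapply(seq_along(keys), function(i) {
        if (is.na(hit[i])) return(TRUE)          # not in panel at all
        mafs <- unlist(panel[hit[i], mafCols])
        mafs <- mafs[!is.na(mafs)]
        if (!length(mafs)) return(TRUE)          # seen in no panel
        all(mafs < param@mafThreshold)
    }, NA)
    names(out) <- keys
    out
}

#' Per-family segregation test
#'
#' Implements the dominant-model segregation rule: within a family with
#' `n` genotyped affected members, a variant segregates when it is carried
#' by at least `n - 1` of them (one affected non-carrier - a phenocopy - is
#' tolerated) and by at most one unaffected member. Members with unknown
#' phenotype or missing genotype contribute to neither count. A variant
#' absent from all genotyped family members does not segregate (reason
#' "absent").
#'
#' @param cohort a [DPCohort-class].
#' @param key a single variant key.
#' @param param a [FilterParam-class].
#' @return data.frame, one row per non-control family: family_id,
#'   n_affected (genotyped), affected_carriers, unaffected_carriers,
#'   segregates, reason.
#' @export
segregationFilter <- function(cohort, key, param = FilterParam()) {
    smp <- cohortSamples(cohort)
    g <- genotypes(cohort)[key, ]
    fams <- unique(smp$family_id[!smp$is_control])
    out <- lapply(fams, function(fid) {
        m <- smp[smp$family_id == fid, ]
        gm <- g[m$sample_id]
        genotyped <- !is.na(gm)
        aff <- m$phenotype == "affected" & genotyped
        una <- m$phenotype == "unaffected" & genotyped
        nAff <- sum(aff)
        affCar <- sum(gm[aff] >= 1)
        unaCar <- sum(gm[una] >= 1)
        present <- any(gm[genotyped] >= 1)
        seg <- present && nAff >= 1L && affCar >= nAff - 1L &&
            unaCar <= param@maxUnaffectedCarriers
        reason <- if (seg) "" else if (!present) "absent"
            else if (nAff < 1L) "no_genotyped_affected"
            else if (affCar < nAff - 1L) "affected_noncarriers"
            else "unaffected_carriers"
        data.frame(family_id = fid, n_affected = nAff,
                   affected_carriers = affCar, unaffected_carriers = unaCar,
                   segregates = seg, reason = reason,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Multi-family recurrence filter
#'
#' Given per-variant segregation results, a variant survives when it
#' segregates in at least one family and its gene harbours segregating
#' variants in at least `multifamilyMinFamilies` distinct families - either
#' the same variant recurring across families or different variants in the
#' same gene.
#'
#' @param segFamilies named list: variant key -> character vector of family
#'   ids in which the variant segregates.
#' @param geneOf named character vector: variant key -> gene symbol.
#' @param param a [FilterParam-class].
#' @return named logical vector over `names(segFamilies)`.
#' @export
multifamilyFilter <- function(segFamilies, geneOf, param = FilterParam()) {
    keys <- names(segFamilies)
    famPerGene <- lapply(split(segFamilies, unname(geneOf[keys])),
                         function(l) unique(unlist(l)))
    out <- vapply(keys, function(k) {
        length(segFamilies[[k]]) >= 1L &&
            length(famPerGene[[geneOf[[k]]]]) >= param@multifamilyMinFamilies
    }, NA)
    names(out) <- keys
    out
}

#' Cohort-control screen
#'
#' Retains a variant only when the number of carriers among the unrelated
#' cohort controls does not exceed `maxControlCarriers` (default one, the
#' published tolerance).
#'
#' @inheritParams qcFilter
#' @return named logical vector.
#' @export
controlScreen <- function(cohort, keys = cohortVariants(cohort)$variant_key,
                          param = FilterParam()) {
    smp <- cohortSamples(cohort)
    ctrl <- smp$sample_id[smp$is_control]
    g <- genotypes(cohort)[keys, ctrl, drop = FALSE]
    out <- rowSums(!is.na(g) & g >= 1) <= param@maxControlCarriers
    names(out) <- keys
    out
}

#' Five-tool predictor consensus
#'
#' Counts how many of SIFT ("D"), PolyPhen-2 ("D" or "P"), LRT ("D"),
#' MutationTaster ("D") and FATHMM ("D") call the variant damaging; a
#' missense variant passes with at least `consensusMinTools` (default 3 of
#' 5) damaging calls. Predicted loss-of-function classes (nonsense,
#' frameshift, splice-site) pass regardless of the missense predictors,
#' which are not defined for them.
#'
#' @inheritParams qcFilter
#' @return data.frame: variant_key, damaging_tools, pass.
#' @export
predictorConsensus <- function(cohort,
                               keys = cohortVariants(cohort)$variant_key,
                               param = FilterParam()) {
    ann <- annotations(cohort)
    hit <- match(keys, ann$variant_key)
    if (anyNA(hit))
        stopf("variant '%s' has no annotation record", keys[which(is.na(hit))[1L]])
    a <- ann[hit, , drop = FALSE]
    count <- (a$sift == "D") + (a$polyphen %in% c("D", "P")) +
        (a$lrt == "D") + (a$mutation_taster == "D") + (a$fathmm == "D")
    isLof <- a$consequence %in% LOF_CLASSES
    data.frame(variant_key = keys, damaging_tools = as.integer(count),
               pass = isLof | count >= param@consensusMinTools,
               stringsAsFactors = FALSE)
}

#' Run the full filter cascade
#'
#' Applies the stages in order: quality control, consequence class,
#' population MAF, pedigree segregation, multi-family recurrence, optional
#' gene allowlist (biological relevance stand-in), cohort-control screen
#' and predictor consensus. Returns the surviving candidate variants and
#' genes together with a complete attrition trace.
#'
#' @param cohort a [DPCohort-class].
#' @param param a [FilterParam-class].
#' @return list with `candidates` (data.frame of surviving variants with
#'   gene and segregating families), `candidateGenes` (character),
#'   `trace` (data.frame: stage, variants_in, variants_out), and `removed`
#'   (named list: stage -> data.frame(variant_key, reason)).
#' @export
runFilterCascade <- function(cohort, param = FilterParam()) {
    vt <- cohortVariants(cohort)
    geneOf <- stats::setNames(vt$gene, vt$variant_key)
    keys <- vt$variant_key
    trace <- list(); removed <- list(); segDetail <- list()

    record <- function(stage, keysIn, keep, reason) {
        trace[[length(trace) + 1L]] <<- data.frame(
            stage = stage, variants_in = length(keysIn),
            variants_out = sum(keep), stringsAsFactors = FALSE)
        if (any(!keep))
            removed[[stage]] <<- data.frame(
                variant_key = keysIn[!keep],
                reason = if (length(reason) == 1L)
                    rep(reason, sum(!keep)) else reason[!keep],
                stringsAsFactors = FALSE)
        keysIn[keep]
    }

    if (length(keys)) {
        keep <- qcFilter(cohort, keys, param)
        keys <- record("quality_control", keys, keep, "failed_gq_dp")
        if (length(keys)) {
            keep <- consequenceFilter(cohort, keys, param)
            keys <- record("consequence", keys, keep, "consequence_not_prioritized")
        } else keys <- record("consequence", keys, logical(0), character(0))
        if (length(keys)) {
            keep <- mafFilter(cohort, keys, param)
            keys <- record("maf", keys, keep, "maf_above_threshold")
        } else keys <- record("maf", keys, logical(0), character(0))
        ## segregation: a variant must segregate in >= 1 family
        segFamilies <- lapply(stats::setNames(keys, keys), function(k) {
            d <- segregationFilter(cohort, k, param)
            segDetail[[k]] <<- d
            d$family_id[d$segregates]
        })
        keep <- lengths(segFamilies) >= 1L
        keys <- record("segregation", keys, keep, "does_not_segregate")
        keep <- multifamilyFilter(segFamilies[keys], geneOf, param)
        keys <- record("multifamily", keys, keep, "single_family")
        if (length(param@geneAllowlist)) {
            keep <- unname(geneOf[keys] %in% param@geneAllowlist)
            keys <- record("gene_allowlist", keys, keep, "not_on_allowlist")
        }
        keep <- controlScreen(cohort, keys, param)
        keys <- record("control_screen", keys, keep, "multiple_control_carriers")
        if (length(keys)) {
            cons <- predictorConsensus(cohort, keys, param)
            keys <- record("predictor_consensus", keys, cons$pass,
                           "predictor_consensus_failed")
        } else keys <- record("predictor_consensus", keys, logical(0),
                              character(0))
        segFamilies <- segFamilies[keys]
    } else {
        for (stage in c("quality_control", "consequence", "maf",
                        "segregation", "multifamily", "control_screen",
                        "predictor_consensus"))
            keys <- record(stage, keys, logical(0), character(0))
        segFamilies <- list()
    }

    candidates <- data.frame(
        variant_key = keys, gene = unname(geneOf[keys]),
        n_segregating_families = lengths(segFamilies)[keys],
        stringsAsFactors = FALSE)
    rownames(candidates) <- NULL
    list(candidates = candidates,
         candidateGenes = sort(unique(candidates$gene)),
         trace = do.call(rbind, trace),
         removed = removed,
         segregation = segDetail)
}
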