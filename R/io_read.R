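## Readers and validators for the five on-disk formats. All coordinate and
## dialect decisions live here: coordinates are 1-based as in VCF, PED
## phenotype codes are 0 = unknown / 1 = unaffected / 2 = affected, and
## multi-allelic VCF records are split into one biallelic record per ALT.

#' Read a multi-sample VCF
#'
#' Parses a VCF v4.2 (via \pkg{vcfR}) into the package's variant table and
#' allele-count matrices. Multi-allelic records are split into one record
#' per ALT allele with per-sample allele counts recomputed for that ALT, so
#' total non-reference allele counts are conserved per sample per site.
#' Missing genotypes (`./.`) become `NA`; missing DP/GQ become `NA` and are
#' treated as passing quality control downstream.
#'
#' @param path path to an uncompressed VCF file.
#' @return list with `variants` (data.frame: variant_key, chrom, pos, ref,
#'   alt, gene - gene taken from an INFO `GENE=` field when present),
#'   `geno`, `gq`, `dp` (matrices, variants x samples).
#' @export
readCohortVCF <- function(path) {
    if (!file.exists(path)) stopf("VCF file '%s' does not exist", path)
    x <- tryCatch(
        suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
        error = function(e) stopf("malformed VCF '%s': %s", path,
                                  conditionMessage(e)))
    fix <- x@fix
    sampleIds <- colnames(x@gt)[-1L]
    if (is.null(sampleIds)) sampleIds <- character(0)
    if (nrow(fix) == 0L) {
        empty <- matrix(NA_integer_, 0L, length(sampleIds),
                        dimnames = list(NULL, sampleIds))
        return(list(variants = data.frame(
                        variant_key = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), gene = character(0)),
                    geno = empty, gq = empty, dp = empty))
    }
    pos <- suppressWarnings(as.integer(fix[, "POS"]))
    bad <- which(is.na(pos) | pos < 1L)
    if (length(bad))
        stopf("malformed VCF record at data line %d: bad POS '%s'",
              bad[1L], fix[bad[1L], "POS"])
    gt <- vcfR::extract.gt(x, element = "GT")
    fmt <- x@gt[, 1L]
    gq <- if (all(grepl("GQ", fmt)))
        vcfR::extract.gt(x, element = "GQ", as.numeric = TRUE) else NULL
    dp <- if (all(grepl("DP", fmt)))
        vcfR::extract.gt(x, element = "DP", as.numeric = TRUE) else NULL
    gene <- vcfR::extract.info(x, element = "GENE")

    outV <- list(); outG <- list(); outQ <- list(); outD <- list()
    for (i in seq_len(nrow(fix))) {
        alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
        gti <- gt[i, , drop = TRUE]
        alleles <- strsplit(as.character(gti), "[/|]")
        for (j in seq_along(alts)) {
            if (identical(alts[j], fix[i, "REF"]))
                stopf("malformed VCF record at data line %d: REF equals ALT", i)
            cnt <- vapply(alleles, function(a) {
                if (length(a) == 0L || any(a == ".") || any(is.na(a)))
                    NA_integer_
                else sum(a == as.character(j))
            }, NA_integer_)
            outV[[length(outV) + 1L]] <- data.frame(
                chrom = fix[i, "CHROM"], pos = pos[i], ref = fix[i, "REF"],
                alt = alts[j],
                gene = if (is.null(gene)) NA_character_ else gene[i],
                stringsAsFactors = FALSE)
            outG[[length(outG) + 1L]] <- cnt
            outQ[[length(outQ) + 1L]] <- if (is.null(gq))
                rep(NA_real_, length(cnt)) else gq[i, ]
            outD[[length(outD) + 1L]] <- if (is.null(dp))
                rep(NA_real_, length(cnt)) else dp[i, ]
        }
    }
    variants <- do.call(rbind, outV)
    variants$variant_key <- variantKey(variants$chrom, variants$pos,
                                       variants$ref, variants$alt)
    variants <- variants[c("variant_key", "chrom", "pos", "ref", "alt",
                           "gene")]
    mk <- function(lst, mode) {
        m <- matrix(unlist(lst), nrow = length(lst), byrow = TRUE,
                    dimnames = list(variants$variant_key, sampleIds))
        storage.mode(m) <- mode
        m
    }
    list(variants = variants, geno = mk(outG, "integer"),
         gq = mk(outQ, "double"), dp = mk(outD, "double"))
}

#' Read a PED pedigree file
#'
#' Six whitespace-delimited columns: family, individual, father, mother,
#' sex (1 = male, 2 = female), phenotype (0 = unknown, 1 = unaffected,
#' 2 = affected). `0` parent entries mean "founder". Controls are singleton
#' families (family id equal to the sample id, no parents); within each
#' multi-member family the first affected member in file order is taken to
#' be the proband.
#'
#' @param path path to the PED file.
#' @return sample sheet data.frame as used in [DPCohort-class].
#' @export
readPedFile <- function(path) {
    if (!file.exists(path)) stopf("PED file '%s' does not exist", path)
    if (file.size(path) == 0L)
        return(data.frame(sample_id = character(0), family_id = character(0),
                          father_id = character(0), mother_id = character(0),
                          sex = character(0), phenotype = character(0),
                          is_proband = logical(0), is_control = logical(0)))
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 6L)
        stopf("PED file '%s' must have >= 6 columns, found %d", path, ncol(raw))
    smp <- data.frame(
        family_id = raw[[1L]], sample_id = raw[[2L]],
        father_id = ifelse(raw[[3L]] == "0", NA_character_, raw[[3L]]),
        mother_id = ifelse(raw[[4L]] == "0", NA_character_, raw[[4L]]),
        sex = normalizeSex(raw[[5L]]),
        stringsAsFactors = FALSE)
    phen <- c(`0` = "unknown", `1` = "unaffected", `2` = "affected")[raw[[6L]]]
    if (anyNA(phen))
        stopf("PED file '%s': invalid phenotype code '%s'", path,
              raw[[6L]][which(is.na(phen))[1L]])
    smp$phenotype <- unname(phen)
    dup <- smp$sample_id[duplicated(smp$sample_id)]
    if (length(dup))
        stopf("PED file '%s': duplicate sample id '%s'", path, dup[1L])
    for (col in c("father_id", "mother_id")) {
        orphan <- setdiff(stats::na.omit(smp[[col]]), smp$sample_id)
        if (length(orphan))
            stopf("PED file '%s': parent '%s' is not a member of the file",
                  path, orphan[1L])
        parentFam <- smp$family_id[match(smp[[col]], smp$sample_id)]
        bad <- which(!is.na(smp[[col]]) & parentFam != smp$family_id)
        if (length(bad))
            stopf("PED file '%s': parent of '%s' belongs to another family",
                  path, smp$sample_id[bad[1L]])
    }
    famSize <- table(smp$family_id)
    smp$is_control <- smp$family_id == smp$sample_id &
        as.vector(famSize[smp$family_id] == 1L) & is.na(smp$father_id) &
        is.na(smp$mother_id)
    smp$is_proband <- FALSE
    for (fid in unique(smp$family_id[!smp$is_control])) {
        idx <- which(smp$family_id == fid & smp$phenotype == "affected")
        if (length(idx)) smp$is_proband[idx[1L]] <- TRUE
    }
    smp[c("sample_id", "family_id", "father_id", "mother_id", "sex",
          "phenotype", "is_proband", "is_control")]
}

#' Split a sample sheet into pedigrees
#'
#' @param samples a sample sheet (see [DPCohort-class]).
#' @return data.frame, one row per non-control family: family_id, n_members,
#'   n_affected, n_unaffected, n_unknown.
#' @export
pedigreeStats <- function(samples) {
    smp <- samples[!samples$is_control, , drop = FALSE]
    fams <- unique(smp$family_id)
    do.call(rbind, lapply(fams, function(fid) {
        m <- smp[smp$family_id == fid, ]
        data.frame(family_id = fid, n_members = nrow(m),
                   n_affected = sum(m$phenotype == "affected"),
                   n_unaffected = sum(m$phenotype == "unaffected"),
                   n_unknown = sum(m$phenotype == "unknown"),
                   stringsAsFactors = FALSE)
    }))
}

#' Read an annotation table
#'
#' Tab-separated with a header naming exactly the mandatory columns
#' (`variant_key`, `gene`, `consequence`, `sift`, `polyphen`, `lrt`,
#' `mutation_taster`, `fathmm`, `phylop_class`, `gerp`); extra columns are
#' preserved. Predictor codes are validated (e.g. SIFT "D"/"T",
#' PolyPhen-2 "D"/"P"/"B") and duplicate variant keys are an error.
#'
#' @param path path to the TSV file.
#' @return annotation data.frame.
#' @export
readAnnotationTable <- function(path) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
    if (length(missing))
        stopf("annotation table '%s' is missing column(s): %s", path,
              paste(missing, collapse = ", "))
    if (nrow(ann) == 0L) return(ann)
    dup <- ann$variant_key[duplicated(ann$variant_key)]
    if (length(dup))
        stopf("annotation table '%s': duplicate variant_key '%s'", path,
              dup[1L])
    bad <- setdiff(ann$consequence, CONSEQUENCE_LEVELS)
    if (length(bad))
        stopf("annotation table '%s': unknown consequence '%s'", path, bad[1L])
    for (tool in names(PREDICTOR_CODES)) {
        bad <- setdiff(ann[[tool]], PREDICTOR_CODES[[tool]])
        if (length(bad))
            stopf("annotation table '%s': unknown %s code '%s'", path, tool,
                  bad[1L])
    }
    ann$gerp <- as.numeric(ann$gerp)
    ann
}

#' Read a reference-panel allele-frequency table
#'
#' Tab-separated with a `variant_key` column, one or more `maf_*` columns
#' (fractions in `[0, 1]`; blank cells mean the variant has not been seen
#' in that panel) and optional `ac`/`an` reference allele counts used by the
#' burden test.
#'
#' @param path path to the TSV file.
#' @return panel data.frame.
#' @export
readPanelAF <- function(path) {
    panel <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!("variant_key" %in% names(panel)))
        stopf("panel table '%s' is missing the variant_key column", path)
    mafCols <- grep("^maf_", names(panel), value = TRUE)
    if (!length(mafCols))
        stopf("panel table '%s' has no maf_* column", path)
    dup <- panel$variant_key[duplicated(panel$variant_key)]
    if (length(dup))
        stopf("panel table '%s': duplicate variant_key '%s'", path, dup[1L])
    for (col in mafCols) {
        panel[[col]] <- as.numeric(panel[[col]])
        bad <- which(!is.na(panel[[col]]) &
                     (panel[[col]] < 0 | panel[[col]] > 1))
        if (length(bad))
            stopf("panel table '%s': %s out of [0, 1] at row %d", path, col,
                  bad[1L])
    }
    panel
}

#' Read growth records
#'
#' Comma-separated with at least `sample_id` and `sex`; the remaining
#' recognised columns (`hsds_4`, `hsds_8or9`, `adult_hsds`,
#' `midparental_hsds`, `th_sds`, `age_onset`, `age_takeoff`, `age_phv`,
#' `age_adult_height`) are optional and may contain blanks.
#'
#' @param path path to the CSV file.
#' @return growth data.frame.
#' @export
readGrowthCSV <- function(path) {
    g <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "sex")
    missing <- setdiff(need, names(g))
    if (length(missing))
        stopf("growth table '%s' is missing column(s): %s", path,
              paste(missing, collapse = ", "))
    if (nrow(g)) g$sex <- normalizeSex(g$sex)
    g
}

#' Assemble a cohort from a fixture directory
#'
#' Reads the files produced by [writeFixtureSet()] (or equivalently
#' formatted inputs) back into a [DPCohort-class]. Sample order follows the
#' VCF; the proband and control flags are restored from PED conventions,
#' the per-variant gene symbol is taken from the annotation table (with the
#' VCF INFO `GENE` field as fallback), and `truth.json` is loaded when
#' present.
#'
#' @param dir directory containing `cohort.vcf`, `cohort.ped`,
#'   `annotations.tsv`, `panel_af.tsv`, `growth.csv` and optionally
#'   `truth.json`.
#' @return a [DPCohort-class].
#' @export
readCohort <- function(dir) {
    vcf <- readCohortVCF(file.path(dir, "cohort.vcf"))
    smp <- readPedFile(file.path(dir, "cohort.ped"))
    ann <- readAnnotationTable(file.path(dir, "annotations.tsv"))
    panel <- readPanelAF(file.path(dir, "panel_af.tsv"))
    growth <- readGrowthCSV(file.path(dir, "growth.csv"))
    vcfIds <- colnames(vcf$geno)
    if (!setequal(vcfIds, smp$sample_id))
        stopf("VCF and PED sample sets differ (e.g. '%s')",
              c(setdiff(vcfIds, smp$sample_id),
                setdiff(smp$sample_id, vcfIds))[1L])
    smp <- smp[match(vcfIds, smp$sample_id), , drop = FALSE]
    rownames(smp) <- NULL
    variants <- vcf$variants
    hit <- match(variants$variant_key, ann$variant_key)
    variants$gene <- ifelse(is.na(hit), variants$gene, ann$gene[hit])
    unknownGene <- variants$variant_key[is.na(variants$gene)]
    if (length(unknownGene))
        stopf("variant '%s' has no gene in the annotation table or VCF",
              unknownGene[1L])
    truthPath <- file.path(dir, "truth.json")
    truth <- if (file.exists(truthPath)) {
        tr <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
        tr$causal_variants <- as.character(tr$causal_variants %||% character(0))
        tr$carriers <- as.character(tr$carriers %||% character(0))
        tr
    } else list()
    DPCohort(samples = smp, variants = variants, geno = vcf$geno,
             gq = vcf$gq, dp = vcf$dp, annotations = ann, panel = panel,
             growth = growth, truth = truth)
}
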