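## Fixture writers: VCF v4.2, PED, annotation/panel TSV, growth CSV,
## truth JSON, plus a checksum manifest.

#' Write a cohort to a directory of standard-format files
#'
#' Emits the five on-disk inputs of the analysis (multi-sample VCF v4.2 with
#' GT/DP/GQ, 6-column PED, annotation TSV, reference-panel TSV, growth CSV)
#' plus a `truth.json` for simulated cohorts, and a `manifest.json` listing
#' each file with its MD5 checksum. Writing is deterministic: the same
#' cohort always produces byte-identical files.
#'
#' Within each family the proband is written as the first affected member,
#' so that [readCohort()] can restore the proband flag from a plain PED
#' file; cohort controls are written as singleton families.
#'
#' @param cohort a [DPCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
writeFixtureSet <- function(cohort, dir) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                        showWarnings = FALSE)
    if (!ok || file.access(dir, 2L) != 0L)
        stopf("cannot write to directory '%s'", dir)
    paths <- c(vcf = file.path(dir, "cohort.vcf"),
               ped = file.path(dir, "cohort.ped"),
               annotation = file.path(dir, "annotations.tsv"),
               panel = file.path(dir, "panel_af.tsv"),
               growth = file.path(dir, "growth.csv"),
               truth = file.path(dir, "truth.json"))
    writeVcfFile(cohort, paths["vcf"])
    writePedFile(cohort, paths["ped"])
    writeTsv(annotations(cohort), paths["annotation"])
    writeTsv(panelAF(cohort), paths["panel"])
    utils::write.csv(growthRecords(cohort), paths["growth"],
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(cohortTruth(cohort), paths["truth"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths)),
                           stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         pretty = TRUE)
    invisible(manifest)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
}

writeVcfFile <- function(cohort, path) {
    smp <- cohortSamples(cohort)
    vt <- cohortVariants(cohort)
    g <- genotypes(cohort)
    gq <- genotypeGQ(cohort)
    dp <- genotypeDepth(cohort)
    hasQC <- length(gq) > 0 && length(dp) > 0
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##source=segburden",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", smp$sample_id), collapse = "\t"))
    lines <- hdr
    if (nrow(vt)) {
        gtStr <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g))
        gtStr[is.na(g)] <- "./."
        if (hasQC) {
            cells <- matrix(sprintf("%s:%d:%d", gtStr, as.integer(dp),
                                    as.integer(gq)), nrow(g))
            cells[is.na(g)] <- "./.:.:."
        } else cells <- gtStr
        body <- vapply(seq_len(nrow(vt)), function(i) {
            paste(c(vt$chrom[i], vt$pos[i], ".", vt$ref[i], vt$alt[i],
                    "100", "PASS", sprintf("GENE=%s", vt$gene[i]),
                    if (hasQC) "GT:DP:GQ" else "GT",
                    cells[i, ]), collapse = "\t")
        }, "")
        lines <- c(lines, body)
    }
    writeLines(lines, path)
}

writePedFile <- function(cohort, path) {
    smp <- cohortSamples(cohort)
    code <- c(affected = "2", unaffected = "1", unknown = "0")
    ## proband first within family (before any other affected member)
    ord <- order(match(smp$family_id, unique(smp$family_id)),
                 -smp$is_proband,
                 seq_len(nrow(smp)))
    smp <- smp[ord, ]
    lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                     smp$family_id, smp$sample_id,
                     ifelse(is.na(smp$father_id), "0", smp$father_id),
                     ifelse(is.na(smp$mother_id), "0", smp$mother_id),
                     ifelse(smp$sex == "M", "1", "2"),
                     code[smp$phenotype])
    writeLines(lines, path)
}
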