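## Accessors for the small published clinical tables bundled with the
## package. Genomic coordinates in the variant tables are synthetic (the
## published tables print transcript-level, not genomic, positions); the
## predictor calls, conservation scores, allele frequencies and growth
## values are the printed ones.

extdataPath <- function(file) {
    p <- system.file("extdata", file, package = "segburden", mustWork = TRUE)
    p
}

#' Published proband growth table
#'
#' Growth data of the ten discovery probands of the familial
#' delayed-puberty cohort: height SDS at 4 and 8/9 years, target height
#' SDS, and the printed delta HSDS and distance-to-target values, plus
#' adult height SDS.
#'
#' @return data.frame, one row per proband.
#' @export
probandGrowthData <- function() {
    utils::read.delim(extdataPath("proband_growth.tsv"),
                      stringsAsFactors = FALSE)
}

#' Published proband pubertal milestones
#'
#' Ages (years) at pubertal onset (Tanner stage 2), growth-spurt takeoff
#' and peak height velocity for the ten discovery probands.
#'
#' @return data.frame, one row per proband.
#' @export
probandMilestoneData <- function() {
    utils::read.delim(extdataPath("proband_milestones.tsv"),
                      stringsAsFactors = FALSE)
}

#' Published predictor calls for the four discovery variants
#'
#' The five-tool predictions (SIFT, PolyPhen-2, LRT, MutationTaster,
#' FATHMM), PhyloP conservation class and GERP++ score of the four
#' discovery missense variants, in the package's annotation-table schema.
#' Genomic coordinates are synthetic placeholders.
#'
#' @return annotation data.frame.
#' @export
discoveryVariantAnnotations <- function() {
    readAnnotationTable(extdataPath("discovery_variant_annotations.tsv"))
}

#' Published panel frequencies for the four discovery variants
#'
#' Cohort, control and reference-panel (Finnish / European / all) minor
#' allele frequencies of the four discovery variants, as fractions; blank
#' panel cells mean "not seen". Coordinates are synthetic placeholders.
#'
#' @return panel data.frame.
#' @export
discoveryVariantPanel <- function() {
    readPanelAF(extdataPath("discovery_variant_panel.tsv"))
}
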