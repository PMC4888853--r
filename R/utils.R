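## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used wherever a quantity is reported at
#' the precision of the clinical tables (one decimal for SDS quantities and
#' carrier prevalence percentages). `round()` in R rounds half to even, which
#' would turn 10.25 into 10.2 instead of 10.3.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(c(0.25, -0.25, 10.179), 1)
roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Canonical variant key
#'
#' Variants are identified throughout the package by the string
#' `chrom:pos:ref:alt` (1-based position, single ALT allele). Including both
#' alleles keeps indel keys unambiguous.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param ref,alt reference and single alternate allele strings.
#' @return character vector of keys.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
    paste(chrom, pos, ref, alt, sep = ":")
}

## Vocabulary ---------------------------------------------------------------

## Consequence classes; all but "other" are prioritized by default.
CONSEQUENCE_LEVELS <- c("nonsense", "missense", "splice_site", "structural",
                        "promoter", "mirna_deleterious", "frameshift", "other")
LOF_CLASSES <- c("nonsense", "frameshift", "splice_site")

PREDICTOR_CODES <- list(
    sift            = c("D", "T"),
    polyphen        = c("D", "P", "B"),
    lrt             = c("D", "N", "U"),
    mutation_taster = c("D", "N"),
    fathmm          = c("D", "T"),
    phylop_class    = c("C", "N")
)

PHENOTYPE_LEVELS <- c("affected", "unaffected", "unknown")
SEX_LEVELS <- c("M", "F")

## Columns that must be present, exactly named, in an annotation table.
ANNOTATION_COLUMNS <- c("variant_key", "gene", "consequence", "sift",
                        "polyphen", "lrt", "mutation_taster", "fathmm",
                        "phylop_class", "gerp")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
    x >= 0 && x == floor(x)

isFraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
    x >= 0 && x <= 1

normalizeSex <- function(sex) {
    s <- as.character(sex)
    s[s %in% c("1", "male", "m")] <- "M"
    s[s %in% c("2", "female", "f")] <- "F"
    bad <- !(s %in% SEX_LEVELS | is.na(s))
    if (any(bad))
        stopf("unknown sex code(s): %s", paste(unique(s[bad]), collapse = ", "))
    s
}
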