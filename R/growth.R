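## Auxological computations: target height from mid-parental height SDS,
## distance to target height, height-SDS change between ages 4 and 8/9,
## screening against published normal limits, and the diagnostic criteria
## for delayed puberty in probands and relatives.

#' Sex-specific target height in SDS units
#'
#' Converts mean parental height SDS to the child's expected (target)
#' height SDS: `0.791 * x - 0.147` for girls and `0.886 * x - 0.071` for
#' boys. The shrinkage coefficients account for regression to the mean
#' between generations.
#'
#' @param midparentalHsds mean parental height SDS.
#' @param sex "M"/"F" (codes 1/2 and male/female also accepted).
#' @return target height SDS.
#' @export
#' @examples
#' targetHeightSDS(0, "F")    # -0.147
#' targetHeightSDS(1, "M")    #  0.815
targetHeightSDS <- function(midparentalHsds, sex) {
    sex <- normalizeSex(sex)
    if (length(sex) == 1L) sex <- rep(sex, length(midparentalHsds))
    if (anyNA(sex)) stopf("sex must be known to compute target height")
    ifelse(sex == "M",
           0.886 * midparentalHsds - 0.071,
           0.791 * midparentalHsds - 0.147)
}

#' Distance from target height
#'
#' `TH - HSDS`: positive when the child is shorter than the mid-parental
#' expectation. The orientation matches the published proband tables, in
#' which short-for-target children have positive distances.
#'
#' @param thSds target height SDS.
#' @param hsds attained height SDS at the age of interest.
#' @return distance in SDS units.
#' @export
distanceToTarget <- function(thSds, hsds) {
    thSds - hsds
}

#' Height-SDS change between ages 4 and 8/9
#'
#' `HSDS(8/9) - HSDS(4)`; negative values are a prepubertal downward drift
#' across height centiles.
#'
#' @param hsds4 height SDS at 4 years.
#' @param hsds8or9 height SDS at 8 (girls) or 9 (boys) years.
#' @return change in SDS units.
#' @export
deltaHSDS <- function(hsds4, hsds8or9) {
    hsds8or9 - hsds4
}

#' Published screening limits for growth metrics
#'
#' Normal limits derived from a national reference of > 70,000 healthy
#' children: a child is outside normal limits when |delta HSDS| >= 1.21,
#' or when the (signed) distance to target height reaches 1.76 SDS at
#' 4 years, 1.72 at 8/9 years, or 1.44 at adult height.
#'
#' @return named numeric vector: delta_hsds, dist_th_4, dist_th_8or9,
#'   dist_th_adult.
#' @export
growthNormalLimits <- function() {
    c(delta_hsds = 1.21, dist_th_4 = 1.76, dist_th_8or9 = 1.72,
      dist_th_adult = 1.44)
}

#' Classify growth records against the normal limits
#'
#' Computes target height (from `th_sds` when supplied, otherwise from
#' `midparental_hsds`), the distances to target height at 4, 8/9 years and
#' adult height, and delta HSDS, then flags each metric. Distance metrics
#' are abnormal when the signed distance is at or above the limit (only a
#' short-for-target child is flagged); delta HSDS is abnormal when its
#' magnitude is at or above the limit. Comparisons at the printed limit
#' count as abnormal ("< limit" is normal). Metrics whose inputs are
#' missing are flagged `NA` (not evaluable), never an error.
#'
#' @param records data.frame with `sample_id` (or `case`), `sex`, and any
#'   of `hsds_4`, `hsds_8or9`, `adult_hsds`, `th_sds`, `midparental_hsds`.
#' @param limits named limits as from [growthNormalLimits()].
#' @return the records with added columns th_sds, delta_hsds, dist_th_4,
#'   dist_th_8or9, dist_th_adult and logical `*_outside` flags (TRUE =
#'   outside normal limits, NA = not evaluable).
#' @export
classifyGrowth <- function(records, limits = growthNormalLimits()) {
    r <- records
    n <- nrow(r)
    getCol <- function(col) if (col %in% names(r)) r[[col]] else
        rep(NA_real_, n)
    th <- getCol("th_sds")
    mp <- getCol("midparental_hsds")
    fill <- is.na(th) & !is.na(mp)
    if (any(fill))
        th[fill] <- targetHeightSDS(mp[fill], r$sex[fill])
    h4 <- getCol("hsds_4"); h89 <- getCol("hsds_8or9")
    ha <- getCol("adult_hsds")
    r$th_sds <- th
    r$delta_hsds <- deltaHSDS(h4, h89)
    r$dist_th_4 <- distanceToTarget(th, h4)
    r$dist_th_8or9 <- distanceToTarget(th, h89)
    r$dist_th_adult <- distanceToTarget(th, ha)
    r$delta_hsds_outside <- abs(r$delta_hsds) >= limits[["delta_hsds"]]
    r$dist_th_4_outside <- r$dist_th_4 >= limits[["dist_th_4"]]
    r$dist_th_8or9_outside <- r$dist_th_8or9 >= limits[["dist_th_8or9"]]
    r$dist_th_adult_outside <- r$dist_th_adult >= limits[["dist_th_adult"]]
    r
}

## Diagnostic thresholds (years): probands by age at pubertal onset
## (genital/breast Tanner stage 2), relatives by any one of growth-spurt
## takeoff, peak height velocity, or late attainment of adult height.
DP_CRITERIA <- list(
    onset = c(M = 13.5, F = 13.0),
    takeoff = c(M = 12.9, F = 11.3),
    phv = c(M = 14.8, F = 12.8),
    adult = c(M = 18, F = 16)
)

#' Diagnose delayed puberty in a proband
#'
#' A proband is affected when pubertal onset (testicular volume > 3 ml /
#' Tanner genital stage 2 in boys, Tanner breast stage 2 in girls) occurs
#' strictly later than 13.5 years (boys) or 13.0 years (girls).
#'
#' @param sex "M"/"F" vector.
#' @param ageOnset age at Tanner stage 2 in years.
#' @return logical vector (NA when the age is missing).
#' @export
diagnoseDPProband <- function(sex, ageOnset) {
    sex <- normalizeSex(sex)
    ageOnset > DP_CRITERIA$onset[sex]
}

#' Diagnose delayed puberty in a relative
#'
#' A relative is affected when any one of three milestones is late
#' (strict comparisons): growth-spurt takeoff after 12.9 / 11.3 years,
#' peak height velocity after 14.8 / 12.8 years, or adult height attained
#' after 18 / 16 years (males / females). Missing milestones are treated
#' as uninformative; if all three are missing the result is NA.
#'
#' @param sex "M"/"F" vector.
#' @param ageTakeoff,agePhv,ageAdultHeight milestone ages in years.
#' @return logical vector.
#' @export
diagnoseDPRelative <- function(sex, ageTakeoff = NA, agePhv = NA,
                               ageAdultHeight = NA) {
    sex <- normalizeSex(sex)
    n <- length(sex)
    rec <- function(x) rep_len(as.numeric(x), n)
    crit <- cbind(rec(ageTakeoff) > DP_CRITERIA$takeoff[sex],
                  rec(agePhv) > DP_CRITERIA$phv[sex],
                  rec(ageAdultHeight) > DP_CRITERIA$adult[sex])
    out <- apply(crit, 1L, function(z) {
        if (any(z %in% TRUE)) TRUE
        else if (all(is.na(z))) NA
        else FALSE
    })
    as.logical(out)
}
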