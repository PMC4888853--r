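## Per-gene rare-variant burden testing against a population reference:
## qualifying-variant selection, 2x2 allele-count tables, a two-sided
## Fisher's exact test computed by hypergeometric enumeration, step-up
## Benjamini-Hochberg adjustment, gene ranking and prevalence summaries.

#' Select qualifying variants for a gene
#'
#' A variant qualifies for the burden test when its reference-panel MAF
#' (AC/AN when available, otherwise the smallest reported `maf_*` value) is
#' below the rule's threshold - absence from the panel qualifies - and its
#' predicted effect is damaging under the rule: SIFT "D" and PolyPhen-2
#' "D" or "P".
#'
#' @param cohort a [DPCohort-class].
#' @param gene gene symbol.
#' @param param a [BurdenParam-class].
#' @param keys optional restriction to a candidate variant set (e.g. the
#'   cascade survivors); default considers all variants of the gene.
#' @return character vector of qualifying variant keys.
#' @export
selectQualifying <- function(cohort, gene, param = BurdenParam(),
                             keys = NULL) {
    ann <- annotations(cohort)
    ann <- ann[ann$gene == gene, , drop = FALSE]
    if (!is.null(keys)) ann <- ann[ann$variant_key %in% keys, , drop = FALSE]
    if (!nrow(ann)) return(character(0))
    maf <- panelMAFOf(cohort, ann$variant_key)
    ok <- (is.na(maf) | maf < param@mafThreshold)
    if (param@requireSift) ok <- ok & ann$sift == "D"
    if (param@requirePolyphen) ok <- ok & ann$polyphen %in% c("D", "P")
    ann$variant_key[ok]
}

## Reference MAF per variant: AC/AN when present, else min maf_* cell,
## NA when the variant is absent from the panel ("not seen").
panelMAFOf <- function(cohort, keys) {
    panel <- panelAF(cohort)
    hit <- match(keys, panel$variant_key)
    mafCols <- grep("^maf_", names(panel), value = TRUE)
    hasAN <- all(c("ac", "an") %in% names(panel))
    vapply(seq_along(keys), function(i) {
        if (is.na(hit[i])) return(NA_real_)
        row <- panel[hit[i], ]
        if (hasAN && !is.na(row$an) && row$an > 0)
            return(row$ac / row$an)
        m <- unlist(row[mafCols])
        m <- m[!is.na(m)]
        if (!length(m)) NA_real_ else min(m)
    }, NA_real_)
}

#' Build the 2x2 burden contingency table for a gene
#'
#' Cohort cells count proband alleles: `a` is the qualifying
#' alternate-allele count summed over probands, `b = 2 * probands - a`.
#' Reference cells come from panel allele counts: `c` is the summed AC over
#' qualifying variants and `d = AN - c` (AN taken as the largest allele
#' number among the gene's qualifying variants). With
#' `countBy = "carrier"`, `a` counts carrier probands and `b` the
#' remainder, with `c`/`d` scaled to individuals (AC and AN halved).
#'
#' @inheritParams selectQualifying
#' @param qualifying qualifying variant keys, as returned by
#'   [selectQualifying()].
#' @return named integer vector with elements a, b, c, d.
#' @export
buildContingencyTable <- function(cohort, gene, qualifying,
                                  param = BurdenParam()) {
    smp <- cohortSamples(cohort)
    probands <- smp$sample_id[smp$is_proband]
    if (!length(probands)) stopf("cohort has no probands")
    panel <- panelAF(cohort)
    g <- genotypes(cohort)[qualifying, probands, drop = FALSE]
    hit <- match(qualifying, panel$variant_key)
    ac <- if ("ac" %in% names(panel)) panel$ac[hit] else rep(NA_real_,
                                                             length(hit))
    an <- if ("an" %in% names(panel)) panel$an[hit] else rep(NA_real_,
                                                             length(hit))
    ac[is.na(ac)] <- 0
    refAN <- if (all(is.na(an))) 0 else max(an, na.rm = TRUE)
    if (param@countBy == "allele") {
        a <- sum(g, na.rm = TRUE)
        b <- 2L * length(probands) - a
        cc <- sum(ac)
        d <- max(0, refAN - cc)
    } else {
        a <- sum(colSums(!is.na(g) & g >= 1) > 0)
        b <- length(probands) - a
        cc <- round(sum(ac) / 2)
        d <- max(0, round(refAN / 2) - cc)
    }
    c(a = as.integer(a), b = as.integer(b), c = as.integer(cc),
      d = as.integer(d))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by full enumeration of the
#' hypergeometric distribution over the feasible range with the observed
#' margins: the p-value is the sum of point probabilities of all tables at
#' least as extreme as (i.e. with point probability not exceeding) that of
#' the observed table, the comparison made with relative tolerance 1e-7 to
#' avoid floating-point inclusion errors. A table with an empty margin has
#' a single attainable configuration and p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts; alternatively `a` may
#'   be a length-4 vector or 2x2 matrix.
#' @return the two-sided p-value in `[0, 1]`.
#' @export
#' @examples
#' fisherExactTwoSided(3, 1, 1, 3)  # 34/70
fisherExactTwoSided <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.null(b)) {
        x <- as.integer(a)
        if (length(x) != 4L) stopf("need four cell counts")
        a <- x[1L]; b <- x[2L]; c <- x[3L]; d <- x[4L]
    }
    cells <- c(a, b, c, d)
    if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
        stopf("cell counts must be non-negative integers")
    row1 <- a + b; col1 <- a + c; col2 <- b + d; n <- a + b + c + d
    if (row1 == 0L || col1 == 0L || col2 == 0L || row1 == n)
        return(1)
    lo <- max(0L, row1 - col2)
    hi <- min(row1, col1)
    dens <- stats::dhyper(lo:hi, col1, col2, row1)
    pObs <- stats::dhyper(a, col1, col2, row1)
    min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: with p-values sorted ascending,
#' `adj_(i) = min_(j >= i) ( G * p_(j) / j )` capped at 1 and mapped back to
#' the input order; tied p-values share their adjusted value.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bhAdjust <- function(p) {
    if (!length(p)) return(numeric(0))
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stopf("p-values must lie in [0, 1]")
    G <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- pmin(1, rev(cummin(rev(G * ps / seq_len(G)))))
    out <- numeric(G)
    out[o] <- adj
    out
}

#' Per-gene rare-variant burden test
#'
#' For each gene, selects qualifying variants, builds the proband-versus-
#' reference 2x2 table, computes the exact two-sided p-value, adjusts the
#' whole set with Benjamini-Hochberg, and ranks genes (ascending adjusted
#' p, then raw p, then gene symbol; ties broken deterministically).
#'
#' @param cohort a [DPCohort-class].
#' @param genes genes to test (default: all genes in the annotation table).
#' @param param a [BurdenParam-class].
#' @param candidateKeys optional variant restriction passed to
#'   [selectQualifying()] (e.g. filter-cascade survivors); `NULL` uses all
#'   raw calls.
#' @return data.frame: gene, n_qualifying, a, b, c, d, odds_ratio, p_raw,
#'   p_adj, rank, significant - ordered by rank.
#' @export
burdenTest <- function(cohort, genes = NULL, param = BurdenParam(),
                       candidateKeys = NULL) {
    if (is.null(genes)) genes <- sort(unique(annotations(cohort)$gene))
    if (!length(genes)) stopf("no genes to test")
    rows <- lapply(genes, function(gene) {
        q <- selectQualifying(cohort, gene, param, keys = candidateKeys)
        tab <- buildContingencyTable(cohort, gene, q, param)
        or <- if (tab["b"] == 0L || tab["c"] == 0L) {
            if (tab["a"] == 0L || tab["d"] == 0L) NA_real_ else Inf
        } else (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
        data.frame(gene = gene, n_qualifying = length(q),
                   a = tab["a"], b = tab["b"], c = tab["c"], d = tab["d"],
                   odds_ratio = unname(or),
                   p_raw = fisherExactTwoSided(tab["a"], tab["b"], tab["c"],
                                               tab["d"]),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res$p_adj <- bhAdjust(res$p_raw)
    rankGenes(res, significanceLevel = param@significanceLevel)
}

#' Rank burden-test results
#'
#' @param results data.frame with at least gene, p_raw, p_adj.
#' @param significanceLevel adjusted-p threshold for the significance flag.
#' @return the data.frame sorted by rank, with `rank` and `significant`
#'   columns added.
#' @export
rankGenes <- function(results, significanceLevel = 0.025) {
    ord <- order(results$p_adj, results$p_raw, results$gene)
    results <- results[ord, , drop = FALSE]
    rownames(results) <- NULL
    results$rank <- seq_len(nrow(results))
    results$significant <- results$p_adj < significanceLevel
    results
}

#' Carrier prevalence
#'
#' Percentage of a cohort carrying a qualifying variant, summing carrier
#' counts over variant classes and rounding half-up to one decimal (the
#' convention of the clinical summaries, e.g. (5 + 29) / 334 -> 10.2).
#'
#' @param carrierCounts integer vector of carrier counts by class (e.g.
#'   loss-of-function and missense).
#' @param n cohort size.
#' @return prevalence as a percentage with one decimal.
#' @export
#' @examples
#' carrierPrevalence(c(lof = 5, missense = 29), 334)
carrierPrevalence <- function(carrierCounts, n) {
    total <- sum(carrierCounts)
    if (n <= 0 || total > n)
        stopf("carrier counts must not exceed the cohort size")
    roundHalfUp(100 * total / n, 1L)
}
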