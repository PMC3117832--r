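# run expr under a fixed RNG state, restoring the caller's stream
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Sample a fraction of orthologous groups
#'
#' Draws a uniform sample of groups without replacement, the way a
#' tractable subset is selected for sequence-level analysis (a 5% sample
#' of 4,850 groups gives 243). The sample size is the smallest integer
#' not below `fraction * n`, with a minimum of one group.
#'
#' @param groups group identifiers: a character vector, an
#'   [OrthoProfiles-class] object, or a data.frame with a `group_id`
#'   column.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed; the same seed always yields the same subset.
#' @return character vector of sampled group identifiers.
#' @examples
#' length(sampleGroups(paste0("KOG", 1:4850), 0.05, seed = 1))  # 243
#' @export
sampleGroups <- function(groups, fraction, seed) {
    if (is(groups, "OrthoProfiles")) groups <- groupIds(groups)
    if (is.data.frame(groups)) groups <- groups$group_id
    groups <- as.character(groups)
    if (length(groups) == 0L) stop("no groups to sample from")
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("fraction must lie in (0, 1]")
    # 5% of 4850 is 242.5 and the intended sample exceeds it: take the
    # ceiling (rounding away float fuzz first)
    k <- max(1L, as.integer(ceiling(round(fraction * length(groups), 9))))
    withSeed(seed, sample(groups, k))
}

#' Correlate EPI with mean evolutionary distance
#'
#' Pearson product-moment correlation between per-group EPI and the
#' per-group mean Poisson-corrected distance, with a two-tailed p-value
#' from the t distribution on n - 2 degrees of freedom. Groups missing a
#' distance (e.g. skipped families) are dropped and counted.
#'
#' @param records per-group EPI: an [OrthoProfiles-class] object after
#'   [computePlasticity()], or a data.frame with `group_id` and `epi`.
#' @param distances per-group distances: a named list of
#'   [FamilyDistance-class] objects, or a data.frame with `group_id` and
#'   `mean_poisson_distance` (or `mean_d`).
#' @return list with `r`, `p`, `n` (paired groups used) and `n_dropped`.
#' @importFrom stats cor.test wilcox.test t.test median quantile sd setNames rpois
#' @export
correlateEpiDistance <- function(records, distances) {
    e <- if (is(records, "OrthoProfiles")) epi(records)
         else stats::setNames(records$epi, records$group_id)
    d <- if (is.data.frame(distances)) {
        col <- intersect(c("mean_poisson_distance", "mean_d"),
                         names(distances))[1]
        if (is.na(col)) stop("distances need a mean_poisson_distance column")
        stats::setNames(as.numeric(distances[[col]]), distances$group_id)
    } else {
        vapply(distances, meanDistance, numeric(1))
    }
    common <- intersect(names(e), names(d))
    keep <- common[!is.na(e[common]) & !is.na(d[common])]
    nDropped <- length(e) - length(keep)
    if (length(keep) < 3L)
        stop("need at least 3 groups with both EPI and distance, got ",
             length(keep))
    x <- unname(e[keep]); y <- unname(d[keep])
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance in ",
             if (stats::sd(x) == 0) "EPI" else "distance")
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = max(ct$p.value, .Machine$double.xmin),
         n = length(keep), n_dropped = nDropped)
}

#' EPI distribution over 100 equal-width bins
#'
#' Groups EPI values into 100 categories of width 0.01 on \[0, 1\]; bins
#' are half-open \[lo, hi) except the last, which is closed so EPI = 1
#' falls in bin 100.
#'
#' @param values numeric EPI values in \[0, 1\].
#' @param label label recorded on the result (attribute `label`).
#' @return data.frame with 100 rows and columns `bin_lo`, `bin_hi`,
#'   `count`, `percent`; attribute `total` is the number of values binned.
#' @export
epiHistogram <- function(values, label = "epi") {
    values <- as.numeric(values)
    values <- values[!is.na(values)]
    if (length(values) == 0L) stop("no EPI values to bin")
    if (any(values < 0 | values > 1))
        stop("EPI values must lie in [0, 1]")
    edges <- seq(0, 1, length.out = 101L)
    idx <- findInterval(values, edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = 100L)
    out <- data.frame(bin_lo = edges[-101L], bin_hi = edges[-1L],
                      count = counts,
                      percent = 100 * counts / length(values))
    attr(out, "label") <- label
    attr(out, "total") <- length(values)
    out
}

#' Compare the EPI distribution of a gene set against a reference
#'
#' Tests whether a phenotype-labeled gene set (e.g. genes whose knockout
#' is lethal) has a shifted EPI distribution relative to a reference set
#' (typically all scored proteins). The default test is the two-sided
#' Mann-Whitney U with normal approximation and tie correction, suited to
#' the bounded, skewed EPI scale; a Welch t-test is available for
#' comparison. Identifiers without an EPI value are dropped and tallied;
#' proteins in several groups contribute one value per membership.
#'
#' @param epiMap per-protein EPI: the data.frame from [proteinEpi()], or a
#'   named numeric vector protein_id -> EPI.
#' @param set a [GeneSet-class] to score.
#' @param reference the reference `GeneSet`.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return one-row data.frame with sample sizes, dropped-id counts,
#'   means, medians, quartiles, standard deviations, the test statistic
#'   (U for `"wilcoxon"`) and the two-sided p-value (floored at machine
#'   precision, never reported as 0).
#' @export
compareGeneSets <- function(epiMap, set, reference,
                            test = c("wilcoxon", "t")) {
    test <- match.arg(test)
    stopifnot(is(set, "GeneSet"), is(reference, "GeneSet"))
    lookup <- function(gs) {
        if (is.data.frame(epiMap)) {
            hit <- epiMap$protein_id %in% gs@ids
            vals <- epiMap$epi[hit]
            found <- unique(epiMap$protein_id[hit])
        } else {
            found <- intersect(gs@ids, names(epiMap))
            vals <- unname(epiMap[names(epiMap) %in% gs@ids])
        }
        list(vals = vals, dropped = length(gs@ids) - length(found))
    }
    a <- lookup(set); b <- lookup(reference)
    if (length(a$vals) == 0L)
        stop("gene set '", set@label, "' has no members with EPI values")
    if (length(b$vals) == 0L)
        stop("reference set '", reference@label,
             "' has no members with EPI values")
    if (test == "wilcoxon") {
        ht <- suppressWarnings(
            stats::wilcox.test(a$vals, b$vals, alternative = "two.sided",
                               exact = FALSE, correct = TRUE))
    } else {
        ht <- stats::t.test(a$vals, b$vals, alternative = "two.sided")
    }
    q <- function(v) unname(stats::quantile(v, c(0.25, 0.75)))
    qa <- q(a$vals); qb <- q(b$vals)
    data.frame(
        set_label = set@label, reference_label = reference@label,
        n_set = length(a$vals), n_ref = length(b$vals),
        n_dropped_set = a$dropped, n_dropped_ref = b$dropped,
        mean_set = mean(a$vals), mean_ref = mean(b$vals),
        median_set = stats::median(a$vals),
        median_ref = stats::median(b$vals),
        q1_set = qa[1], q3_set = qa[2], q1_ref = qb[1], q3_ref = qb[2],
        sd_set = stats::sd(a$vals), sd_ref = stats::sd(b$vals),
        test = test, statistic = unname(ht$statistic),
        p_value = max(ht$p.value, .Machine$double.xmin),
        stringsAsFactors = FALSE)
}
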