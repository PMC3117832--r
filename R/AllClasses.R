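#' OrthoProfiles: phyletic profiles of orthologous groups
#'
#' An `OrthoProfiles` object holds the per-species member counts of a set of
#' orthologous groups over a fixed species panel. It extends
#' [SummarizedExperiment::SummarizedExperiment]: rows are groups, columns are
#' the species of the panel, and the single assay `"counts"` stores
#' \eqn{s(i,\alpha)}, the number of members (orthologs plus paralogs) group
#' \eqn{\alpha} has in species \eqn{i}. The full protein membership table
#' (protein_id, species_id, group_id) is kept in
#' `metadata(x)$members` so per-protein results can be derived later.
#'
#' Row metadata always carries `nProteins` (\eqn{N_\alpha}) and `nSpecies`
#' (\eqn{M_\alpha}, species with at least one member); after
#' [computePlasticity()] it additionally carries `diversity`, `abundance` and
#' `epi`.
#'
#' @section Validity:
#' Counts are non-negative integers; every group has at least one member;
#' group and species identifiers are unique and non-empty.
#'
#' @seealso [readGroupTable()], [computePlasticity()], [speciesPanel()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass OrthoProfiles
setClass("OrthoProfiles", contains = "SummarizedExperiment")

setValidity("OrthoProfiles", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0) || any(cnt != round(cnt)))
            msg <- c(msg, "counts must be non-negative integers")
        if (nrow(cnt) > 0 && any(rowSums(cnt) < 1))
            msg <- c(msg, "every group must have at least one member")
    }
    if (is.null(rownames(object)) && nrow(object) > 0)
        msg <- c(msg, "group identifiers (rownames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "group identifiers must be unique")
    if (is.null(colnames(object)) && ncol(object) > 0)
        msg <- c(msg, "species identifiers (colnames) are required")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "species identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' FamilyDistance: Poisson-corrected distances within one aligned family
#'
#' Result container for [familyMeanDistance()]: all unordered pairwise
#' Poisson-corrected amino-acid distances among the aligned members of one
#' orthologous group, computed under pairwise deletion, plus their mean.
#' Pairs that could not be scored (no comparable sites, or saturated with
#' p = 1 so that \eqn{-\ln(1-p)} is undefined) are excluded from the mean
#' and counted in `nSkipped` so the exclusion is never silent.
#'
#' @slot groupId single group identifier.
#' @slot pairs data.frame with columns `seq1`, `seq2`, `sites` (compared
#'   columns after pairwise deletion), `p` (proportion of differing sites)
#'   and `d` (Poisson distance, substitutions/site); `NA` rows mark skipped
#'   pairs.
#' @slot meanDistance arithmetic mean of the finite pairwise distances.
#' @slot nSkipped number of pairs excluded as incomparable or saturated.
#'
#' @seealso [pairwisePoisson()], [batchFamilyDistances()]
#' @exportClass FamilyDistance
setClass("FamilyDistance",
    representation(groupId = "character", pairs = "data.frame",
                   meanDistance = "numeric", nSkipped = "integer"))

setValidity("FamilyDistance", function(object) {
    msg <- character()
    p <- object@pairs
    need <- c("seq1", "seq2", "sites", "p", "d")
    if (!all(need %in% names(p)))
        msg <- c(msg, paste("pairs must have columns",
                            paste(need, collapse = ", ")))
    else {
        ok <- !is.na(p$d)
        if (any(p$d[ok] < 0)) msg <- c(msg, "distances must be >= 0")
        if (any(p$p[ok] < 0 | p$p[ok] >= 1))
            msg <- c(msg, "finite distances require 0 <= p < 1")
    }
    if (length(object@groupId) != 1L) msg <- c(msg, "groupId must be scalar")
    if (length(msg)) msg else TRUE
})

#' GeneSet: a labeled set of gene/protein identifiers
#'
#' Minimal carrier for phenotype classes (e.g. "inviable", "viable",
#' "total") used by [compareGeneSets()].
#'
#' @slot label free-text class label.
#' @slot ids unique identifiers.
#' @exportClass GeneSet
setClass("GeneSet", representation(label = "character", ids = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@label) != 1L || !nzchar(object@label))
        msg <- c(msg, "label must be a non-empty string")
    if (length(object@ids) == 0L) msg <- c(msg, "ids must be non-empty")
    if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneSet-class Constructor.
#' @param label class label (e.g. `"inviable"`).
#' @param ids character vector of identifiers (deduplicated).
#' @return a `GeneSet`.
#' @export
GeneSet <- function(label, ids) {
    new("GeneSet", label = as.character(label),
        ids = unique(as.character(ids)))
}

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@label, "': ", length(object@ids), " ids\n",
        sep = "")
})

setMethod("show", "FamilyDistance", function(object) {
    cat("FamilyDistance for group", object@groupId, "\n")
    cat("  pairs:", nrow(object@pairs), " skipped:", object@nSkipped, "\n")
    cat("  mean Poisson distance:", format(object@meanDistance), "\n")
})
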