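#' Normalized Shannon diversity of a phyletic profile
#'
#' The diversity of an orthologous group is the Shannon entropy of its
#' member counts across the species panel, normalized to \[0, 1\]:
#' \deqn{H_\alpha = -\frac{1}{\ln M} \sum_{i=1}^{M} p_i \ln p_i,\qquad
#'       p_i = s(i,\alpha)/N_\alpha,}
#' with the convention \eqn{0\ln 0 = 0}. Species absent from the group
#' (count 0) contribute nothing to the sum but do enter through `M`, the
#' full panel size: a group only reaches \eqn{H_\alpha = 1} when all `M`
#' species carry an equal number of members (one gene per organism being
#' the canonical case), and \eqn{H_\alpha = 0} when a single species holds
#' every member. Natural logarithms throughout.
#'
#' @param counts numeric vector of per-species member counts
#'   \eqn{s(i,\alpha)}, one entry per panel species (zeros included).
#' @param M panel size used for normalization; defaults to
#'   `length(counts)`. Must be at least 2 (with `M = 1`, `ln M = 0` and
#'   the normalization is undefined).
#' @return diversity \eqn{H_\alpha} in \[0, 1\].
#' @examples
#' computeDiversity(c(99, 1))   # 0.080793136
#' computeDiversity(c(50, 50))  # 1
#' @export
computeDiversity <- function(counts, M = length(counts)) {
    counts <- checkCounts(counts)
    if (M < 2)
        stop("diversity is undefined for a panel of M = ", M,
             " species (ln M = 0); need M >= 2")
    if (length(counts) > M)
        stop("more count entries (", length(counts),
             ") than panel species (", M, ")")
    occupied <- counts > 0
    # uniform full occupancy gives H = 1 exactly; shortcut avoids the
    # roundoff of summing M identical p*log(p) terms
    if (sum(occupied) == M && length(unique(counts[occupied])) == 1L)
        return(1)
    p <- counts / sum(counts)
    p <- p[p > 0]                       # 0 * ln 0 := 0
    -sum(p * log(p)) / log(M)
}

#' Abundance of an orthologous group
#'
#' The abundance is the total number of members divided by the number of
#' species that contain at least one member: the average copy number per
#' occupied species, \eqn{D_\alpha = N_\alpha / M_\alpha \ge 1}. Species
#' with zero members do not affect it.
#'
#' @inheritParams computeDiversity
#' @return abundance \eqn{D_\alpha \ge 1}.
#' @examples
#' computeAbundance(c(99, 1))   # 50
#' computeAbundance(c(3, 0, 1)) # 2
#' @export
computeAbundance <- function(counts) {
    counts <- checkCounts(counts)
    sum(counts) / sum(counts > 0)
}

#' Evolutionary Plasticity Index
#'
#' Combines diversity and abundance into a single plasticity score,
#' \deqn{EPI = 1 - H_\alpha / \sqrt{D_\alpha} \in [0, 1].}
#' `EPI = 0` exactly when the group is maximally even and single-copy
#' (\eqn{H = 1}, \eqn{D = 1}): one conserved gene in every species. EPI
#' grows toward 1 as the phyletic pattern becomes patchier (lower H) or
#' more heavily duplicated (higher D) — i.e. as the family accumulated
#' more deletion and duplication episodes across the panel.
#'
#' @param H diversity in \[0, 1\].
#' @param D abundance, at least 1.
#' @return EPI in \[0, 1\]; vectorized over `H` and `D`.
#' @examples
#' computeEpi(computeDiversity(c(99, 1)), computeAbundance(c(99, 1)))
#' computeEpi(1, 50)   # 0.858578644
#' computeEpi(1, 1)    # 0
#' @export
computeEpi <- function(H, D) {
    if (any(!is.finite(H)) || any(H < 0) || any(H > 1))
        stop("diversity H must lie in [0, 1]")
    if (any(!is.finite(D)) || any(D < 1))
        stop("abundance D must be >= 1")
    1 - H / sqrt(D)
}

checkCounts <- function(counts) {
    counts <- as.numeric(counts)
    if (length(counts) == 0L || any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
        stop("counts must be non-negative integers")
    if (sum(counts) < 1)
        stop("group has no members (N = 0)")
    counts
}

#' Compute plasticity for every group of an OrthoProfiles object
#'
#' Adds `diversity`, `abundance` and `epi` columns to the row metadata,
#' one value per orthologous group, computed from the group-by-species
#' count matrix with the full panel size as the diversity normalization
#' constant.
#'
#' @param x an [OrthoProfiles-class] object over a panel of at least two
#'   species.
#' @return `x` with plasticity columns in `rowData(x)`; retrieve them with
#'   [diversity()], [abundance()] and [epi()], or as a data.frame with
#'   [plasticityTable()].
#' @examples
#' m <- data.frame(protein_id = paste0("p", 1:4),
#'                 species_id = c("sp1", "sp1", "sp2", "sp2"),
#'                 group_id   = c("G1", "G1", "G1", "G2"))
#' op <- computePlasticity(OrthoProfiles(m))
#' plasticityTable(op)
#' @export
computePlasticity <- function(x) {
    stopifnot(is(x, "OrthoProfiles"))
    if (ncol(x) < 2)
        stop("plasticity needs a panel of at least 2 species (M = ",
             ncol(x), ")")
    cnt <- SummarizedExperiment::assay(x, "counts")
    H <- vapply(seq_len(nrow(cnt)), function(i)
        tryCatch(computeDiversity(cnt[i, ], M = ncol(cnt)),
                 error = function(e) stop("group '", rownames(cnt)[i], "': ",
                                          conditionMessage(e))),
        numeric(1))
    D <- vapply(seq_len(nrow(cnt)), function(i) computeAbundance(cnt[i, ]),
                numeric(1))
    rd <- SummarizedExperiment::rowData(x)
    rd$diversity <- H
    rd$abundance <- D
    rd$epi <- computeEpi(H, D)
    SummarizedExperiment::rowData(x) <- rd
    x
}

#' @rdname diversity
#' @export
setMethod("diversity", "OrthoProfiles", function(x)
    plasticityColumn(x, "diversity"))

#' @rdname abundance
#' @export
setMethod("abundance", "OrthoProfiles", function(x)
    plasticityColumn(x, "abundance"))

#' @rdname epi
#' @export
setMethod("epi", "OrthoProfiles", function(x)
    plasticityColumn(x, "epi"))

plasticityColumn <- function(x, col) {
    rd <- SummarizedExperiment::rowData(x)
    if (!col %in% names(rd))
        stop("no '", col, "' column; run computePlasticity() first")
    stats::setNames(rd[[col]], rownames(x))
}

#' Per-group diversity values
#' @param x an `OrthoProfiles` processed by [computePlasticity()].
#' @return named numeric vector (group id -> \eqn{H_\alpha}).
#' @name diversity
NULL

#' Per-group abundance values
#' @param x an `OrthoProfiles` processed by [computePlasticity()].
#' @return named numeric vector (group id -> \eqn{D_\alpha}).
#' @name abundance
NULL

#' Per-group EPI values
#' @param x an `OrthoProfiles` processed by [computePlasticity()].
#' @return named numeric vector (group id -> EPI).
#' @name epi
NULL

#' Extract the plasticity results as a data.frame
#'
#' @param x an `OrthoProfiles` processed by [computePlasticity()].
#' @return data.frame with columns `group_id`, `n_proteins`, `n_species`,
#'   `diversity`, `abundance`, `epi`, in the object's group order.
#' @export
plasticityTable <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!all(c("diversity", "abundance", "epi") %in% names(rd)))
        stop("no plasticity columns; run computePlasticity() first")
    data.frame(group_id = rownames(x),
               n_proteins = rd$nProteins,
               n_species = rd$nSpecies,
               diversity = rd$diversity,
               abundance = rd$abundance,
               epi = rd$epi,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Transfer group EPI to member proteins
#'
#' Once a group's EPI is known it can be transferred to every protein that
#' composes the group. Proteins belonging to several groups yield one
#' entry per (protein, group) membership.
#'
#' @param x an `OrthoProfiles` processed by [computePlasticity()].
#' @return data.frame with columns `protein_id`, `group_id`, `epi`.
#' @seealso [annotateEpi()] for projecting these values onto a network,
#'   where multi-group proteins are collapsed by a stated rule.
#' @export
proteinEpi <- function(x) {
    e <- epi(x)
    mem <- members(x)
    data.frame(protein_id = mem$protein_id,
               group_id = mem$group_id,
               epi = unname(e[mem$group_id]),
               row.names = NULL, stringsAsFactors = FALSE)
}
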