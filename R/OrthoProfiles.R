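#' Build an OrthoProfiles object from a membership table
#'
#' Constructs the group-by-species count matrix from a long membership
#' table. Duplicate (protein_id, group_id) rows are collapsed to a single
#' member; a protein listed in several groups contributes to each of them.
#' Groups and species are ordered lexicographically so the result is
#' invariant under row permutations of the input.
#'
#' @param members data.frame with columns `protein_id`, `species_id`,
#'   `group_id` (one row per group membership).
#' @param panel optional character vector fixing the species panel. Species
#'   absent from every group still count toward the panel size `M` used to
#'   normalize diversity. When `NULL` the panel is inferred as the union of
#'   species seen in `members`. Species present in `members` but missing
#'   from an explicit panel are an error.
#'
#' @return an [OrthoProfiles-class] object.
#' @examples
#' m <- data.frame(protein_id = c("pA", "pB", "pC", "pD"),
#'                 species_id = c("sp1", "sp1", "sp2", "sp2"),
#'                 group_id   = c("G1", "G1", "G1", "G2"))
#' op <- OrthoProfiles(m)
#' assay(op, "counts")
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @export
OrthoProfiles <- function(members, panel = NULL) {
    need <- c("protein_id", "species_id", "group_id")
    miss <- setdiff(need, names(members))
    if (length(miss))
        stop("membership table is missing column(s): ",
             paste(miss, collapse = ", "))
    members <- as.data.frame(members)[, need]
    members[] <- lapply(members, as.character)
    if (nrow(members) == 0L)
        stop("membership table contains no rows")
    # one member per (protein, group); a protein may sit in several groups
    members <- members[!duplicated(members[, c("protein_id", "group_id")]), ,
                       drop = FALSE]
    rownames(members) <- NULL
    seen <- sort(unique(members$species_id))
    if (is.null(panel)) {
        panel <- seen
    } else {
        panel <- as.character(panel)
        if (anyDuplicated(panel))
            stop("explicit species panel contains duplicates")
        bad <- setdiff(seen, panel)
        if (length(bad))
            stop("species in table absent from the explicit panel: ",
                 paste(bad, collapse = ", "))
        panel <- sort(panel)
    }
    grp <- sort(unique(members$group_id))
    cnt <- table(factor(members$group_id, levels = grp),
                 factor(members$species_id, levels = panel))
    cnt <- matrix(as.integer(cnt), nrow = length(grp),
                  dimnames = list(grp, panel))
    rd <- S4Vectors::DataFrame(
        nProteins = as.integer(rowSums(cnt)),
        nSpecies  = as.integer(rowSums(cnt > 0)),
        row.names = grp)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = cnt), rowData = rd)
    S4Vectors::metadata(se)$members <- members
    new("OrthoProfiles", se)
}

#' Species panel of an OrthoProfiles object
#'
#' @param x an `OrthoProfiles`.
#' @return character vector of species identifiers; its length is the
#'   panel size `M` over which diversity is normalized.
#' @rdname speciesPanel
#' @export
setMethod("speciesPanel", "OrthoProfiles", function(x) colnames(x))

#' Group identifiers
#'
#' @param x an `OrthoProfiles`.
#' @return character vector of orthologous-group identifiers.
#' @rdname groupIds
#' @export
setMethod("groupIds", "OrthoProfiles", function(x) rownames(x))

#' Protein membership table
#'
#' @param x an `OrthoProfiles`.
#' @return data.frame with columns `protein_id`, `species_id`, `group_id`,
#'   one row per (protein, group) membership.
#' @rdname members
#' @export
setMethod("members", "OrthoProfiles", function(x)
    S4Vectors::metadata(x)$members)

#' @importFrom methods callNextMethod new validObject is
setMethod("show", "OrthoProfiles", function(object) {
    cat("OrthoProfiles:", nrow(object), "orthologous groups over",
        ncol(object), "species\n")
    cat("  proteins:", sum(SummarizedExperiment::assay(object, "counts")),
        "\n")
    extra <- intersect(c("diversity", "abundance", "epi"),
                       names(SummarizedExperiment::rowData(object)))
    if (length(extra))
        cat("  plasticity columns:", paste(extra, collapse = ", "), "\n")
})
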