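#' Read an orthologous-group membership table
#'
#' Reads a tab-separated membership table in the style of STRING/COG
#' orthology dumps: one row per protein, columns `protein_id`,
#' `species_id`, `group_id` (header required, no quoting). Duplicate
#' (protein, group) rows are collapsed; a protein mapped to several groups
#' is counted once in each.
#'
#' @param path path to the TSV file.
#' @param panel optional explicit species panel (character vector, or path
#'   to a one-identifier-per-line file). Controls the panel size `M` used
#'   by [computeDiversity()]; by default the panel is inferred as the union
#'   of species present in the table.
#' @return an [OrthoProfiles-class] object.
#' @seealso [OrthoProfiles()] for the underlying constructor.
#' @importFrom utils read.delim write.table
#' @export
readGroupTable <- function(path, panel = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- tryCatch(
        utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE),
        error = function(e) stop("cannot parse membership table '", path,
                                 "': ", conditionMessage(e)))
    need <- c("protein_id", "species_id", "group_id")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("membership table '", path, "' is missing column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(tab) == 0L)
        stop("membership table '", path, "' contains no rows")
    if (!is.null(panel) && length(panel) == 1L && file.exists(panel))
        panel <- readIdLines(panel)
    OrthoProfiles(tab, panel = panel)
}

# one-id-per-line reader shared by gene sets and panel files
readIdLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    unique(lines)
}

#' Read an aligned amino-acid family
#'
#' Reads one group's multiple alignment from aligned FASTA. All sequences
#' must have equal length; the amino-acid alphabet plus the gap character
#' `-` (and `X`/`?` for missing residues) is expected.
#'
#' @param path path to an aligned FASTA file.
#' @return a [Biostrings::AAStringSet] of equal-width sequences.
#' @importFrom Biostrings readAAStringSet width writeXStringSet AAStringSet
#' @export
readAlignment <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    aln <- tryCatch(Biostrings::readAAStringSet(path),
                    error = function(e) stop("cannot parse FASTA '", path,
                                             "': ", conditionMessage(e)))
    if (length(aln) == 0L)
        stop("alignment '", path, "' contains no sequences")
    w <- Biostrings::width(aln)
    if (length(unique(w)) != 1L)
        stop("ragged alignment '", path, "': sequence lengths ",
             paste(sort(unique(w)), collapse = ", "))
    # FASTA descriptions may carry annotation after the id
    names(aln) <- vapply(strsplit(names(aln), "\\s+"), `[`, "", 1L)
    if (anyDuplicated(names(aln)))
        stop("alignment '", path, "' has duplicated sequence ids")
    aln
}

#' Read a phenotype gene set
#'
#' Reads a plain-text identifier list (one per line; `#` comments and blank
#' lines ignored) into a labeled [GeneSet-class], e.g. the identifiers of
#' genes scored inviable in a knockout screen.
#'
#' @param path path to the list file.
#' @param label class label to attach (e.g. `"inviable"`).
#' @return a `GeneSet`.
#' @export
readGeneSet <- function(path, label) {
    if (!file.exists(path)) stop("file not found: ", path)
    ids <- readIdLines(path)
    if (length(ids) == 0L)
        stop("gene-set file '", path, "' contains no identifiers")
    GeneSet(label, ids)
}

#' Write and re-read the per-group plasticity table
#'
#' `writePlasticityTable()` writes the per-group results of
#' [computePlasticity()] as TSV with columns `group_id`, `n_proteins`,
#' `n_species`, `diversity`, `abundance`, `epi`; real values are printed at
#' nine decimal places. `readPlasticityTable()` reads such a file back.
#'
#' @param x an `OrthoProfiles` after [computePlasticity()], or a
#'   data.frame with the six columns above.
#' @param path output path.
#' @return `writePlasticityTable()` returns `path` invisibly;
#'   `readPlasticityTable()` returns a data.frame.
#' @export
writePlasticityTable <- function(x, path) {
    df <- if (is(x, "OrthoProfiles")) plasticityTable(x) else as.data.frame(x)
    need <- c("group_id", "n_proteins", "n_species", "diversity",
              "abundance", "epi")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("plasticity table is missing column(s): ",
             paste(miss, collapse = ", "))
    out <- df[, need, drop = FALSE]
    for (col in c("diversity", "abundance", "epi"))
        out[[col]] <- sprintf("%.9f", df[[col]])
    ok <- tryCatch({
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) stop("cannot write '", path, "': ",
                                conditionMessage(e)))
    invisible(path)
}

#' @rdname writePlasticityTable
#' @export
readPlasticityTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = c(group_id = "character"),
                      stringsAsFactors = FALSE)
}
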