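#' Poisson-corrected distance between two aligned amino-acid sequences
#'
#' Compares two rows of a protein alignment under pairwise deletion:
#' columns where either sequence has a gap (`-`) or missing data (`X`,
#' `?`) are dropped for this pair only. Over the remaining `sites`
#' columns, `p` is the proportion of differing residues and the
#' Poisson-corrected distance is
#' \deqn{d = -\ln(1 - p)}
#' substitutions per site, correcting the observed difference for multiple
#' hits under a Poisson substitution model. Residues are compared
#' case-insensitively and literally (no similarity matrix); no
#' rate-heterogeneity correction is applied.
#'
#' @param seqA,seqB aligned sequences of equal length (character strings
#'   or [Biostrings::AAString]-like objects).
#' @return list with elements `p`, `sites`, `d`.
#' @section Errors:
#' A pair with no comparable sites after deletion is incomparable, and a
#' saturated pair (`p = 1`, so `d` diverges) is undefined; both raise an
#' error here and are excluded (but counted) by [familyMeanDistance()].
#' @examples
#' pairwisePoisson("ACDE-F", "ACDG-F")  # sites 5, p 0.2, d -ln(0.8)
#' @export
pairwisePoisson <- function(seqA, seqB) {
    a <- alignedChars(seqA)
    b <- alignedChars(seqB)
    if (length(a) != length(b))
        stop("sequences differ in aligned length (", length(a), " vs ",
             length(b), ")")
    st <- pairStats(a, b)
    if (st$status == "incomparable")
        stop("no comparable sites after pairwise deletion")
    if (st$status == "saturated")
        stop("saturated pair (p = 1): Poisson distance undefined")
    st[c("p", "sites", "d")]
}

alignedChars <- function(x) {
    x <- as.character(x)
    if (length(x) != 1L) stop("expected a single sequence")
    toupper(strsplit(x, "", fixed = TRUE)[[1L]])
}

# shared with familyMeanDistance, which must tally rather than fail
MISSING_RESIDUES <- c("-", "X", "?", ".")

pairStats <- function(a, b) {
    keep <- !(a %in% MISSING_RESIDUES | b %in% MISSING_RESIDUES)
    sites <- sum(keep)
    if (sites == 0L)
        return(list(p = NA_real_, sites = 0L, d = NA_real_,
                    status = "incomparable"))
    p <- sum(a[keep] != b[keep]) / sites
    if (p >= 1)
        return(list(p = p, sites = sites, d = NA_real_,
                    status = "saturated"))
    list(p = p, sites = sites, d = -log(1 - p), status = "ok")
}

#' Mean Poisson-corrected distance within an aligned family
#'
#' Evaluates [pairwisePoisson()] for every unordered pair of sequences in
#' a family alignment and averages the finite distances. Incomparable or
#' saturated pairs are excluded from the mean and counted in `nSkipped`,
#' so any exclusion is visible rather than silently biasing the average.
#'
#' @param aln equal-width [Biostrings::AAStringSet] (e.g. from
#'   [readAlignment()]) with at least two sequences.
#' @param groupId identifier recorded on the result; defaults to
#'   `"family"`.
#' @return a [FamilyDistance-class] object.
#' @export
familyMeanDistance <- function(aln, groupId = "family") {
    if (is(aln, "XStringSet")) {
        seqs <- as.character(aln)
    } else {
        seqs <- vapply(aln, as.character, "")
    }
    if (length(seqs) < 2L)
        stop("family '", groupId, "' needs at least 2 sequences, got ",
             length(seqs))
    if (length(unique(nchar(seqs))) != 1L)
        stop("family '", groupId, "' alignment is ragged")
    if (is.null(names(seqs)))
        names(seqs) <- paste0("seq", seq_along(seqs))
    chars <- lapply(seqs, alignedChars)
    ids <- names(seqs)
    pair <- utils::combn(length(seqs), 2L)
    res <- lapply(seq_len(ncol(pair)), function(k)
        pairStats(chars[[pair[1L, k]]], chars[[pair[2L, k]]]))
    pairs <- data.frame(
        seq1 = ids[pair[1L, ]],
        seq2 = ids[pair[2L, ]],
        sites = vapply(res, function(r) as.integer(r$sites), 1L),
        p = vapply(res, function(r) as.numeric(r$p), 1),
        d = vapply(res, function(r) as.numeric(r$d), 1),
        stringsAsFactors = FALSE)
    finite <- !is.na(pairs$d)
    if (!any(finite))
        stop("family '", groupId,
             "': all pairs incomparable or saturated, mean undefined")
    new("FamilyDistance", groupId = as.character(groupId), pairs = pairs,
        meanDistance = mean(pairs$d[finite]),
        nSkipped = as.integer(sum(!finite)))
}

#' @describeIn familyMeanDistance mean of the finite pairwise distances.
#' @param x a `FamilyDistance`.
#' @export
setMethod("meanDistance", "FamilyDistance", function(x) x@meanDistance)

#' @describeIn familyMeanDistance the pairwise table (`seq1`, `seq2`,
#'   `sites`, `p`, `d`; skipped pairs carry `NA` distances).
#' @export
setMethod("pairDistances", "FamilyDistance", function(x) x@pairs)

#' Poisson distances for a directory of family alignments
#'
#' Resolves one aligned FASTA per group (filename stem = group id,
#' extension `.fasta`, `.fa` or `.faa`) and runs [familyMeanDistance()] on
#' each. Groups whose file is absent, or whose family cannot be scored
#' (fewer than two sequences, all pairs saturated), are skipped with a
#' message rather than aborting the batch.
#'
#' @param dir directory containing the alignments.
#' @param groups group identifiers to evaluate; default: every FASTA file
#'   found in `dir`.
#' @return named list of [FamilyDistance-class] objects.
#' @export
batchFamilyDistances <- function(dir, groups = NULL) {
    if (!dir.exists(dir)) stop("directory not found: ", dir)
    if (is.null(groups)) {
        files <- list.files(dir, pattern = "\\.(fasta|fa|faa)$")
        groups <- sort(unique(sub("\\.(fasta|fa|faa)$", "", files)))
    }
    if (length(groups) == 0L) stop("no alignment files in ", dir)
    out <- list()
    for (g in groups) {
        hits <- file.path(dir, paste0(g, c(".fasta", ".fa", ".faa")))
        hit <- hits[file.exists(hits)][1]
        if (is.na(hit)) {
            message("no alignment for group '", g, "', skipped")
            next
        }
        fd <- tryCatch(familyMeanDistance(readAlignment(hit), groupId = g),
                       error = function(e) {
                           message("group '", g, "' skipped: ",
                                   conditionMessage(e))
                           NULL
                       })
        if (!is.null(fd)) out[[g]] <- fd
    }
    if (length(out) == 0L)
        stop("no family could be scored in ", dir)
    out
}

#' Write a per-family distance summary table
#'
#' @param distances named list of [FamilyDistance-class] objects (e.g.
#'   from [batchFamilyDistances()]).
#' @param path output TSV path; columns `group_id`, `n_seqs`, `n_pairs`,
#'   `n_skipped_pairs`, `mean_poisson_distance`.
#' @return `path`, invisibly.
#' @export
writeDistanceTable <- function(distances, path) {
    rows <- lapply(distances, function(fd) {
        p <- fd@pairs
        data.frame(group_id = fd@groupId,
                   n_seqs = length(unique(c(p$seq1, p$seq2))),
                   n_pairs = nrow(p),
                   n_skipped_pairs = fd@nSkipped,
                   mean_poisson_distance = sprintf("%.9f", fd@meanDistance),
                   stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
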