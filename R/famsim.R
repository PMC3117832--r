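#' Gene-family simulation regime
#'
#' Parameters of the synthetic gene-family generator. Each simulated
#' family is retained independently by every panel species with
#' probability `retention`; a retaining species holds `1 + Poisson(dupRate)`
#' copies. High retention with no duplication emulates conserved
#' single-copy families (EPI 0 by construction); low retention with heavy
#' duplication emulates plastic families shaped by repeated deletion and
#' duplication episodes.
#'
#' @param retention per-species retention probability in (0, 1].
#' @param dupRate mean number of extra copies per retaining species
#'   (Poisson rate, >= 0).
#' @param nFamilies number of families to simulate (>= 1).
#' @param label prefix used in simulated group identifiers.
#' @return a `FamilyRegime` list.
#' @export
familyRegime <- function(retention, dupRate, nFamilies, label = "fam") {
    if (!is.numeric(retention) || retention <= 0 || retention > 1)
        stop("retention must lie in (0, 1]")
    if (!is.numeric(dupRate) || dupRate < 0)
        stop("dupRate must be >= 0")
    if (nFamilies < 1 || nFamilies != round(nFamilies))
        stop("nFamilies must be a positive integer")
    structure(list(retention = retention, dupRate = dupRate,
                   nFamilies = as.integer(nFamilies),
                   label = as.character(label)),
              class = "FamilyRegime")
}

#' A synthetic species panel
#'
#' @param M panel size; defaults to 55, the number of eukaryotes in the
#'   orthology resource the method was designed around.
#' @param prefix identifier prefix.
#' @return character vector of species identifiers.
#' @export
makeSpeciesPanel <- function(M = 55, prefix = "sp") {
    if (M < 1 || M != round(M)) stop("M must be a positive integer")
    sprintf("%s%02d", prefix, seq_len(M))
}

#' Simulate an orthologous-group membership table
#'
#' Draws gene families under one or more [familyRegime()]s over a species
#' panel and assembles them into an [OrthoProfiles-class] object. Families
#' that end up retained by no species are redrawn, so every emitted group
#' has at least one member. Fully reproducible from `seed`.
#'
#' @param panel character vector of species identifiers (see
#'   [makeSpeciesPanel()]); at least 2 species.
#' @param regimes a `FamilyRegime` or list of them.
#' @param seed integer seed.
#' @return an `OrthoProfiles` whose group ids carry the regime label.
#' @examples
#' op <- simulateOrthoTable(makeSpeciesPanel(10),
#'                          familyRegime(1, 0, 5, "cons"), seed = 1)
#' epi(computePlasticity(op))  # all exactly 0
#' @export
simulateOrthoTable <- function(panel, regimes, seed) {
    if (length(panel) < 2) stop("panel must contain at least 2 species")
    if (inherits(regimes, "FamilyRegime")) regimes <- list(regimes)
    if (!all(vapply(regimes, inherits, TRUE, "FamilyRegime")))
        stop("regimes must be FamilyRegime objects")
    withSeed(seed, {
        members <- do.call(rbind, lapply(regimes, simulateRegime,
                                         panel = panel))
        OrthoProfiles(members, panel = panel)
    })
}

# draw one regime's families; assumes the RNG is already seeded
simulateRegime <- function(regime, panel) {
    M <- length(panel)
    rows <- vector("list", regime$nFamilies)
    for (f in seq_len(regime$nFamilies)) {
        gid <- sprintf("%sF%04d", regime$label, f)
        repeat {
            retained <- stats::runif(M) < regime$retention
            if (any(retained)) break
        }
        copies <- 1L + stats::rpois(sum(retained), regime$dupRate)
        sp <- rep(panel[retained], copies)
        idx <- unlist(lapply(copies, seq_len))
        rows[[f]] <- data.frame(
            protein_id = sprintf("%s_%s_c%d", gid, sp, idx),
            species_id = sp, group_id = gid, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# substitute sites of a character-vector sequence under a Poisson jump
# process: each site receives Poisson(d) substitutions, each to a
# uniformly chosen different residue
evolveLineage <- function(x, d) {
    nsub <- stats::rpois(length(x), d)
    top <- max(nsub, 0L)
    j <- 1L
    while (j <= top) {
        idx <- which(nsub >= j)
        cur <- match(x[idx], AA20)
        x[idx] <- AA20[(cur - 1L + sample.int(19L, length(idx),
                                              replace = TRUE)) %% 20L + 1L]
        j <- j + 1L
    }
    x
}

#' Evolve a pair of sequences at a known distance
#'
#' Draws a uniform random ancestor over the 20 amino acids and evolves
#' two independent lineages, each site receiving `Poisson(dTrue/2)`
#' substitutions per lineage (total divergence `dTrue` substitutions per
#' site), every substitution going to a uniformly chosen different
#' residue. Under this uniform-exchange process the expected proportion
#' of differing sites is `(19/20) * (1 - exp(-dTrue * 20/19))` (see
#' [expectedPoissonP()]), slightly below `1 - exp(-dTrue)` because
#' parallel and back substitutions can restore identity among only 20
#' states.
#'
#' @param length number of sites.
#' @param dTrue true divergence in substitutions per site (>= 0).
#' @param seed integer seed.
#' @return [Biostrings::AAStringSet] of two ungapped sequences
#'   (`lineage1`, `lineage2`).
#' @export
evolvePair <- function(length, dTrue, seed) {
    if (length < 1 || length != round(length))
        stop("length must be a positive integer")
    if (!is.numeric(dTrue) || dTrue < 0)
        stop("dTrue must be >= 0")
    withSeed(seed, {
        anc <- sample(AA20, length, replace = TRUE)
        pair <- vapply(1:2, function(i)
            paste(evolveLineage(anc, dTrue / 2), collapse = ""), "")
        Biostrings::AAStringSet(stats::setNames(pair,
                                                c("lineage1", "lineage2")))
    })
}

#' @describeIn evolvePair expected observed difference proportion at true
#'   distance `d` under the uniform-exchange substitution process; used by
#'   recovery tests to form the model-matched expectation
#'   `-log(1 - expectedPoissonP(d))`.
#' @param d true divergence in substitutions per site.
#' @export
expectedPoissonP <- function(d) (19 / 20) * (1 - exp(-d * 20 / 19))

# evolve a star family: every leaf diverges d/2 from a common ancestor,
# so every pair sits at total distance d; RNG must already be seeded
evolveFamilyChars <- function(nSeqs, length, d, ids) {
    anc <- sample(AA20, length, replace = TRUE)
    seqs <- vapply(seq_len(nSeqs), function(i)
        paste(evolveLineage(anc, d / 2), collapse = ""), "")
    Biostrings::AAStringSet(stats::setNames(seqs, ids))
}

#' Write a self-consistent synthetic fixture bundle
#'
#' Emits everything needed to run the whole pipeline end to end with no
#' database access: a membership table mixing a conserved regime
#' (retention 1, no duplication) with a plastic regime (retention 0.3,
#' duplication rate 3) over a 55-species panel; one aligned FASTA per
#' group whose members diverged further in plastic families than in
#' conserved ones; two phenotype gene-set files drawn from low- and
#' high-EPI groups; and an edge-list interaction network over the
#' synthetic proteins with a pathway-label table.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed; identical seeds give identical bundles.
#' @param nFamilies families per regime.
#' @param panel species panel.
#' @param seqLength alignment length in residues.
#' @param setSize proteins per phenotype gene set.
#' @return named list of the written paths (`members`, `alignmentDir`,
#'   `lowSet`, `highSet`, `edges`, `nodeLabels`).
#' @export
makeFixtureSuite <- function(outDir, seed, nFamilies = 25,
                             panel = makeSpeciesPanel(55),
                             seqLength = 150, setSize = 200) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    alnDir <- file.path(outDir, "alignments")
    dir.create(alnDir, showWarnings = FALSE)
    regimes <- list(familyRegime(1, 0, nFamilies, "cons"),
                    familyRegime(0.3, 3, nFamilies, "plas"))
    op <- simulateOrthoTable(panel, regimes, seed = seed)
    memPath <- file.path(outDir, "members.tsv")
    utils::write.table(members(op), memPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    op <- computePlasticity(op)
    pe <- proteinEpi(op)
    withSeed(seed + 1L, {
        # conserved families diverged little, plastic families a lot
        for (g in groupIds(op)) {
            mem <- members(op)
            ids <- mem$protein_id[mem$group_id == g]
            d <- if (startsWith(g, "cons")) stats::runif(1, 0.05, 0.3)
                 else stats::runif(1, 0.6, 1.5)
            aln <- evolveFamilyChars(length(ids), seqLength, d, ids)
            Biostrings::writeXStringSet(aln,
                file.path(alnDir, paste0(g, ".fasta")))
        }
        consIds <- pe$protein_id[startsWith(pe$group_id, "cons")]
        plasIds <- pe$protein_id[startsWith(pe$group_id, "plas")]
        low <- sample(consIds, min(setSize, length(consIds)))
        high <- sample(plasIds, min(setSize, length(plasIds)))
        lowPath <- file.path(outDir, "low_epi_set.txt")
        highPath <- file.path(outDir, "high_epi_set.txt")
        writeLines(c("# synthetic low-EPI (conserved-regime) proteins", low),
                   lowPath)
        writeLines(c("# synthetic high-EPI (plastic-regime) proteins", high),
                   highPath)
        # ring edges within each family plus sparse cross-family links
        mem <- members(op)
        ringEdges <- do.call(rbind, lapply(split(mem$protein_id,
                                                 mem$group_id), function(p) {
            if (length(p) < 2) return(NULL)
            data.frame(node1 = p, node2 = c(p[-1], p[1]),
                       stringsAsFactors = FALSE)
        }))
        nCross <- nrow(ringEdges) %/% 5
        cross <- data.frame(node1 = sample(mem$protein_id, nCross),
                            node2 = sample(mem$protein_id, nCross),
                            stringsAsFactors = FALSE)
        edges <- rbind(ringEdges, cross)
        edges <- edges[edges$node1 != edges$node2, ]
        edges$weight <- round(stats::runif(nrow(edges), 0.4, 1), 3)
        edgePath <- file.path(outDir, "edges.tsv")
        utils::write.table(edges, edgePath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        labels <- data.frame(
            node_id = mem$protein_id,
            pathway = ifelse(startsWith(mem$group_id, "cons"),
                             "conserved_module", "plastic_module"),
            stringsAsFactors = FALSE)
        labelPath <- file.path(outDir, "node_labels.tsv")
        utils::write.table(labels, labelPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        list(members = memPath, alignmentDir = alnDir, lowSet = lowPath,
             highSet = highPath, edges = edgePath, nodeLabels = labelPath)
    })
}
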