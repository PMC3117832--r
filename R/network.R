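#' Build a protein-interaction network from an edge list
#'
#' Reads a tab-separated edge list (columns `node1`, `node2` and optional
#' `weight`, header required) into an undirected [igraph] graph. Edges
#' below the confidence threshold are dropped — the default 0.700 is the
#' conventional high-confidence STRING cutoff — as are self-loops;
#' duplicate edges are collapsed keeping the maximum weight, and only
#' interacting proteins are retained (no isolated nodes).
#'
#' @param edges path to the TSV, or a data.frame with the same columns.
#' @param minConfidence drop edges with `weight < minConfidence`;
#'   unweighted edge lists are kept in full.
#' @return an undirected `igraph` graph with edge attribute `weight`
#'   where weights were supplied.
#' @importFrom igraph graph_from_data_frame simplify V E ego vcount ecount
#'   vertex_attr vertex_attr<- as_data_frame is_igraph degree delete_vertices
#' @export
buildNetwork <- function(edges, minConfidence = 0.700) {
    if (is.character(edges)) {
        if (!file.exists(edges)) stop("file not found: ", edges)
        edges <- utils::read.delim(edges, header = TRUE, sep = "\t",
                                   quote = "", stringsAsFactors = FALSE)
    }
    need <- c("node1", "node2")
    miss <- setdiff(need, names(edges))
    if (length(miss))
        stop("edge list is missing column(s): ", paste(miss, collapse = ", "))
    edges$node1 <- as.character(edges$node1)
    edges$node2 <- as.character(edges$node2)
    weighted <- "weight" %in% names(edges)
    if (weighted) {
        edges$weight <- as.numeric(edges$weight)
        edges <- edges[is.na(edges$weight) | edges$weight >= minConfidence, ,
                       drop = FALSE]
    }
    edges <- edges[edges$node1 != edges$node2, , drop = FALSE]
    if (nrow(edges) == 0L)
        stop("no edges remain after confidence filtering (threshold ",
             minConfidence, ")")
    cols <- c(need, if (weighted) "weight")
    g <- igraph::graph_from_data_frame(edges[, cols, drop = FALSE],
                                       directed = FALSE)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = list(weight = "max", "ignore"))
    g
}

#' Annotate network nodes with the EPI of their orthologous group
#'
#' Projects per-protein EPI values onto the network: each node found in
#' the map receives an `epi` vertex attribute. A protein belonging to
#' several groups is collapsed with the `"min"` rule by default (a node
#' is treated as being as conserved as its most conserved family);
#' `"mean"` is available as an alternative. Unmapped nodes keep an `NA`
#' attribute and their count is reported.
#'
#' @param g an `igraph` graph from [buildNetwork()].
#' @param epiMap the data.frame from [proteinEpi()] (columns `protein_id`,
#'   `epi`), or a named numeric vector protein_id -> EPI.
#' @param combine rule for multi-group proteins: `"min"` or `"mean"`.
#' @return `g` with vertex attribute `epi`.
#' @export
annotateEpi <- function(g, epiMap, combine = c("min", "mean")) {
    combine <- match.arg(combine)
    if (is.data.frame(epiMap)) {
        agg <- tapply(epiMap$epi, epiMap$protein_id,
                      if (combine == "min") min else mean)
        epiMap <- stats::setNames(as.numeric(agg), names(agg))
    } else {
        epiMap <- tapply(unname(epiMap), names(epiMap),
                         if (combine == "min") min else mean)
        epiMap <- stats::setNames(as.numeric(epiMap), names(epiMap))
    }
    if (length(epiMap) == 0L) stop("EPI map is empty")
    if (any(epiMap < 0 | epiMap > 1, na.rm = TRUE))
        stop("EPI values must lie in [0, 1]")
    ids <- igraph::V(g)$name
    vals <- unname(epiMap[ids])
    if (all(is.na(vals)))
        stop("no network node has an EPI value")
    nMissing <- sum(is.na(vals))
    if (nMissing > 0)
        message(nMissing, " of ", length(ids),
                " nodes have no EPI annotation")
    igraph::vertex_attr(g, "epi") <- vals
    g
}

#' Neighborhood-mean smoothing of node EPI
#'
#' Produces a landscape-style regional summary of plasticity on the
#' network: the smoothed value at each node is the mean EPI over the node
#' itself and all annotated nodes within `radius` hops. `radius = 0`
#' returns each node's own EPI unchanged.
#'
#' @param g an annotated graph from [annotateEpi()].
#' @param radius non-negative integer hop count.
#' @return named numeric vector node -> smoothed EPI (`NA` where no
#'   annotated node lies within reach).
#' @export
smoothEpi <- function(g, radius = 1) {
    if (!"epi" %in% igraph::vertex_attr_names(g))
        stop("network is not annotated; run annotateEpi() first")
    e <- igraph::V(g)$epi
    if (all(is.na(e))) stop("network has no annotated nodes")
    if (radius < 0 || radius != round(radius))
        stop("radius must be a non-negative integer")
    ids <- igraph::V(g)$name
    if (radius == 0) return(stats::setNames(e, ids))
    hoods <- igraph::ego(g, order = radius, mindist = 0)
    sm <- vapply(hoods, function(h) {
        v <- e[as.integer(h)]
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    stats::setNames(sm, ids)
}

#' @importFrom igraph vertex_attr_names
NULL

#' Per-pathway EPI summary
#'
#' Summarizes node EPI by pathway label, reproducing regional claims such
#' as "this pathway is the least plastic region of the network". Nodes
#' carrying several labels are counted under each.
#'
#' @param g an annotated graph from [annotateEpi()].
#' @param nodeLabels data.frame with columns `node_id`, `pathway` (one
#'   row per label; a node may appear on several rows), or a path to such
#'   a TSV.
#' @return data.frame with one row per pathway: `pathway`, `n`, `mean`,
#'   `median`, `min`, `max` of node EPI, sorted by ascending mean (least
#'   plastic first).
#' @export
moduleSummary <- function(g, nodeLabels) {
    if (is.character(nodeLabels)) {
        if (!file.exists(nodeLabels)) stop("file not found: ", nodeLabels)
        nodeLabels <- utils::read.delim(nodeLabels, header = TRUE,
                                        sep = "\t", quote = "",
                                        stringsAsFactors = FALSE)
    }
    need <- c("node_id", "pathway")
    miss <- setdiff(need, names(nodeLabels))
    if (length(miss))
        stop("node-label table is missing column(s): ",
             paste(miss, collapse = ", "))
    if (!"epi" %in% igraph::vertex_attr_names(g))
        stop("network is not annotated; run annotateEpi() first")
    e <- stats::setNames(igraph::V(g)$epi, igraph::V(g)$name)
    nodeLabels <- nodeLabels[nodeLabels$node_id %in% names(e), ,
                             drop = FALSE]
    nodeLabels$epi <- unname(e[nodeLabels$node_id])
    nodeLabels <- nodeLabels[!is.na(nodeLabels$epi), , drop = FALSE]
    if (nrow(nodeLabels) == 0L)
        stop("no labeled node carries an EPI annotation")
    sp <- split(nodeLabels$epi, nodeLabels$pathway)
    out <- data.frame(
        pathway = names(sp),
        n = vapply(sp, length, 1L),
        mean = vapply(sp, mean, 1),
        median = vapply(sp, stats::median, 1),
        min = vapply(sp, min, 1),
        max = vapply(sp, max, 1),
        row.names = NULL, stringsAsFactors = FALSE)
    out[order(out$mean), , drop = FALSE]
}

#' Export node attributes for network viewers
#'
#' Writes a node-attribute TSV (`node_id`, `epi`, `smoothed_epi`,
#' `pathway`) loadable by Cytoscape-style tools.
#'
#' @param g an annotated graph from [annotateEpi()].
#' @param smoothed optional named vector from [smoothEpi()].
#' @param nodeLabels optional data.frame (`node_id`, `pathway`);
#'   multi-label nodes are joined with commas.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeNodeAttributes <- function(g, path, smoothed = NULL,
                                nodeLabels = NULL) {
    ids <- igraph::V(g)$name
    out <- data.frame(node_id = ids,
                      epi = if ("epi" %in% igraph::vertex_attr_names(g))
                          igraph::V(g)$epi else NA_real_,
                      stringsAsFactors = FALSE)
    out$smoothed_epi <- if (!is.null(smoothed)) unname(smoothed[ids])
                        else NA_real_
    out$pathway <- if (!is.null(nodeLabels)) {
        lab <- tapply(nodeLabels$pathway, nodeLabels$node_id,
                      function(v) paste(sort(unique(v)), collapse = ","))
        unname(lab[ids])
    } else NA_character_
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}
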