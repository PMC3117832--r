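edgeDf <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    names(d)[1:2] <- c("node1", "node2")
    d
}

test_that("network construction filters by confidence and cleans edges", {
    g <- buildNetwork(edgeDf(c("a", "b", "c"), c("b", "c", "d"),
                             weight = c(0.9, 0.8, 0.5)))
    expect_equal(igraph::ecount(g), 2L)
    expect_false("d" %in% igraph::V(g)$name)   # isolated after filtering

    # unweighted edge lists are kept in full
    g2 <- buildNetwork(edgeDf(c("a", "b"), c("b", "c")))
    expect_equal(igraph::ecount(g2), 2L)

    # duplicates collapse keeping the maximum weight; self-loops dropped
    g3 <- buildNetwork(edgeDf(c("a", "b", "a", "x"),
                              c("b", "a", "a", "x"),
                              weight = c(0.8, 0.95, 0.99, 0.9)))
    expect_equal(igraph::ecount(g3), 1L)
    expect_equal(igraph::E(g3)$weight, 0.95)

    expect_error(buildNetwork(edgeDf("a", "a", weight = 0.9)), "no edges")
    expect_error(buildNetwork(edgeDf(c("a", "b"), c("b", "c"),
                                     weight = c(0.1, 0.2))), "no edges")
    expect_error(buildNetwork(data.frame(from = "a", to = "b")), "node1")

    # rebuilding from its own edge data is a fixed point
    g4 <- buildNetwork(setNames(igraph::as_data_frame(g3, "edges"),
                                c("node1", "node2", "weight")))
    expect_equal(igraph::ecount(g4), igraph::ecount(g3))
    expect_setequal(igraph::V(g4)$name, igraph::V(g3)$name)
})

test_that("EPI annotation follows the stated multi-group rule", {
    g <- buildNetwork(edgeDf(c("a", "b"), c("b", "c")))
    pe <- data.frame(protein_id = c("a", "b", "b", "c"),
                     group_id = c("G1", "G1", "G2", "G2"),
                     epi = c(0.3, 0.2, 0.6, 0.6))
    ga <- annotateEpi(g, pe)
    e <- setNames(igraph::V(ga)$epi, igraph::V(ga)$name)
    expect_equal(unname(e[c("a", "c")]), c(0.3, 0.6))
    expect_equal(unname(e["b"]), 0.2)     # min across the two groups

    gm <- annotateEpi(g, pe, combine = "mean")
    em <- setNames(igraph::V(gm)$epi, igraph::V(gm)$name)
    expect_equal(unname(em["b"]), 0.4)

    expect_message(annotateEpi(g, pe[pe$protein_id != "c", ]), "1 of 3")
    expect_error(annotateEpi(g, data.frame(protein_id = "zz",
                                           group_id = "G", epi = 0.5)),
                 "no network node")
    pe$epi[1] <- 1.5
    expect_error(annotateEpi(g, pe), "\\[0, 1\\]")
})

test_that("neighborhood smoothing averages annotated nodes within reach", {
    # star: center plus four leaves
    star <- buildNetwork(edgeDf(rep("center", 4), paste0("leaf", 1:4)))
    pe <- data.frame(protein_id = c("center", paste0("leaf", 1:4)),
                     group_id = "G", epi = c(0, 1, 1, 1, 1))
    star <- annotateEpi(star, pe)

    s0 <- smoothEpi(star, radius = 0)
    expect_equal(s0, setNames(igraph::V(star)$epi, igraph::V(star)$name))
    s1 <- smoothEpi(star, radius = 1)
    expect_equal(unname(s1["center"]), 0.8)
    expect_equal(unname(s1["leaf1"]), 0.5)

    # contraction: smoothed values stay inside the annotated range
    expect_true(all(s1 >= min(pe$epi) & s1 <= max(pe$epi)))

    # large radius on a connected graph converges to the global mean
    sInf <- smoothEpi(star, radius = 10)
    expect_equal(unname(sInf), rep(mean(pe$epi), 5), tolerance = 1e-12)

    # disconnected annotated singleton keeps its own value
    g2 <- buildNetwork(edgeDf(c("a", "c"), c("b", "d")))
    pe2 <- data.frame(protein_id = c("a", "b", "c", "d"), group_id = "G",
                      epi = c(0.2, 0.4, 0.9, 0.9))
    g2 <- annotateEpi(g2, pe2)
    expect_equal(unname(smoothEpi(g2, radius = 5)[c("c", "d")]),
                 c(0.9, 0.9))

    expect_error(smoothEpi(buildNetwork(edgeDf("a", "b")), 1),
                 "not annotated")
})

test_that("pathway summaries rank modules by plasticity", {
    g <- buildNetwork(edgeDf(c("a", "b", "c"), c("b", "c", "a")))
    g <- annotateEpi(g, data.frame(protein_id = c("a", "b", "c"),
                                   group_id = "G",
                                   epi = c(0.1, 0.2, 0.8)))
    labels <- data.frame(node_id = c("a", "b", "c", "c"),
                         pathway = c("tca", "tca", "glycolysis", "tca"))
    summ <- moduleSummary(g, labels)
    expect_equal(summ$pathway[1], "tca")   # least plastic first
    expect_equal(summ$mean[summ$pathway == "glycolysis"], 0.8)
    # the multi-label node is counted under both pathways
    expect_equal(summ$n[summ$pathway == "tca"], 3L)
    expect_equal(summ$mean[summ$pathway == "tca"],
                 mean(c(0.1, 0.2, 0.8)))

    expect_error(moduleSummary(g, labels[0, ]), "no labeled")

    path <- tempfile(fileext = ".tsv")
    writeNodeAttributes(g, path, smoothed = smoothEpi(g, 1),
                        nodeLabels = labels)
    tab <- read.delim(path)
    expect_setequal(tab$node_id, c("a", "b", "c"))
    expect_equal(tab$pathway[tab$node_id == "c"], "glycolysis,tca")
})
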