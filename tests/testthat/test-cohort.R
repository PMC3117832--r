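test_that("group sampling takes the smallest integer above fraction*n", {
    ids <- paste0("KOG", seq_len(4850))
    s <- sampleGroups(ids, 0.05, seed = 42)
    expect_length(s, 243L)
    expect_true(all(s %in% ids))
    expect_false(anyDuplicated(s) > 0)

    expect_setequal(sampleGroups(ids[1:10], 1, seed = 1), ids[1:10])
    expect_identical(sampleGroups(ids, 0.05, seed = 7),
                     sampleGroups(ids, 0.05, seed = 7))
    expect_length(sampleGroups(ids[1:50], 0.001, seed = 1), 1L)
    expect_error(sampleGroups(ids, 0, seed = 1), "\\(0, 1\\]")
    expect_error(sampleGroups(ids, 1.2, seed = 1), "\\(0, 1\\]")
})

test_that("EPI-distance correlation matches the covariance-formula oracle", {
    # exact positive line
    rec <- data.frame(group_id = paste0("G", 1:5),
                      epi = c(0.1, 0.2, 0.3, 0.4, 0.5))
    dst <- data.frame(group_id = rec$group_id,
                      mean_poisson_distance = 2 * rec$epi + 0.05)
    res <- correlateEpiDistance(rec, dst)
    expect_equal(res$r, 1, tolerance = 1e-12)
    expect_equal(res$n, 5L)

    # ten fixed synthetic pairs against the literal formula
    set.seed(88)
    x <- runif(10); y <- 0.7 * x + rnorm(10, sd = 0.1)
    rec <- data.frame(group_id = paste0("G", 1:10), epi = x)
    dst <- data.frame(group_id = rec$group_id, mean_poisson_distance = y)
    res <- correlateEpiDistance(rec, dst)
    rOracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tOracle <- rOracle * sqrt(8 / (1 - rOracle^2))
    expect_equal(res$r, rOracle, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(tOracle), df = 8), tolerance = 1e-12)

    # affine rescaling with positive slope leaves r unchanged
    dst2 <- dst; dst2$mean_poisson_distance <- 3 * y + 10
    expect_equal(correlateEpiDistance(rec, dst2)$r, res$r,
                 tolerance = 1e-12)

    # groups without a distance are dropped and counted
    res3 <- correlateEpiDistance(rec, dst[1:6, ])
    expect_equal(res3$n, 6L)
    expect_equal(res3$n_dropped, 4L)

    expect_error(correlateEpiDistance(rec[1:2, ], dst[1:2, ]),
                 "at least 3")
    recC <- rec; recC$epi <- 0.5
    expect_error(correlateEpiDistance(recC, dst), "zero variance")
})

test_that("the 100-bin EPI histogram conserves counts and handles bounds", {
    h <- epiHistogram(c(0, 0.005))
    expect_equal(nrow(h), 100L)
    expect_equal(h$count[1], 2L)
    expect_equal(sum(h$count), 2L)

    h1 <- epiHistogram(1)
    expect_equal(h1$count[100], 1L)

    # half-open bins: 0.01 belongs to the second bin
    h2 <- epiHistogram(c(0.0099999, 0.01))
    expect_equal(h2$count[1:2], c(1L, 1L))

    set.seed(4)
    v <- runif(1000)
    hv <- epiHistogram(v)
    expect_equal(sum(hv$count), 1000L)
    expect_equal(sum(hv$percent), 100, tolerance = 1e-9)

    expect_error(epiHistogram(numeric()), "no EPI values")
    expect_error(epiHistogram(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney comparison agrees with brute-force enumeration", {
    mkMap <- function(vals) setNames(vals, paste0("p", seq_along(vals)))
    set.seed(31)
    for (i in 1:12) {
        n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
        # grid values force ties through the tie-corrected path too
        x <- sample(seq(0, 1, 0.25), n1, replace = TRUE)
        y <- sample(seq(0, 1, 0.25), n2, replace = TRUE)
        if (sd(c(x, y)) == 0) next
        m <- mkMap(c(x, y))
        res <- compareGeneSets(m, GeneSet("set", names(m)[seq_len(n1)]),
                               GeneSet("ref", names(m)[n1 + seq_len(n2)]))
        expect_equal(res$statistic, bruteU(x, y))
        expect_gt(res$p_value, 0)
        expect_lte(res$p_value, 1)
    }

    # at moderate n the approximate p agrees with a permutation oracle
    set.seed(77)
    x <- runif(15, 0, 0.6); y <- runif(15, 0.2, 1)
    m <- mkMap(c(x, y))
    res <- compareGeneSets(m, GeneSet("set", names(m)[1:15]),
                           GeneSet("ref", names(m)[16:30]))
    pool <- c(x, y)
    uObs <- bruteU(x, y); mu <- 15 * 15 / 2
    perm <- replicate(20000, {
        i <- sample(30, 15)
        abs(bruteU(pool[i], pool[-i]) - mu)
    })
    pPerm <- mean(perm >= abs(uObs - mu) - 1e-12)
    expect_lt(abs(res$p_value - pPerm), 0.02)
})

test_that("gene-set comparison reports shifts with descriptive statistics", {
    vals <- setNames(c(rep(0.1, 20), rep(0.9, 20)), paste0("p", 1:40))
    low <- GeneSet("low", paste0("p", 1:20))
    high <- GeneSet("high", paste0("p", 21:40))
    res <- compareGeneSets(vals, low, high)
    expect_equal(res$statistic, 0)        # every low value below every high
    expect_lt(res$p_value, 1e-6)
    expect_equal(res$mean_set, 0.1)
    expect_equal(res$median_ref, 0.9)
    expect_gt(res$p_value, 0)             # floored, never exactly zero

    # identical sets: no shift
    same <- compareGeneSets(vals, GeneSet("a", paste0("p", 1:40)),
                            GeneSet("b", paste0("p", 1:40)))
    expect_gt(same$p_value, 0.9)
    expect_equal(same$median_set, same$median_ref)

    # ids missing from the map are dropped and tallied
    padded <- GeneSet("low+", c(paste0("p", 1:20), "absent1", "absent2"))
    res2 <- compareGeneSets(vals, padded, high)
    expect_equal(res2$n_dropped_set, 2L)
    expect_equal(res2$n_set, 20L)

    expect_error(compareGeneSets(vals, GeneSet("ghost", "zzz"), high),
                 "ghost")

    # the t-test variant runs on the same interface
    spread <- setNames(c(seq(0.05, 0.15, length.out = 20),
                         seq(0.85, 0.95, length.out = 20)),
                       paste0("p", 1:40))
    rt <- compareGeneSets(spread, low, high, test = "t")
    expect_lt(rt$p_value, 1e-6)
    expect_identical(rt$test, "t")
})
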