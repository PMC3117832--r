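# independent oracles used across the suite; deliberately literal and slow

# Shannon diversity by direct term-by-term summation
entropyOracle <- function(counts, M = length(counts)) {
    N <- sum(counts)
    acc <- 0
    for (s in counts) {
        if (s > 0) {
            p <- s / N
            acc <- acc - p * log(p)
        }
    }
    acc / log(M)
}

# Mann-Whitney U of x over y by explicit pair counting (ties count 1/2)
bruteU <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
}

# exact two-sided p by enumerating all assignments of the pooled values
exactMwP <- function(x, y) {
    pool <- c(x, y)
    n1 <- length(x)
    idx <- utils::combn(length(pool), n1)
    us <- apply(idx, 2, function(i) bruteU(pool[i], pool[-i]))
    uObs <- bruteU(x, y)
    mu <- n1 * length(y) / 2
    mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# build an OrthoProfiles from a list of named per-species count vectors
opFromCounts <- function(countList, panel = NULL) {
    rows <- lapply(names(countList), function(g) {
        cnt <- countList[[g]]
        sp <- rep(names(cnt), cnt)
        if (length(sp) == 0) stop("empty group in fixture")
        data.frame(protein_id = sprintf("%s_%s_%d", g, sp,
                                        sequence(unname(cnt[cnt > 0]))),
                   species_id = sp, group_id = g,
                   stringsAsFactors = FALSE)
    })
    OrthoProfiles(do.call(rbind, rows), panel = panel)
}

# random small membership table for property tests (RNG must be seeded)
randomCounts <- function(maxM = 8, maxCount = 20) {
    M <- sample(2:maxM, 1)
    repeat {
        cnt <- sample(0:maxCount, M, replace = TRUE)
        if (sum(cnt) > 0) return(cnt)
    }
}
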