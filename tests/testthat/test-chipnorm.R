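test_that("peak-union merge handles overlap and adjacency", {
    # 0-based [10,20) + [15,30) -> [10,30): 1-based 11..20 + 16..30
    m <- mergePeakUnion(gr1(11, 20), gr1(16, 30))
    expect_identical(granges(m), gr1(11, 30))
    # touching intervals merge (0-based end == start)
    m2 <- mergePeakUnion(gr1(11, 20), gr1(21, 30))
    expect_identical(granges(m2), gr1(11, 30))
    # separated by one base: two intervals
    m3 <- mergePeakUnion(gr1(11, 20), gr1(22, 30))
    expect_equal(length(m3), 2L)
    expect_error(mergePeakUnion(gr1(5, 10), data.frame()), "GRanges")
})

test_that("peak-union merge equals the per-base mask oracle", {
    withr::with_seed(37, {
        for (i in 1:100) {
            n <- sample(2:100, 1)
            s <- sample(5000, n, replace = TRUE)
            e <- s + sample(0:200, n, replace = TRUE)
            got <- mergePeakUnion(gr1(s, e), gr1(1, 2))  # extra list
            want <- maskUnionOracle(c(s, 1), c(e, 2), 6000)
            expect_equal(start(got), unname(want[, "start"]))
            expect_equal(end(got), unname(want[, "end"]))
        }
    })
})

test_that("RiPPM factors scale reads in the peak union per million", {
    bins <- gr1(c(1, 101, 201), c(100, 200, 300))
    counts <- cbind(s1 = c(6e5, 4e5, 50), s2 = c(3e5, 2e5, 25))
    wc <- WindowCounts(bins, counts, sex = c("M", "F"),
        genotype = c("control", "control"),
        totalReads = c(2e6, 1e6))
    union <- gr1(1, 200)   # first two bins only
    f <- rippmFactors(wc, union)
    expect_equal(unname(f), c(1, 0.5))
    norm <- normalizeCounts(wc, f)
    expect_equal(unname(norm[, "s2"]), unname(2 * counts[, "s2"]))
    # in-peak scale invariance: tripling one sample's counts triples its
    # factor and leaves its normalized profile unchanged
    counts3 <- counts; counts3[, 1] <- counts3[, 1] * 3
    wc3 <- WindowCounts(bins, counts3, sex = c("M", "F"),
        genotype = c("control", "control"), totalReads = c(6e6, 1e6))
    f3 <- rippmFactors(wc3, union)
    expect_equal(unname(f3[1] / f[1]), 3)
    expect_equal(normalizeCounts(wc3, f3)[, 1], norm[, 1])
    # zero in-peak reads is an error
    wc0 <- WindowCounts(bins, cbind(s1 = c(0, 0, 5), s2 = c(1, 1, 1)),
        sex = c("M", "F"), genotype = c("control", "control"),
        totalReads = c(10, 10))
    expect_error(rippmFactors(wc0, union), "zero in-peak")
})

test_that("reciprocal overlap requires the fraction of both lengths", {
    a <- gr1(1, 100)
    expect_equal(length(reciprocalOverlap(a, a, 1)), 1L)
    # [0,100) vs [50,150): overlap 50 < 80 -> fails at 0.8
    expect_equal(length(reciprocalOverlap(gr1(1, 100), gr1(51, 150),
        0.8)), 0L)
    # [0,100) vs [10,95): overlap 85 >= 80 and >= 0.8*85 -> passes
    expect_equal(length(reciprocalOverlap(gr1(1, 100), gr1(11, 95),
        0.8)), 1L)
    # asymmetric containment fails the long interval's fraction
    expect_equal(length(reciprocalOverlap(gr1(1, 1000), gr1(1, 100),
        0.8)), 0L)
})

test_that("the static-site cascade keeps floor-rounded percentile cuts", {
    # 100 identical candidate pairs with deterministic count ranking
    n <- 100L
    starts <- seq(1L, by = 200L, length.out = n)
    sites <- gr1(starts, starts + 99L)
    bins <- sites
    # counts descending in site order; 4 samples, no noise
    base <- rev(seq_len(n)) * 10L
    counts <- cbind(a = base, b = base, c = base, d = base)
    wc <- WindowCounts(bins, counts, sex = c("M", "F", "M", "F"),
        genotype = rep("control", 4), totalReads = rep(1e6, 4))
    st <- identifyStaticSites(sites, sites, wc)
    expect_equal(auditLog(st)$n, c(100L, 35L, 26L))
    # retained sites equal a direct recomputation of the filters: the 35
    # highest-count sites, then (all CVs zero) the 26 leftmost of those
    topByCount <- sites[order(-base)][1:35]
    want <- sort(topByCount)[1:26]
    expect_identical(granges(staticSites(st)), granges(want))
    expect_error(identifyStaticSites(gr1(1e6, 1e6 + 10), sites, wc),
        "pair")
})

test_that("doubling one library doubles its factor and fixes normalization", {
    sim <- simulateWindowCounts(tinyConfig(seed = 61L))
    wc <- sim$windows
    scanM <- scanDifferentialWindows(wc,
        list(sex = "M", genotype = "control"),
        list(sex = "M", genotype = "KO"), windowSizes = 1000L)
    scanF <- scanDifferentialWindows(wc,
        list(sex = "F", genotype = "control"),
        list(sex = "F", genotype = "KO"), windowSizes = 1000L)
    ndM <- stringentNondiffSites(scanM, sim$peaks)
    ndF <- stringentNondiffSites(scanF, sim$peaks)
    st <- identifyStaticSites(ndM, ndF, wc)
    cts2 <- assay(wc, "counts"); cts2[, 1] <- cts2[, 1] * 2L
    tot2 <- colData(wc)$totalReads; tot2[1] <- tot2[1] * 2L
    wc2 <- WindowCounts(rowRanges(wc), cts2, sex = colData(wc)$sex,
        genotype = colData(wc)$genotype, totalReads = tot2)
    st2 <- identifyStaticSites(ndM, ndF, wc2)
    expect_identical(granges(staticSites(st2)), granges(staticSites(st)))
    f1 <- scalingFactors(st); f2 <- scalingFactors(st2)
    expect_equal(unname(f2[1] / f1[1]), 2)
    expect_equal(unname(f2[-1]), unname(f1[-1]))
    n1 <- normalizeCounts(wc, f1); n2 <- normalizeCounts(wc2, f2)
    expect_equal(n2, n1)
})

test_that("normalization comparisons report both overlap directions", {
    a <- gr1(c(1, 100, 200), c(50, 150, 250))
    expect_equal(unname(compareNormalizations(a, a)), c(1, 1))
    b <- gr1(1000, 1100)
    expect_equal(unname(compareNormalizations(a, b)), c(0, 0))
    # toy case against an O(n^2) pairwise check
    withr::with_seed(43, {
        sx <- sample(2000, 30)
        x <- gr1(sx, sx + sample(10:80, 30, replace = TRUE))
        sy <- sample(2000, 20)
        y <- gr1(sy, sy + sample(10:80, 20, replace = TRUE))
        got <- compareNormalizations(x, y)
        ovAB <- vapply(seq_along(x), function(i)
            any(start(x)[i] <= end(y) & start(y) <= end(x)[i]),
            logical(1))
        ovBA <- vapply(seq_along(y), function(i)
            any(start(y)[i] <= end(x) & start(x) <= end(y)[i]),
            logical(1))
        expect_equal(unname(got), c(mean(ovAB), mean(ovBA)))
    })
})
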