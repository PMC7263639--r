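test_that("a lone gene gets the full basal-plus-extension domain", {
    # plus-strand TSS at 0-based 5,000,000 on a 10 Mb chromosome
    g <- toyGenes(starts = 5000001, lengths = 20000, strands = "+",
        chromLen = 1e7)
    d <- buildRegulatoryDomains(g)
    expect_equal(d$basal_start, 5000001 - 5000)
    expect_equal(d$basal_end, 5000001 + 999)
    expect_equal(start(d), 5000001 - 1e6)
    expect_equal(end(d), 5000001 + 1e6 - 1)
    # minus strand: basal spans TSS+5000 down to TSS-1000 genomically
    gm <- toyGenes(starts = 5000001, lengths = 20000, strands = "-",
        chromLen = 1e7)
    dm <- buildRegulatoryDomains(gm)
    tss <- 5000001 + 20000 - 1
    expect_equal(dm$basal_start, tss - 999)
    expect_equal(dm$basal_end, tss + 5000)
    gBad <- suppressWarnings(toyGenes(2e7, 100, chromLen = 1e6))
    expect_error(buildRegulatoryDomains(gBad), "outside")
})

test_that("neighbouring genes truncate each other's extensions", {
    g <- toyGenes(starts = c(1000000, 1100000), lengths = c(5000, 5000),
        strands = c("+", "+"), chromLen = 5e6)
    d <- buildRegulatoryDomains(g)
    # gene 1 extension stops at gene 2's basal start; and vice versa
    expect_equal(end(d)[1], 1100000 - 5000 - 1)
    expect_equal(start(d)[2], 1000000 + 1000)
    # the two extended domains do not overlap the other's basal domain
    expect_lt(end(d)[1], d$basal_start[2])
    expect_gt(start(d)[2], d$basal_end[1])
})

test_that("extended domains match the per-base oracle on toy genomes", {
    withr::with_seed(53, {
        for (rep in 1:8) {
            n <- sample(2:10, 1)
            chromLen <- 300000L
            starts <- sort(sample(seq(20000L, 260000L), n))
            lens <- sample(500:8000, n, replace = TRUE)
            g <- toyGenes(starts = starts, lengths = lens,
                strands = sample(c("+", "-"), n, replace = TRUE),
                chromLen = chromLen)
            d <- buildRegulatoryDomains(g, maxExtension = 50000)
            oracle <- greatOracle(g, chromLen, maxExt = 50000)
            for (i in seq_len(n)) {
                mask <- logical(chromLen)
                mask[start(d)[i]:end(d)[i]] <- TRUE
                # outside its own basal, the domain may not cover bases
                # the oracle assigns to nobody or excludes for this gene
                expect_equal(which(mask), which(oracle[[i]]),
                    label = sprintf("rep %d gene %d", rep, i))
            }
        }
    })
})

test_that("enhancer sites map to all genes whose domains they touch", {
    g <- toyGenes(starts = c(1000000, 2300000), lengths = c(5000, 5000),
        strands = c("+", "-"), chromLen = 5e6)
    d <- buildRegulatoryDomains(g)
    # within 1 Mb of gene 1's TSS only: exclusive association
    a1 <- mapEnhancerMarks(gr1(1050000, 1050100), d)
    expect_identical(a1$gene, "g001")
    # beyond 1 Mb of both TSSs: no association
    a2 <- mapEnhancerMarks(gr1(4000000, 4000100), d)
    expect_equal(nrow(a2), 0L)
    # neighbouring genes extend toward each other across the gap, so a
    # mid-gap site within 1 Mb of both maps to both (multi-assignment)
    gNear <- toyGenes(starts = c(1000000, 1150000),
        lengths = c(5000, 5000), strands = c("+", "-"), chromLen = 5e6)
    dNear <- buildRegulatoryDomains(gNear)
    a3 <- mapEnhancerMarks(gr1(1050000, 1050100), dNear)
    expect_setequal(a3$gene, c("g001", "g002"))
})

test_that("H3K27me3 sites map by gene body or TSS window", {
    g <- toyGenes(starts = 100000, lengths = 20000, strands = "+",
        chromLen = 1e6)
    expect_identical(mapK27me3ToGenes(gr1(110000, 110500), g)$gene,
        "g001")                                     # internal
    expect_identical(mapK27me3ToGenes(gr1(97400, 97600), g)$gene,
        "g001")                                     # 2.5 kb upstream
    expect_equal(nrow(mapK27me3ToGenes(gr1(130000, 130200), g)), 0L)
    # 10 kb downstream of the TES: not associated
    # monotonicity: adding a site never removes existing associations
    s1 <- gr1(110000, 110500)
    s2 <- c(s1, gr1(97400, 97600))
    a1 <- mapK27me3ToGenes(s1, g); a2 <- mapK27me3ToGenes(s2, g)
    expect_true(all(paste(a1$gene, start(s1)[a1$site]) %in%
        paste(a2$gene, start(s2)[a2$site])))
})

test_that("the eight mark-pattern groups form a bijection", {
    flags <- expand.grid(k27 = c(FALSE, TRUE), ac = c(FALSE, TRUE),
        me = c(FALSE, TRUE))
    groups <- classifyMarkGroup(flags$k27, flags$ac, flags$me)
    expect_setequal(groups, 1:8)
    expect_equal(length(unique(groups)), 8L)
    expect_equal(classifyMarkGroup(FALSE, FALSE, FALSE), 1L)
    expect_equal(classifyMarkGroup(TRUE, TRUE, TRUE), 2L)
    expect_equal(classifyMarkGroup(TRUE, FALSE, TRUE), 3L)
    expect_equal(classifyMarkGroup(TRUE, TRUE, FALSE), 4L)
    expect_equal(classifyMarkGroup(TRUE, FALSE, FALSE), 5L)
    expect_equal(classifyMarkGroup(FALSE, TRUE, TRUE), 6L)
    expect_equal(classifyMarkGroup(FALSE, TRUE, FALSE), 7L)
    expect_equal(classifyMarkGroup(FALSE, FALSE, TRUE), 8L)
})

test_that("gene mark flags combine the three site lists", {
    g <- toyGenes(starts = c(100000, 300000, 500000),
        lengths = rep(10000, 3), chromLen = 1e6)
    d <- buildRegulatoryDomains(g)
    mkSites <- function(s, e, dir) {
        x <- gr1(s, e); mcols(x)$direction <- dir; x
    }
    k27 <- mkSites(c(102000, 302000), c(104000, 304000),
        c("down", "up"))
    # enhancer sites placed inside the owning gene's basal domain, where
    # no neighbour's extension reaches
    ac <- mkSites(99000, 99500, "up")
    me <- mkSites(496000, 496500, "up")
    mf <- geneMarkFlags(g$gene_id, k27, ac, me, g, d)
    f <- mf$flags
    expect_identical(f$group[f$gene == "g001"], 4L)  # k27 down + ac up
    expect_identical(f$group[f$gene == "g002"], 1L)  # only an up k27 site
    expect_identical(f$group[f$gene == "g003"], 8L)  # k4me1 only
    expect_equal(length(mf$conflicts), 0L)
    # opposing sites at one gene are reported as conflicts
    k27b <- mkSites(c(102000, 104500), c(104000, 106000),
        c("down", "up"))
    mfb <- geneMarkFlags(g$gene_id, k27b, ac, me, g, d)
    expect_identical(mfb$conflicts, "g001")
    expect_true(mfb$flags$k27me3_down[mfb$flags$gene == "g001"])
})

test_that("group distributions tally counts and fractions per set", {
    flags <- data.frame(gene = sprintf("g%02d", 1:10),
        k27me3_down = FALSE, k27ac_up = FALSE, k4me1_up = FALSE,
        group = c(1L, 1L, 2L, 5L, 1L, 8L, 1L, 1L, 2L, 5L))
    sets <- list(all = flags$gene, firstFive = flags$gene[1:5])
    gd <- groupDistribution(flags, sets)
    allRows <- gd[gd$set == "all", ]
    expect_equal(sum(allRows$count), 10L)
    expect_equal(sum(allRows$fraction), 1)
    expect_equal(allRows$count[allRows$group == 1], 5L)
    five <- gd[gd$set == "firstFive", ]
    expect_equal(sum(five$count), 5L)
    expect_equal(five$fraction[five$group == 1], 3 / 5)
    # a set of genes all (0,0,0) is 100% group 1
    pure <- groupDistribution(
        data.frame(gene = "x", k27me3_down = FALSE, k27ac_up = FALSE,
            k4me1_up = FALSE, group = 1L), list(s = "x"))
    expect_equal(pure$fraction[pure$group == 1], 1)
})
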