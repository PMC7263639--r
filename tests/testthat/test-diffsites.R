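# small deterministic WindowCounts builder: one chromosome of uniform
# bins with prescribed per-group bin means, Poisson noise
makeTrack <- function(mu, reps = 4L, binWidth = 100L, seed = 1,
        dispersion = 0) {
    nb <- nrow(mu)
    bins <- gr1((seq_len(nb) - 1L) * binWidth + 1L,
        (seq_len(nb)) * binWidth)
    withr::with_seed(seed, {
        m <- mu[, rep(seq_len(ncol(mu)), each = reps)]
        counts <- if (dispersion == 0) {
            matrix(rpois(length(m), m), nb)
        } else {
            matrix(rnbinom(length(m), mu = m, size = 1 / dispersion), nb)
        }
    })
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    WindowCounts(bins, counts,
        sex = rep("M", ncol(counts)),
        genotype = rep(c("control", "KO"), each = reps),
        totalReads = pmax(rep(round(mean(colSums(counts)) / 0.8),
            ncol(counts)), colSums(counts)))
}

test_that("window tiling follows the step grid and rejects bad configs", {
    mu <- matrix(20, nrow = 200, ncol = 2)
    wc <- makeTrack(mu)
    scan <- scanDifferentialWindows(wc, 1:4, 5:8,
        windowSizes = c(1000L, 2000L))
    w1 <- scan$windows[["1000"]]
    expect_true(all((start(w1) - start(w1)[1]) %% 100L == 0L))
    expect_true(all(width(w1) == 1000L))
    w2 <- scan$windows[["2000"]]
    expect_true(all((start(w2) - start(w2)[1]) %% 200L == 0L))
    # every interior base is covered by window/step = 10 windows
    cov <- GenomicRanges::coverage(w1)[[1]]
    expect_equal(max(S4Vectors::runValue(cov)), 10L)
    expect_error(scanDifferentialWindows(wc, 1:4, 5:8,
        windowSizes = 1050L), "multiple")
    expect_error(scanDifferentialWindows(wc, 1L, 2:8), "2 replicates")
})

test_that("identical groups yield no filtered differential sites", {
    mu <- matrix(30, nrow = 400, ncol = 2)   # flat track, no effects
    wc <- makeTrack(mu, seed = 5)
    scan <- scanDifferentialWindows(wc, 1:4, 5:8)
    sites <- filterSites(consolidateRegions(scan$regions))
    expect_equal(length(sites), 0L)
})

test_that("an 8-fold spiked region is found at every window size", {
    # 2 kb spike (bins 101..120) at mean 40/bin over background 4
    mu <- matrix(4, nrow = 400, ncol = 2)
    mu[101:120, 1] <- 40; mu[101:120, 2] <- 5
    wc <- makeTrack(mu, seed = 9)
    scan <- scanDifferentialWindows(wc, 1:4, 5:8)
    spike <- gr1(10001, 12000)
    for (w in c("1000", "2000", "5000", "10000")) {
        wins <- scan$windows[[w]]
        hitP <- wins$PValue[overlapsAny(wins, spike, type = "within") |
            overlapsAny(spike, wins, type = "within")]
        expect_true(any(hitP < 1e-4), label = paste("window size", w))
    }
    # the merged candidate region covers the spike at each size
    for (w in unique(scan$regions$windowSize)) {
        reg <- scan$regions[scan$regions$windowSize == w]
        ov <- GenomicRanges::intersect(granges(reg), spike)
        expect_equal(sum(width(ov)), width(spike),
            label = paste("coverage at", w))
    }
    # direction: spike is higher in group A, so logFC (B over A) < 0
    expect_true(all(scan$regions$direction == "down"))
    # candidate boundaries lie on the step grid of their window size
    for (w in unique(scan$regions$windowSize)) {
        reg <- scan$regions[scan$regions$windowSize == w]
        expect_true(all((start(reg) - 1L) %% (w / 10) == 0L))
    }
})

test_that("consolidation keeps the largest window's record", {
    mk <- function(s, e, w, fc, p, dir) {
        g <- gr1(s, e)
        mcols(g)$windowSize <- w; mcols(g)$logFC <- fc
        mcols(g)$PValue <- p; mcols(g)$direction <- dir
        g
    }
    regs <- c(
        mk(1000, 2000, 1000, 2.5, 1e-8, "up"),
        mk(900, 6000, 5000, 2.1, 1e-6, "up"),    # same locus, larger window
        mk(9000, 11000, 2000, 3.0, 1e-9, "up"),  # unique to 2 kb
        mk(1500, 2500, 1000, -2.2, 1e-7, "down")) # opposite direction
    cons <- consolidateRegions(regs)
    expect_equal(length(cons), 3L)
    up1 <- cons[cons$direction == "up" & start(cons) == 900]
    expect_equal(up1$windowSize, 5000)
    expect_equal(up1$logFC, 2.1)
    expect_true(any(start(cons) == 9000 & cons$windowSize == 2000))
    expect_true(any(cons$direction == "down"))
    # idempotent and order-independent
    expect_identical(consolidateRegions(cons), cons)
    perm <- regs[c(3, 1, 4, 2)]
    expect_identical(consolidateRegions(perm), cons)
})

test_that("consolidation equals the connected-component oracle", {
    withr::with_seed(47, {
        for (i in 1:60) {
            n <- sample(2:25, 1)
            s <- sample(5000, n, replace = TRUE)
            df <- data.frame(start = s,
                end = s + sample(50:800, n, replace = TRUE),
                windowSize = sample(c(1000, 2000, 5000, 10000), n,
                    replace = TRUE),
                PValue = runif(n, 0, 1e-4),
                logFC = runif(n, 1.5, 4) *
                    sample(c(-1, 1), n, replace = TRUE))
            df$direction <- ifelse(df$logFC > 0, "up", "down")
            g <- gr1(df$start, df$end)
            mcols(g) <- df[, c("windowSize", "logFC", "PValue",
                "direction")]
            cons <- consolidateRegions(g)
            keep <- consolidateOracle(df)
            want <- sort(g[keep])
            expect_identical(granges(cons), granges(want))
            expect_equal(cons$PValue, want$PValue)
        }
    })
})

test_that("site filters apply strict FDR and fold-change cutoffs", {
    mk <- function(fc, p) {
        g <- gr1(1000, 2000)
        mcols(g)$windowSize <- 1000; mcols(g)$logFC <- log2(abs(fc)) *
            sign(fc)
        mcols(g)$PValue <- p
        mcols(g)$direction <- ifelse(fc > 0, "up", "down")
        g
    }
    expect_equal(length(filterSites(mk(2.5, 0.01))), 1L)
    expect_equal(filterSites(mk(2.5, 0.01))$direction, "up")
    expect_equal(length(filterSites(mk(1.8, 0.01))), 0L)
    expect_equal(length(filterSites(mk(-3, 0.2))), 0L)
    expect_equal(length(filterSites(mk(-3, 0.01))), 1L)
    expect_equal(filterSites(mk(-3, 0.01))$direction, "down")
})

test_that("peak-overlap filtering keeps any-overlap sites", {
    sites <- gr1(c(1000, 5000, 9000), c(1999, 5999, 9999))
    mcols(sites)$direction <- "up"
    peaks <- gr1(c(1200, 5999), c(1500, 6500))  # inside; 1 bp overlap
    kept <- macsOverlapFilter(sites, peaks)
    expect_equal(start(kept), c(1000, 5000))
    expect_warning(all <- macsOverlapFilter(sites, NULL), "unfiltered")
    expect_identical(all, sites)
})

test_that("sites are annotated by the priority category order", {
    genes <- toyGenes(starts = c(50000, 200000), lengths = c(10000, 5000),
        strands = c("+", "-"), chromLen = 5e5)
    site <- function(s, e) gr1(s, e)
    ann <- annotateSites(c(
        site(49800, 49900),    # 100 bp upstream of TSS -> ProximalPromoter
        site(47900, 48100),    # ~2 kb upstream -> Promoter3k
        site(54000, 54500),    # mid-gene -> Genebody
        site(204800, 204900),  # 100 bp from minus-strand TSS (at 205000)
        site(300000, 300500)), # far from everything
        genes, genedeserts = gr1(299000, 310000))
    expect_identical(ann$category,
        c("ProximalPromoter", "Promoter3k", "Genebody",
          "ProximalPromoter", "Genedesert"))
    expect_identical(ann$gene[1:4], c("g001", "g001", "g001", "g002"))
    expect_true(is.na(ann$gene[5]))
    # without the desert annotation the last site is OtherIntergenic
    ann2 <- annotateSites(site(300000, 300500), genes)
    expect_identical(ann2$category, "OtherIntergenic")
    expect_error(annotateSites(gr1(1, 10, chrom = "chrZ"), genes),
        "unknown chromosome")
})

test_that("sex-biased site direction labels flip with the group order", {
    mu <- matrix(4, nrow = 300, ncol = 2)
    mu[101:120, 1] <- 40; mu[101:120, 2] <- 5   # higher in group 1
    wc <- makeTrack(mu, seed = 13)
    # scan with A = group2, B = group1: spike is up
    sAB <- differentialSites(wc, 5:8, 1:4, windowSizes = c(1000L, 2000L))
    sBA <- differentialSites(wc, 1:4, 5:8, windowSizes = c(1000L, 2000L))
    expect_true(all(sAB$direction == "up"))
    expect_true(all(sBA$direction == "down"))
    expect_equal(callSexBiasedSites(sAB),
        c(male = length(sAB), female = 0L))
    expect_equal(callSexBiasedSites(sBA,
        labels = c(up = "female", down = "male")),
        c(male = length(sBA), female = 0L))
})
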