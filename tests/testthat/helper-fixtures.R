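# Shared fixtures for the test suite. Everything is generated in code;
# sizes are kept small so individual files run in seconds.

# a small but complete configuration for unit tests
tinyConfig <- function(seed = 42L, ...) {
    args <- list(nGenes = 200L, nWindows = 4000L,
        nStaticRegions = 8L, nMaleBiasedRegions = 5L,
        nKoLostRegions = 5L, nWeakRegions = 20L, seed = seed)
    do.call(simConfig, utils::modifyList(args, list(...)))
}

# gene models on one chromosome from start positions / lengths / strands
toyGenes <- function(starts, lengths, strands = "+", chrom = "chr1",
        chromLen = max(starts + lengths) + 2e6) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(starts, width = lengths),
        strand = rep_len(strands, length(starts)))
    S4Vectors::mcols(gr)$gene_id <- sprintf("g%03d", seq_along(starts))
    GenomeInfoDb::seqlengths(gr) <- chromLen
    gr
}

# GRanges from 1-based start/end vectors
gr1 <- function(starts, ends, chrom = "chr1") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

# a fake differential-expression table with the given statistics
fakeDe <- function(genes, logFC = 0, FDR = 1, PValue = FDR) {
    data.frame(gene = genes,
        logFC = rep_len(logFC, length(genes)),
        PValue = rep_len(PValue, length(genes)),
        FDR = rep_len(FDR, length(genes)),
        row.names = genes, stringsAsFactors = FALSE)
}

# brute-force Benjamini-Hochberg, written independently of p.adjust
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
}

# per-base boolean-mask union of intervals on one chromosome
maskUnionOracle <- function(starts, ends, len) {
    mask <- logical(len)
    for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
    r <- rle(mask)
    stops <- cumsum(r$lengths)
    begins <- stops - r$lengths + 1L
    cbind(start = begins[r$values], end = stops[r$values])
}

# brute-force consolidation: connected components of same-direction
# overlapping regions, keeping the largest window size (ties: smallest p,
# then leftmost)
consolidateOracle <- function(df) {
    keep <- integer(0)
    for (dir in unique(df$direction)) {
        idx <- which(df$direction == dir)
        n <- length(idx)
        adj <- matrix(FALSE, n, n)
        for (i in seq_len(n)) for (j in seq_len(n)) {
            adj[i, j] <- df$start[idx[i]] <= df$end[idx[j]] &&
                df$start[idx[j]] <= df$end[idx[i]]
        }
        comp <- seq_len(n)
        repeat {
            changed <- FALSE
            for (i in seq_len(n)) for (j in seq_len(n)) {
                if (adj[i, j] && comp[j] != comp[i]) {
                    comp[comp == comp[j]] <- comp[i]
                    changed <- TRUE
                }
            }
            if (!changed) break
        }
        for (cc in unique(comp)) {
            mem <- idx[comp == cc]
            o <- mem[order(-df$windowSize[mem], df$PValue[mem],
                df$start[mem])]
            keep <- c(keep, o[1L])
        }
    }
    sort(keep)
}

# exhaustive two-sided Fisher p from first principles: enumerate every
# table with the observed margins via choose(), sum the probabilities of
# tables no more probable than the observed one
fisherOracle <- function(A, B, C, D) {
    m <- A + B; n <- C + D; k <- A + C
    lo <- max(0L, k - n); hi <- min(k, m)
    probs <- vapply(lo:hi, function(x)
        exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
        numeric(1))
    obs <- probs[A - lo + 1L]
    min(sum(probs[probs <= obs * (1 + 1e-7)]), 1)
}

# per-base GREAT assignment oracle: a base belongs to a gene's extended
# domain iff it is in the basal domain, or lies between the basal domain
# and the nearest other basal boundary in that direction, within 1 Mb of
# the TSS
greatOracle <- function(genes, chromLen, basalUp = 5000, basalDown = 1000,
        maxExt = 1e6) {
    n <- length(genes)
    minus <- as.vector(GenomicRanges::strand(genes) == "-")
    tss <- ifelse(minus, GenomicRanges::end(genes),
        GenomicRanges::start(genes))
    bs <- pmax(ifelse(minus, tss - basalDown + 1, tss - basalUp), 1)
    be <- pmin(ifelse(minus, tss + basalUp, tss + basalDown - 1), chromLen)
    pos <- seq_len(chromLen)
    owner <- vector("list", n)
    for (i in seq_len(n)) {
        others <- logical(chromLen)
        for (j in seq_len(n)[-i]) others[bs[j]:be[j]] <- TRUE
        # nearest other-basal base at or left / at or right of each base
        lastBlock <- cummax(ifelse(others, pos, 0L))
        nextBlock <- chromLen + 1L -
            rev(cummax(rev(ifelse(others, chromLen + 1L - pos, 0L))))
        basal <- pos >= bs[i] & pos <= be[i]
        leftExt <- pos < bs[i] & pos >= tss[i] - maxExt &
            nextBlock >= bs[i]
        rightExt <- pos > be[i] & pos <= tss[i] + maxExt - 1 &
            lastBlock <= be[i]
        owner[[i]] <- basal | leftExt | rightExt
    }
    owner
}
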