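#' Merge peak lists into a peak union
#'
#' Collapses any number of peak lists into the minimal set of maximal
#' non-overlapping intervals covering their union. Touching intervals
#' (one starting where the other ends, in 0-based half-open terms) are
#' merged, matching the semantics of interval-merge tools.
#'
#' @param ... `GRanges` objects, a single `GRangesList`, or a list of
#'   `GRanges`.
#' @return sorted, disjoint `GRanges` covering the union.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(21, 30))
#' mergePeakUnion(a, b)   # one interval, 11..30
#' @export
mergePeakUnion <- function(...) {
    args <- list(...)
    if (length(args) == 1L && (is.list(args[[1L]]) ||
        is(args[[1L]], "GRangesList")))
        args <- as.list(args[[1L]])
    bad <- !vapply(args, function(x) is(x, "GRanges"), logical(1))
    if (any(bad)) stop("all peak lists must be GRanges")
    gr <- do.call(c, lapply(args, granges))
    GenomicRanges::reduce(sort(gr), min.gapwidth = 1L)
}

#' Reads-in-peaks-per-million scaling factors
#'
#' For each sample, the reads falling inside the peak union divided by one
#' million gives the RiPPM scaling factor; normalized counts are raw
#' counts divided by the factor.
#'
#' @param wc a [WindowCounts-class] object.
#' @param union peak-union `GRanges` (e.g. from [mergePeakUnion()]).
#' @return numeric vector of per-sample factors.
#' @export
rippmFactors <- function(wc, union) {
    if (length(union) == 0L) stop("peak union is empty")
    inPeak <- overlapsAny(rowRanges(wc), union)
    reads <- colSums(assay(wc, "counts")[inPeak, , drop = FALSE])
    if (any(reads == 0))
        stop("sample(s) with zero in-peak reads cannot be normalized: ",
            paste(colnames(wc)[reads == 0], collapse = ", "))
    setNames(reads / 1e6, colnames(wc))
}

#' Normalize window counts by per-sample scaling factors
#'
#' @param wc a [WindowCounts-class] object.
#' @param factors per-sample factors ([rippmFactors()] or
#'   [scalingFactors()] of a static-site set).
#' @return matrix of normalized counts.
#' @export
normalizeCounts <- function(wc, factors) {
    t(t(assay(wc, "counts")) / factors)
}

#' Reciprocal overlap test between intervals
#'
#' Two intervals reciprocally overlap at fraction `frac` when their
#' overlap length is at least `frac` times the length of each. Given two
#' `GRanges`, returns the pairs satisfying the criterion.
#'
#' @param a,b `GRanges`.
#' @param frac required fraction of both lengths (default 0.8).
#' @return a `Hits` object of qualifying pairs (query in `a`, subject in
#'   `b`).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150))
#' length(reciprocalOverlap(a, b, 0.8)) == 0   # overlap 50 < 80
#' @export
reciprocalOverlap <- function(a, b, frac = 0.8) {
    hits <- findOverlaps(a, b)
    if (length(hits) == 0L) return(hits)
    ov <- width(pintersect(a[queryHits(hits)], b[subjectHits(hits)]))
    keep <- ov >= frac * width(a[queryHits(hits)]) &
        ov >= frac * width(b[subjectHits(hits)])
    hits[keep]
}

#' Identify static H3K27me3 sites and derive scaling factors
#'
#' The static-site cascade finds regions whose H3K27me3 signal is
#' invariant across individuals and genotypes, then uses the reads in
#' those regions as an internal normalization anchor:
#' \enumerate{
#'   \item pair the stringently non-differential sites from the male and
#'     the female knockout-vs-control comparisons by >= 80% reciprocal
#'     overlap and keep the intersection interval of each pair;
#'   \item rank the survivors by mean raw read count across all samples
#'     and keep the top 35%;
#'   \item compute per-sample RPM (reads per million total reads), and
#'     keep the 75% of sites with the lowest coefficient of variation;
#'   \item per-sample scaling factor = reads in retained sites / 1e6.
#' }
#' Percentile cuts keep `floor(k * n)` sites, ties broken by genomic
#' coordinate.
#'
#' @param nondiffM,nondiffF `GRanges` of stringently non-differential
#'   sites from the two same-sex comparisons (see
#'   [stringentNondiffSites()]).
#' @param wc the [WindowCounts-class] object covering them.
#' @param recipFrac reciprocal-overlap fraction for pairing.
#' @param topCountFrac fraction retained by the read-count rank filter.
#' @param keepLowCvFrac fraction retained by the variability filter.
#' @return a [StaticSiteSet-class] with sites, factors and audit counts.
#' @export
identifyStaticSites <- function(nondiffM, nondiffF, wc, recipFrac = 0.8,
        topCountFrac = 0.35, keepLowCvFrac = 0.75) {
    hits <- reciprocalOverlap(nondiffM, nondiffF, recipFrac)
    if (length(hits) == 0L)
        stop("static-site cascade: no reciprocally overlapping pairs")
    paired <- pintersect(nondiffM[queryHits(hits)],
        nondiffF[subjectHits(hits)])
    paired <- sort(unique(granges(paired)))
    audit <- data.frame(stage = "reciprocal-overlap pairing",
        n = length(paired))

    counts <- assay(wc, "counts")
    siteCounts <- function(sites) {
        ov <- findOverlaps(rowRanges(wc), sites)
        out <- matrix(0, length(sites), ncol(wc),
            dimnames = list(NULL, colnames(wc)))
        agg <- rowsum(counts[queryHits(ov), , drop = FALSE],
            subjectHits(ov))
        out[as.integer(rownames(agg)), ] <- agg
        out
    }
    sc <- siteCounts(paired)
    keepN <- floor(topCountFrac * length(paired))
    if (keepN == 0L) stop("static-site cascade: count filter empties set")
    ord <- order(-rowMeans(sc), as.integer(seqnames(paired)),
        start(paired))
    top <- sort(paired[ord[seq_len(keepN)]])
    audit <- rbind(audit, data.frame(stage = "top mean-read-count filter",
        n = length(top)))

    scTop <- siteCounts(top)
    rpm <- t(t(scTop) / (colData(wc)$totalReads / 1e6))
    cv <- apply(rpm, 1L, function(v) sd(v) / mean(v))
    keepN2 <- floor(keepLowCvFrac * length(top))
    if (keepN2 == 0L)
        stop("static-site cascade: variability filter empties set")
    ord2 <- order(cv, as.integer(seqnames(top)), start(top))
    retained <- sort(top[ord2[seq_len(keepN2)]])
    audit <- rbind(audit, data.frame(stage = "least-variant (CV) filter",
        n = length(retained)))

    reads <- colSums(siteCounts(retained))
    if (any(reads == 0))
        stop("static-site cascade: sample with zero reads in static sites")
    new("StaticSiteSet", sites = retained,
        factors = setNames(reads / 1e6, colnames(wc)), audit = audit)
}

#' Overlap fraction between two differential site sets
#'
#' Fraction of sites in each set overlapping (by at least one base) any
#' site of the other; used to compare site calls under different
#' normalizations.
#'
#' @param a,b `GRanges` of differential sites.
#' @return named numeric vector `c(a_in_b, b_in_a)`.
#' @export
compareNormalizations <- function(a, b) {
    c(a_in_b = if (length(a)) mean(overlapsAny(a, b)) else NA_real_,
      b_in_a = if (length(b)) mean(overlapsAny(b, a)) else NA_real_)
}
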