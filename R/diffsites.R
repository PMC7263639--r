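#' Scan tiled windows for differential histone-mark signal
#'
#' Tiles the covered genome with windows of each requested size (step =
#' 1/10 of the window size), aggregates bin counts into windows, tests each
#' window for a difference between the two groups with the shared NB exact
#' test under a common dispersion, and merges adjacent significant windows
#' of the same size and direction into candidate regions.
#'
#' Normalization: when `normFactors` (e.g. RiPPM or static-site factors)
#' are supplied they define the effective library sizes; otherwise total
#' mapped reads are used.
#'
#' @param wc a [WindowCounts-class] object whose bins evenly divide the
#'   window steps.
#' @param groupA,groupB sample selections (named lists over `colData`
#'   columns, or column indices).
#' @param windowSizes window widths in bp (default 1, 2, 5 and 10 kb).
#' @param pCutoff per-window p-value cutoff for significance (default
#'   1e-4).
#' @param normFactors optional per-sample scaling factors.
#' @param dispersion optional fixed NB dispersion; estimated from all
#'   windows when `NULL`.
#' @return a list of class `windowScan`: `windows` (per size, `GRanges`
#'   with `logFC`/`PValue`; `logFC` is log2 of group B over group A),
#'   `regions` (`GRanges` of merged significant regions with `windowSize`,
#'   `logFC`, `PValue`, `direction`), and `params`.
#' @export
scanDifferentialWindows <- function(wc, groupA, groupB,
        windowSizes = c(1000L, 2000L, 5000L, 10000L), pCutoff = 1e-4,
        normFactors = NULL, dispersion = NULL) {
    bins <- rowRanges(wc)
    binW <- unique(width(bins))
    if (length(binW) != 1L)
        stop("bins must have uniform width")
    if (any(windowSizes %% 10L != 0L) ||
        any((windowSizes %/% 10L) %% binW != 0L))
        stop("window step (windowSize/10) must be a multiple of the bin width")
    idxA <- groupColumns(wc, groupA)
    idxB <- groupColumns(wc, groupB)
    if (length(idxA) < 2L || length(idxB) < 2L)
        stop("each group needs at least 2 replicates")
    counts <- assay(wc, "counts")[, c(idxA, idxB), drop = FALSE]
    lib <- colData(wc)$totalReads[c(idxA, idxB)]
    if (!is.null(normFactors)) {
        nf <- normFactors[c(idxA, idxB)]
        lib <- nf * 1e6
    }
    nA <- length(idxA); nB <- length(idxB)
    jA <- seq_len(nA); jB <- nA + seq_len(nB)

    perSize <- lapply(windowSizes, function(w) {
        step <- w %/% 10L
        winList <- list(); cntList <- list()
        for (chr in seqlevels(bins)) {
            b <- bins[seqnames(bins) == chr]
            if (length(b) == 0L) next
            lo <- min(start(b)); hi <- max(end(b))
            if (hi - lo + 1L < w) next
            starts <- seq(lo, hi - w + 1L, by = step)
            wins <- GRanges(chr, IRanges(starts, width = w))
            ov <- findOverlaps(bins, wins, type = "within")
            m <- matrix(0, length(wins), ncol(counts))
            agg <- rowsum(counts[queryHits(ov), , drop = FALSE],
                subjectHits(ov))
            m[as.integer(rownames(agg)), ] <- agg
            winList[[chr]] <- wins; cntList[[chr]] <- m
        }
        if (length(winList) == 0L)
            stop("no chromosome long enough for window size ", w)
        wins <- unlist(GenomicRanges::GRangesList(winList),
            use.names = FALSE)
        m <- do.call(rbind, cntList)
        y <- pseudoCounts(m, lib, rep(1, length(lib)))
        phi <- if (is.null(dispersion))
            estimateDispersion(y, list(jA, jB))$common else dispersion
        sA <- rowSums(y[, jA, drop = FALSE])
        sB <- rowSums(y[, jB, drop = FALSE])
        pv <- vapply(seq_along(sA), function(i) {
            if (sA[i] + sB[i] < 0.5) return(1)
            exactNbPvalue(sA[i], sB[i], nA, nB, phi)
        }, numeric(1))
        mcols(wins)$logFC <- ifelse(sA + sB < 0.5, 0,
            log2((sB / nB + 0.5) / (sA / nA + 0.5)))
        mcols(wins)$PValue <- pv
        wins
    })
    names(perSize) <- as.character(windowSizes)

    regions <- lapply(windowSizes, function(w) {
        wins <- perSize[[as.character(w)]]
        sig <- wins[wins$PValue < pCutoff & wins$logFC != 0]
        if (length(sig) == 0L) return(GRanges())
        out <- lapply(c(1, -1), function(dir) {
            s <- sig[sign(sig$logFC) == dir]
            if (length(s) == 0L) return(GRanges())
            merged <- GenomicRanges::reduce(s, min.gapwidth = 1L)
            hit <- findOverlaps(s, merged)
            best <- vapply(split(queryHits(hit), subjectHits(hit)),
                function(i) i[which.min(s$PValue[i])], integer(1))
            mcols(merged)$windowSize <- w
            mcols(merged)$logFC <- s$logFC[best]
            mcols(merged)$PValue <- s$PValue[best]
            mcols(merged)$direction <- if (dir > 0) "up" else "down"
            merged
        })
        out <- do.call(c, out[lengths(out) > 0])
        if (is.null(out)) GRanges() else out
    })
    regions <- do.call(c, regions[lengths(regions) > 0])
    regions <- if (is.null(regions)) GRanges() else sort(regions)
    structure(list(windows = perSize, regions = regions,
        params = list(windowSizes = windowSizes, pCutoff = pCutoff,
            nA = nA, nB = nB)),
        class = "windowScan")
}

#' @export
print.windowScan <- function(x, ...) {
    cat("windowScan:", length(x$regions), "candidate regions from window",
        "sizes", paste(x$params$windowSizes, collapse = "/"), "bp\n")
    invisible(x)
}

#' Consolidate candidate regions across window sizes
#'
#' Regions discovered at two or more window sizes that overlap (same
#' direction) collapse to a single record keeping the interval and
#' statistics of the largest window size; regions unique to one window
#' size pass through unchanged. The output carries no two overlapping
#' records of the same direction.
#'
#' @param regions `GRanges` with `windowSize`, `logFC`, `PValue`,
#'   `direction` metadata (the `regions` slot of one or more scans,
#'   concatenated).
#' @return consolidated, sorted `GRanges` with the same metadata columns.
#' @export
consolidateRegions <- function(regions) {
    if (length(regions) == 0L) return(regions)
    keepIdx <- integer(0)
    for (dir in unique(regions$direction)) {
        idx <- which(regions$direction == dir)
        r <- regions[idx]
        comp <- overlapComponents(r)
        for (members in split(seq_along(r), comp)) {
            o <- members[order(-r$windowSize[members],
                r$PValue[members], start(r[members]))]
            keepIdx <- c(keepIdx, idx[o[1L]])
        }
    }
    sort(regions[keepIdx])
}

# Connected components of the interval-overlap graph, via union-find.
overlapComponents <- function(gr) {
    parent <- seq_along(gr)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    hits <- findOverlaps(gr, gr)
    for (k in seq_along(hits)) {
        a <- find(queryHits(hits)[k]); b <- find(subjectHits(hits)[k])
        if (a != b) parent[a] <- b
    }
    vapply(seq_along(gr), find, integer(1))
}

#' Filter consolidated regions into differential sites
#'
#' Benjamini-Hochberg FDR is computed across all supplied regions, and
#' sites passing `FDR < fdrCutoff` and `|fold-change| > fcCutoff` (both
#' strict) are retained.
#'
#' @param regions consolidated `GRanges` from [consolidateRegions()].
#' @param fdrCutoff,fcCutoff thresholds (defaults 0.05 and 2).
#' @return `GRanges` of retained sites with an added `FDR` column.
#' @export
filterSites <- function(regions, fdrCutoff = 0.05, fcCutoff = 2) {
    if (length(regions) == 0L) {
        mcols(regions)$FDR <- numeric(0)
        return(regions)
    }
    mcols(regions)$FDR <- p.adjust(regions$PValue, "BH")
    regions[regions$FDR < fdrCutoff &
        abs(regions$logFC) > log2(fcCutoff)]
}

#' Retain differential sites overlapping called peaks
#'
#' For marks analysed against a peak-caller background (H3K27ac,
#' H3K4me1), differential sites must overlap at least one called peak by
#' one base or more. With `peaks = NULL` the sites pass through with a
#' warning (H3K27me3 mode, where no peak filter applies).
#'
#' @param sites `GRanges` of differential sites.
#' @param peaks `GRanges` of called peaks, or `NULL`.
#' @return filtered `GRanges`.
#' @export
macsOverlapFilter <- function(sites, peaks = NULL) {
    if (is.null(peaks)) {
        warning("no peaks supplied; sites passed through unfiltered")
        return(sites)
    }
    subsetByOverlaps(sites, peaks)
}

#' Stringently non-differential sites from a window scan
#'
#' Windows with `p > pMin` and `|fold-change| < fcMax` in a comparison
#' are merged (and optionally restricted to peak regions) to give the
#' candidate invariant sites consumed by the static-site cascade.
#'
#' @param scan a `windowScan` from [scanDifferentialWindows()].
#' @param peaks optional `GRanges`; when given, non-differential windows
#'   are intersected with the peaks so that only marked regions qualify.
#' @param windowSize which scan size to use (default: the smallest).
#' @param pMin,fcMax the stringent non-differential rule (defaults 0.1
#'   and 1.2).
#' @return `GRanges` of merged non-differential sites.
#' @export
stringentNondiffSites <- function(scan, peaks = NULL,
        windowSize = NULL, pMin = 0.1, fcMax = 1.2) {
    if (is.null(windowSize))
        windowSize <- min(scan$params$windowSizes)
    wins <- scan$windows[[as.character(windowSize)]]
    if (is.null(wins)) stop("window size ", windowSize, " not in scan")
    nd <- wins[wins$PValue > pMin & abs(wins$logFC) < log2(fcMax)]
    nd <- GenomicRanges::reduce(granges(nd), min.gapwidth = 1L)
    if (!is.null(peaks))
        nd <- GenomicRanges::intersect(nd, granges(peaks))
    sort(nd)
}

#' Full differential-site discovery for one comparison
#'
#' Convenience chain: scan windows at all sizes, consolidate across
#' sizes, optionally keep sites overlapping called peaks, then apply the
#' final FDR and fold-change filters.
#'
#' @inheritParams scanDifferentialWindows
#' @param peaks optional peak `GRanges` ([macsOverlapFilter()]); applied
#'   only when supplied.
#' @param fdrCutoff,fcCutoff final site filters.
#' @return `GRanges` of differential sites.
#' @export
differentialSites <- function(wc, groupA, groupB,
        windowSizes = c(1000L, 2000L, 5000L, 10000L), pCutoff = 1e-4,
        normFactors = NULL, dispersion = NULL, peaks = NULL,
        fdrCutoff = 0.05, fcCutoff = 2) {
    scan <- scanDifferentialWindows(wc, groupA, groupB, windowSizes,
        pCutoff, normFactors, dispersion)
    cons <- consolidateRegions(scan$regions)
    if (!is.null(peaks)) cons <- macsOverlapFilter(cons, peaks)
    filterSites(cons, fdrCutoff, fcCutoff)
}

#' Annotate differential sites with genomic categories
#'
#' Each site receives the first matching category in the priority order
#' ProximalPromoter (within 0.25 kb of a TSS), Promoter1k (within 1 kb),
#' Promoter3k (within 3 kb), Genebody (overlapping the region from the
#' gene's TSS to 1 kb downstream of its TES), Genedesert, Pericentromere,
#' Subtelomere, OtherIntergenic. Genic categories also record the
#' associated gene (nearest TSS among qualifying genes).
#'
#' @param sites `GRanges` of differential sites.
#' @param genes `GRanges` of gene models with strand and a `gene_id`
#'   metadata column.
#' @param genedeserts,pericentromeres,subtelomeres optional annotation
#'   `GRanges` for the non-genic categories.
#' @return `sites` with added `category` and `gene` metadata columns.
#' @export
annotateSites <- function(sites, genes, genedeserts = NULL,
        pericentromeres = NULL, subtelomeres = NULL) {
    known <- unique(c(seqlevels(genes),
        if (!is.null(genedeserts)) seqlevels(genedeserts),
        if (!is.null(pericentromeres)) seqlevels(pericentromeres),
        if (!is.null(subtelomeres)) seqlevels(subtelomeres)))
    bad <- setdiff(unique(as.character(seqnames(sites))), known)
    if (length(bad))
        stop("site(s) on unknown chromosome: ", paste(bad, collapse = ", "))
    tss <- resize(genes, width = 1L, fix = "start")
    body <- resizeTrim(genes, width(genes) + 1000L, fix = "start")
    genic <- list(
        ProximalPromoter = resizeTrim(tss, 501L, fix = "center"),
        Promoter1k = resizeTrim(tss, 2001L, fix = "center"),
        Promoter3k = resizeTrim(tss, 6001L, fix = "center"),
        Genebody = body)
    category <- rep(NA_character_, length(sites))
    gene <- rep(NA_character_, length(sites))
    for (nm in names(genic)) {
        todo <- which(is.na(category))
        if (!length(todo)) break
        hits <- findOverlaps(sites[todo], genic[[nm]], ignore.strand = TRUE)
        if (length(hits) == 0L) next
        d <- abs((start(sites[todo][queryHits(hits)]) +
            end(sites[todo][queryHits(hits)])) / 2 -
            start(tss[subjectHits(hits)]))
        o <- order(queryHits(hits), d)
        first <- !duplicated(queryHits(hits)[o])
        q <- queryHits(hits)[o][first]; s <- subjectHits(hits)[o][first]
        category[todo[q]] <- nm
        gene[todo[q]] <- genes$gene_id[s]
    }
    nonGenic <- list(Genedesert = genedeserts,
        Pericentromere = pericentromeres, Subtelomere = subtelomeres)
    for (nm in names(nonGenic)) {
        if (is.null(nonGenic[[nm]])) next
        todo <- which(is.na(category))
        if (!length(todo)) break
        hit <- overlapsAny(sites[todo], nonGenic[[nm]],
            ignore.strand = TRUE)
        category[todo[hit]] <- nm
    }
    category[is.na(category)] <- "OtherIntergenic"
    mcols(sites)$category <- category
    mcols(sites)$gene <- gene
    sites
}

#' Count sex-biased sites by direction
#'
#' For sites from a male-vs-female comparison, counts how many are biased
#' toward each sex. Direction labels state which sex group B of the scan
#' was, so that `up` sites map to the correct sex.
#'
#' @param sites filtered `GRanges` with a `direction` column.
#' @param labels mapping of scan directions to sexes; default assumes the
#'   scan was run with females as group A and males as group B.
#' @return named integer vector of counts (male, female).
#' @export
callSexBiasedSites <- function(sites,
        labels = c(up = "male", down = "female")) {
    sex <- unname(labels[sites$direction])
    c(male = sum(sex == "male"), female = sum(sex == "female"))
}
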