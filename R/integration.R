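#' Build basal-plus-extension regulatory domains
#'
#' Each gene gets a basal regulatory domain from 5 kb upstream to 1 kb
#' downstream of its TSS (strand-aware). The domain is then extended in
#' both directions up to the nearest other gene's basal domain, capped at
#' 1 Mb from the TSS per side and clipped at chromosome ends. Extensions
#' never shrink the basal domain: a neighbouring basal domain overlapping
#' the gene's own basal domain simply stops the extension at the basal
#' boundary.
#'
#' @param genes `GRanges` of gene models with strand and a `gene_id`
#'   column; `seqlengths` must be set (or supplied via `chromLengths`).
#' @param chromLengths optional named vector of chromosome lengths.
#' @param basalUpstream,basalDownstream basal domain geometry in bp.
#' @param maxExtension maximum extension from the TSS per side, in bp.
#' @return `GRanges` of extended domains with metadata columns `gene_id`,
#'   `basal_start`, `basal_end`.
#' @export
buildRegulatoryDomains <- function(genes, chromLengths = NULL,
        basalUpstream = 5000L, basalDownstream = 1000L,
        maxExtension = 1e6) {
    if (!is.null(chromLengths))
        seqlengths(genes) <- chromLengths[seqlevels(genes)]
    sl <- seqlengths(genes)
    if (anyNA(sl)) stop("chromosome lengths are required")
    tss <- ifelse(strand(genes) == "-", end(genes), start(genes))
    if (any(tss < 1L | tss > sl[as.character(seqnames(genes))]))
        stop("TSS outside chromosome bounds")
    # basal domain built by hand (strand-aware) and clamped at the
    # chromosome ends, so no out-of-bound intermediate is created
    minus <- as.vector(strand(genes) == "-")
    bStart <- ifelse(minus, tss - basalDownstream + 1L,
        tss - basalUpstream)
    bEnd <- ifelse(minus, tss + basalUpstream,
        tss + basalDownstream - 1L)
    chrLen <- sl[as.character(seqnames(genes))]
    bStart <- pmax(bStart, 1L)
    bEnd <- pmin(bEnd, chrLen)
    extStart <- integer(length(genes)); extEnd <- integer(length(genes))
    for (chr in seqlevels(genes)) {
        idx <- which(as.character(seqnames(genes)) == chr)
        if (!length(idx)) next
        o <- idx[order(bStart[idx], bEnd[idx])]
        n <- length(o)
        u <- bStart[o]
        cm <- cummax(bEnd[o])
        # farthest right basal end among genes starting strictly left of
        # this one, and nearest basal start strictly right of it
        nSmaller <- findInterval(u - 1L, u)
        prevEnd <- ifelse(nSmaller > 0, cm[pmax(nSmaller, 1L)], -Inf)
        nGe <- findInterval(u, u)    # count of starts <= u
        nextStart <- ifelse(nGe < n, u[pmin(nGe + 1L, n)], Inf)
        lo <- pmax(tss[o] - maxExtension, prevEnd + 1L, 1L)
        hi <- pmin(tss[o] + maxExtension - 1L, nextStart - 1L, sl[chr])
        extStart[o] <- as.integer(pmin(lo, bStart[o]))
        extEnd[o] <- as.integer(pmax(hi, bEnd[o]))
    }
    out <- GRanges(seqnames(genes), IRanges(extStart, extEnd),
        strand = strand(genes), seqlengths = sl)
    mcols(out)$gene_id <- genes$gene_id
    mcols(out)$basal_start <- bStart
    mcols(out)$basal_end <- bEnd
    out
}

#' Map enhancer-mark sites to genes through regulatory domains
#'
#' A site is associated with every gene whose extended regulatory domain
#' it overlaps by at least one base (multi-assignment, as in
#' basal-plus-extension mapping).
#'
#' @param sites `GRanges` of differential sites.
#' @param domains output of [buildRegulatoryDomains()].
#' @return data.frame with columns `gene`, `site` (index into `sites`).
#' @export
mapEnhancerMarks <- function(sites, domains) {
    hits <- findOverlaps(sites, domains, ignore.strand = TRUE)
    data.frame(gene = domains$gene_id[subjectHits(hits)],
        site = queryHits(hits), stringsAsFactors = FALSE)
}

#' Map H3K27me3 sites to genes by gene body or TSS window
#'
#' An H3K27me3 site is associated with a gene when it overlaps the gene
#' body (transcript span) or the 3 kb region surrounding the TSS.
#'
#' @param sites `GRanges` of H3K27me3 differential sites.
#' @param genes gene-model `GRanges` with `gene_id`.
#' @param tssFlank half-width of the TSS window in bp (default 3000).
#' @return data.frame with columns `gene`, `site`.
#' @export
mapK27me3ToGenes <- function(sites, genes, tssFlank = 3000L) {
    tss <- resize(genes, width = 1L, fix = "start")
    tssWin <- resizeTrim(tss, 2L * tssFlank + 1L, fix = "center")
    hits1 <- findOverlaps(sites, genes, ignore.strand = TRUE)
    hits2 <- findOverlaps(sites, tssWin, ignore.strand = TRUE)
    assoc <- unique(rbind(
        data.frame(gene = genes$gene_id[subjectHits(hits1)],
            site = queryHits(hits1)),
        data.frame(gene = genes$gene_id[subjectHits(hits2)],
            site = queryHits(hits2))))
    rownames(assoc) <- NULL
    assoc
}

#' Histone-mark pattern group from the three mark flags
#'
#' Maps the triple (H3K27me3 lost, H3K27ac gained, H3K4me1 gained) to the
#' eight pattern groups:
#' 1 = (0,0,0), 2 = (1,1,1), 3 = (1,0,1), 4 = (1,1,0), 5 = (1,0,0),
#' 6 = (0,1,1), 7 = (0,1,0), 8 = (0,0,1).
#'
#' @param k27me3Down,k27acUp,k4me1Up logical vectors (recycled).
#' @return integer group in 1..8.
#' @examples
#' classifyMarkGroup(TRUE, TRUE, FALSE)   # group 4
#' @export
classifyMarkGroup <- function(k27me3Down, k27acUp, k4me1Up) {
    key <- paste0(as.integer(k27me3Down), as.integer(k27acUp),
        as.integer(k4me1Up))
    map <- c(`000` = 1L, `111` = 2L, `101` = 3L, `110` = 4L,
        `100` = 5L, `011` = 6L, `010` = 7L, `001` = 8L)
    unname(map[key])
}

#' Per-gene mark flags and pattern groups
#'
#' Sets each gene's flag when any associated site of the corresponding
#' mark and direction exists: a down-regulated H3K27me3 site mapped by the
#' gene-body/TSS rule, or an up-regulated H3K27ac / H3K4me1 site mapped by
#' regulatory domain. Genes associated with both an up- and a
#' down-regulated site of the same mark keep the flag and are listed in
#' the returned `conflicts`.
#'
#' @param geneIds character vector of genes to classify.
#' @param k27me3Sites,k27acSites,k4me1Sites differential site `GRanges`
#'   with a `direction` column (possibly empty).
#' @param genes gene-model `GRanges` (for the H3K27me3 rule).
#' @param domains regulatory domains (for the enhancer marks).
#' @return list with `flags` (data.frame: gene, k27me3_down, k27ac_up,
#'   k4me1_up, group) and `conflicts` (genes with opposing sites of one
#'   mark).
#' @export
geneMarkFlags <- function(geneIds, k27me3Sites, k27acSites, k4me1Sites,
        genes, domains) {
    assocDir <- function(sites, mapper, dir) {
        if (length(sites) == 0L) return(character(0))
        keep <- which(sites$direction == dir)
        if (!length(keep)) return(character(0))
        unique(mapper(sites[keep])$gene)
    }
    k27dn <- assocDir(k27me3Sites,
        function(s) mapK27me3ToGenes(s, genes), "down")
    k27up <- assocDir(k27me3Sites,
        function(s) mapK27me3ToGenes(s, genes), "up")
    acUp <- assocDir(k27acSites,
        function(s) mapEnhancerMarks(s, domains), "up")
    acDn <- assocDir(k27acSites,
        function(s) mapEnhancerMarks(s, domains), "down")
    meUp <- assocDir(k4me1Sites,
        function(s) mapEnhancerMarks(s, domains), "up")
    meDn <- assocDir(k4me1Sites,
        function(s) mapEnhancerMarks(s, domains), "down")
    flags <- data.frame(gene = geneIds,
        k27me3_down = geneIds %in% k27dn,
        k27ac_up = geneIds %in% acUp,
        k4me1_up = geneIds %in% meUp,
        stringsAsFactors = FALSE)
    flags$group <- classifyMarkGroup(flags$k27me3_down, flags$k27ac_up,
        flags$k4me1_up)
    conflicts <- unique(c(intersect(k27dn, k27up),
        intersect(acUp, acDn), intersect(meUp, meDn)))
    list(flags = flags, conflicts = intersect(geneIds, conflicts))
}

#' Distribution of histone-mark pattern groups over gene sets
#'
#' @param flags the `flags` data.frame from [geneMarkFlags()].
#' @param geneSets named list of character vectors of gene ids.
#' @return data.frame with one row per set and group: `set`, `group`,
#'   `count`, `fraction` (fractions sum to 1 within each set).
#' @export
groupDistribution <- function(flags, geneSets) {
    out <- lapply(names(geneSets), function(nm) {
        sub <- flags[flags$gene %in% geneSets[[nm]], ]
        counts <- tabulate(sub$group, nbins = 8L)
        data.frame(set = nm, group = 1:8, count = counts,
            fraction = if (nrow(sub)) counts / nrow(sub) else NA_real_)
    })
    do.call(rbind, out)
}
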