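#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps pintersect reduce promoters resize tileGenome countOverlaps
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowRanges assayNames
#' @importFrom GenomeInfoDb seqlengths "seqlengths<-" seqlevels
#' @importFrom stats p.adjust rlnorm rnbinom rpois rgamma runif dnbinom dpois dbinom
#'   dhyper median sd var quantile setNames
#' @importFrom utils read.delim write.table head
#' @importFrom tools md5sum
NULL

#' Simulation configuration for synthetic liver expression and ChIP data
#'
#' Holds every tunable parameter of the synthetic data generator: the
#' four-group design (control/knockout crossed with male/female), the
#' negative-binomial noise model (variance \eqn{\mu + \phi\mu^2}), the
#' fractions and effect sizes of sex-biased and knockout-responsive genes,
#' and the layout of the simulated histone-mark window track (static,
#' male-biased, knockout-lost and weak peak regions on a background).
#'
#' Create instances with [simConfig()]; slots are validated on construction.
#'
#' @slot nGenes number of simulated genes.
#' @slot nWindows number of genomic bins in the window track.
#' @slot repsPerGroup RNA-seq biological replicates per sex-genotype group.
#' @slot chipRepsPerGroup ChIP-seq replicates per group.
#' @slot baselineMean expected reads per gene in the reference (control male)
#'   condition.
#' @slot dispersion negative-binomial dispersion \eqn{\phi} for gene counts.
#' @slot chipDispersion NB dispersion for window-track bin counts; broad
#'   repressive-mark windows pool many reads and show lower replicate
#'   variability than per-gene expression.
#' @slot fracFemaleBiased,fracMaleBiased,fracKoResponsive fractions of genes
#'   that are female-biased, male-biased, or sex-independent knockout
#'   responders; they must sum to at most 1.
#' @slot fracBiasedKoResponsive fraction of sex-biased genes whose bias is
#'   erased in the knockout (de-repressed female-biased genes in males,
#'   down-regulated male-biased genes in males).
#' @slot sexbiasLog2fc,koLog2fc log2 effect sizes.
#' @slot geneLengthRange length-2 range (bp) for uniform gene lengths.
#' @slot librarySize target total reads per RNA-seq sample (NA derives
#'   `nGenes * baselineMean`).
#' @slot binWidth width (bp) of one window-track bin.
#' @slot regionBins number of consecutive bins per simulated peak region.
#' @slot nStaticRegions,nMaleBiasedRegions,nKoLostRegions,nWeakRegions number
#'   of regions of each kind placed on the track.
#' @slot windowBackgroundMean,staticMean expected reads per bin outside peaks
#'   and inside high-signal regions.
#' @slot chipLog2fc log2 fold difference of male-biased and knockout-lost
#'   regions relative to their low state.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
    representation(
        nGenes = "integer", nWindows = "integer",
        repsPerGroup = "integer", chipRepsPerGroup = "integer",
        baselineMean = "numeric", dispersion = "numeric",
        chipDispersion = "numeric",
        fracFemaleBiased = "numeric", fracMaleBiased = "numeric",
        fracKoResponsive = "numeric", fracBiasedKoResponsive = "numeric",
        sexbiasLog2fc = "numeric", koLog2fc = "numeric",
        geneLengthRange = "numeric", librarySize = "numeric",
        binWidth = "integer", regionBins = "integer",
        nStaticRegions = "integer", nMaleBiasedRegions = "integer",
        nKoLostRegions = "integer", nWeakRegions = "integer",
        windowBackgroundMean = "numeric", staticMean = "numeric",
        chipLog2fc = "numeric", seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    fr <- object@fracFemaleBiased + object@fracMaleBiased +
        object@fracKoResponsive
    props <- c(object@fracFemaleBiased, object@fracMaleBiased,
        object@fracKoResponsive, object@fracBiasedKoResponsive)
    if (any(props < 0) || any(props > 1))
        msg <- c(msg, "gene fractions must lie in [0, 1]")
    if (fr > 1)
        msg <- c(msg, "fracFemaleBiased + fracMaleBiased + fracKoResponsive must be <= 1")
    if (object@dispersion < 0 || object@chipDispersion < 0)
        msg <- c(msg, "dispersions must be >= 0")
    if (object@repsPerGroup < 2L || object@chipRepsPerGroup < 2L)
        msg <- c(msg, "at least 2 replicates per group are required")
    for (s in c("nGenes", "nWindows", "binWidth", "regionBins"))
        if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be >= 1"))
    if (object@baselineMean <= 0 || object@windowBackgroundMean <= 0 ||
        object@staticMean <= 0)
        msg <- c(msg, "mean parameters must be positive")
    if (length(object@geneLengthRange) != 2L ||
        any(object@geneLengthRange < 1) ||
        diff(object@geneLengthRange) < 0)
        msg <- c(msg, "geneLengthRange must be an increasing length-2 range")
    nRegionBins <- (object@nStaticRegions + object@nMaleBiasedRegions +
        object@nKoLostRegions + object@nWeakRegions) *
        (object@regionBins + 5L)
    if (nRegionBins > object@nWindows)
        msg <- c(msg, "nWindows too small for the requested peak regions")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults mirror the study design the generator emulates: four groups
#' (control and Ezh1/Ezh2-knockout, male and female) with 3 RNA-seq and 4
#' ChIP-seq replicates each, a 10% female-biased / 5% male-biased gene
#' complement with 4-fold sex effects, and a window track carrying static,
#' male-biased and knockout-lost H3K27me3 regions with 8-fold differences.
#'
#' @param nGenes,nWindows,repsPerGroup,chipRepsPerGroup,baselineMean,dispersion
#'   see [SimConfig-class].
#' @param fracFemaleBiased,fracMaleBiased,fracKoResponsive,fracBiasedKoResponsive
#'   gene category fractions.
#' @param sexbiasLog2fc,koLog2fc,geneLengthRange,librarySize,binWidth,regionBins
#'   effect sizes and track geometry.
#' @param nStaticRegions,nMaleBiasedRegions,nKoLostRegions,nWeakRegions,windowBackgroundMean,staticMean,chipLog2fc,seed
#'   window-track composition and RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 200, seed = 7)
#' @export
simConfig <- function(nGenes = 2000L, nWindows = 36000L,
    repsPerGroup = 3L, chipRepsPerGroup = 4L,
    baselineMean = 500, dispersion = 0.05, chipDispersion = 0.01,
    fracFemaleBiased = 0.10, fracMaleBiased = 0.05,
    fracKoResponsive = 0.10, fracBiasedKoResponsive = 0.6,
    sexbiasLog2fc = 2, koLog2fc = 1.5,
    geneLengthRange = c(500, 10000), librarySize = NA_real_,
    binWidth = 100L, regionBins = 20L,
    nStaticRegions = 40L, nMaleBiasedRegions = 25L,
    nKoLostRegions = 25L, nWeakRegions = 150L,
    windowBackgroundMean = 4, staticMean = 40,
    chipLog2fc = 3, seed = 1L) {
    new("SimConfig",
        nGenes = as.integer(nGenes), nWindows = as.integer(nWindows),
        repsPerGroup = as.integer(repsPerGroup),
        chipRepsPerGroup = as.integer(chipRepsPerGroup),
        baselineMean = baselineMean, dispersion = dispersion,
        chipDispersion = chipDispersion,
        fracFemaleBiased = fracFemaleBiased,
        fracMaleBiased = fracMaleBiased,
        fracKoResponsive = fracKoResponsive,
        fracBiasedKoResponsive = fracBiasedKoResponsive,
        sexbiasLog2fc = sexbiasLog2fc, koLog2fc = koLog2fc,
        geneLengthRange = geneLengthRange, librarySize = librarySize,
        binWidth = as.integer(binWidth), regionBins = as.integer(regionBins),
        nStaticRegions = as.integer(nStaticRegions),
        nMaleBiasedRegions = as.integer(nMaleBiasedRegions),
        nKoLostRegions = as.integer(nKoLostRegions),
        nWeakRegions = as.integer(nWeakRegions),
        windowBackgroundMean = windowBackgroundMean, staticMean = staticMean,
        chipLog2fc = chipLog2fc, seed = as.integer(seed))
}

#' @describeIn SimConfig-class compact parameter listing
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes,", object@nWindows,
        "window bins,", 4L * object@repsPerGroup, "RNA samples,",
        4L * object@chipRepsPerGroup, "ChIP samples\n")
    cat("  baselineMean =", object@baselineMean,
        " dispersion =", object@dispersion,
        " sexbiasLog2fc =", object@sexbiasLog2fc,
        " seed =", object@seed, "\n")
})

#' Liver expression experiment container
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying `counts` and
#' `fpkm` assays, per-sample `sex` (`"M"`/`"F"`), `genotype`
#' (`"control"`/`"KO"`) and `replicate` columns, and a `length` (bp) column
#' in `rowData`. The validity method enforces non-negative integral counts
#' and a complete sex-by-genotype labelling.
#'
#' @export
setClass("LiverExpression", contains = "SummarizedExperiment")

setValidity("LiverExpression", function(object) {
    msg <- character()
    if (!all(c("counts", "fpkm") %in% assayNames(object)))
        msg <- c(msg, "assays 'counts' and 'fpkm' are required")
    cd <- colData(object)
    if (!all(c("sex", "genotype", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must have sex, genotype and replicate")
    else {
        if (!all(cd$sex %in% c("M", "F")))
            msg <- c(msg, "sex must be 'M' or 'F'")
        if (!all(cd$genotype %in% c("control", "KO")))
            msg <- c(msg, "genotype must be 'control' or 'KO'")
    }
    if ("counts" %in% assayNames(object)) {
        cts <- assay(object, "counts")
        if (any(cts < 0) || any(cts != round(cts)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (!"length" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must carry gene 'length' (bp)")
    if (length(msg)) msg else TRUE
})

#' Construct a LiverExpression object
#'
#' @param counts gene-by-sample matrix of non-negative integer read counts.
#' @param sex,genotype,replicate per-sample labels (`"M"`/`"F"`,
#'   `"control"`/`"KO"`, integer replicate index).
#' @param length per-gene transcript length in bp.
#' @param fpkm optional FPKM matrix; computed from counts, lengths and
#'   per-sample total counts when omitted
#'   (\eqn{FPKM = 10^9 \cdot count / (libSize \cdot length)}).
#' @return A [LiverExpression-class] object.
#' @examples
#' counts <- matrix(rpois(40, 50), nrow = 10,
#'     dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' le <- LiverExpression(counts, sex = c("M", "M", "F", "F"),
#'     genotype = rep("control", 4), replicate = c(1, 2, 1, 2),
#'     length = rep(1000, 10))
#' @export
LiverExpression <- function(counts, sex, genotype, replicate, length,
        fpkm = NULL) {
    counts <- as.matrix(counts)
    if (is.null(fpkm)) fpkm <- computeFpkm(counts, length)
    se <- SummarizedExperiment(
        assays = list(counts = counts, fpkm = fpkm),
        colData = DataFrame(sex = sex, genotype = genotype,
            replicate = replicate, libSize = colSums(counts),
            row.names = colnames(counts)),
        rowData = DataFrame(length = length, row.names = rownames(counts)))
    new("LiverExpression", se)
}

#' Compute FPKM from raw counts
#'
#' @param counts count matrix.
#' @param length per-gene length (bp).
#' @param libSize per-sample library sizes; defaults to column sums.
#' @return matrix of FPKM values.
#' @export
computeFpkm <- function(counts, length, libSize = colSums(counts)) {
    t(t(counts / length) / libSize) * 1e9
}

#' @describeIn LiverExpression-class summary of the design
#' @param object a `LiverExpression`
#' @export
setMethod("show", "LiverExpression", function(object) {
    cat("LiverExpression:", nrow(object), "genes x", ncol(object),
        "samples\n")
    print(table(sex = colData(object)$sex,
        genotype = colData(object)$genotype))
})

#' ChIP-seq window count container
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are fixed
#' genomic bins (`rowRanges`) and whose `counts` assay holds raw ChIP read
#' counts per bin and sample. `colData` carries `sex`, `genotype` and
#' `totalReads` (total mapped reads per sample, at least the column sum over
#' bins).
#'
#' @export
setClass("WindowCounts", contains = "RangedSummarizedExperiment")

setValidity("WindowCounts", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- colData(object)
    need <- c("sex", "genotype", "totalReads")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must have sex, genotype, totalReads")
    else if ("counts" %in% assayNames(object)) {
        cts <- assay(object, "counts")
        if (any(cts < 0) || any(cts != round(cts)))
            msg <- c(msg, "counts must be non-negative integers")
        if (any(cd$totalReads < colSums(cts)))
            msg <- c(msg, "totalReads must be >= in-window column sums")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a WindowCounts object
#'
#' @param bins `GRanges` of genomic bins (one row per bin).
#' @param counts bin-by-sample integer count matrix.
#' @param sex,genotype per-sample labels.
#' @param totalReads per-sample total mapped reads.
#' @return A [WindowCounts-class] object.
#' @export
WindowCounts <- function(bins, counts, sex, genotype,
        totalReads = colSums(counts)) {
    counts <- as.matrix(counts)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = bins,
        colData = DataFrame(sex = sex, genotype = genotype,
            totalReads = totalReads, row.names = colnames(counts)))
    new("WindowCounts", se)
}

#' @describeIn WindowCounts-class summary of the track
#' @param object a `WindowCounts`
#' @export
setMethod("show", "WindowCounts", function(object) {
    cat("WindowCounts:", nrow(object), "bins x", ncol(object),
        "samples;", sum(width(rowRanges(object))), "bp covered\n")
})

#' Static H3K27me3 site set with scaling factors
#'
#' Result of the static-site identification cascade
#' ([identifyStaticSites()]): the retained invariant sites, the per-sample
#' scaling factors derived from reads falling in them, and an audit trail of
#' how many candidate sites survived each filter stage.
#'
#' @slot sites `GRanges` of retained static sites.
#' @slot factors per-sample scaling factors (reads in sites / 1e6).
#' @slot audit data.frame with columns `stage` and `n` (sites surviving).
#' @export
setClass("StaticSiteSet",
    representation(sites = "GRanges", factors = "numeric",
        audit = "data.frame"))

setValidity("StaticSiteSet", function(object) {
    msg <- character()
    if (any(object@factors <= 0))
        msg <- c(msg, "scaling factors must be positive")
    if (is.unsorted(rev(object@audit$n)))
        msg <- c(msg, "audit stage counts must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' @describeIn StaticSiteSet-class cascade summary
#' @param object a `StaticSiteSet`
#' @export
setMethod("show", "StaticSiteSet", function(object) {
    cat("StaticSiteSet:", length(object@sites), "sites retained\n")
    for (i in seq_len(nrow(object@audit)))
        cat(sprintf("  %-28s %d\n", object@audit$stage[i], object@audit$n[i]))
})

#' @describeIn StaticSiteSet-class retained sites
#' @param x a `StaticSiteSet`
#' @export
staticSites <- function(x) x@sites

#' @describeIn StaticSiteSet-class per-sample scaling factors
#' @export
scalingFactors <- function(x) x@factors

#' @describeIn StaticSiteSet-class per-stage audit counts
#' @export
auditLog <- function(x) x@audit

#' Two-by-two contingency table with enrichment score
#'
#' Counts follow the convention of enrichment analyses of gene sets:
#' `A` = focal-set genes with the property, `B` = non-focal genes with the
#' property, `C` = focal genes without the property, `D` = background genes
#' with neither. The enrichment score is \eqn{ES = (A/B)/(C/D)} and its
#' significance comes from the two-sided Fisher exact test.
#'
#' @slot A,B,C,D non-negative integer counts.
#' @export
setClass("ContingencyTable",
    representation(A = "integer", B = "integer", C = "integer",
        D = "integer"))

setValidity("ContingencyTable", function(object) {
    counts <- c(object@A, object@B, object@C, object@D)
    if (any(counts < 0)) "counts must be non-negative" else TRUE
})

#' Construct a contingency table from four counts
#'
#' @param A,B,C,D the four cell counts (see [ContingencyTable-class]).
#' @return A [ContingencyTable-class] object.
#' @examples
#' ct <- contingencyTable(240, 602, 404, 10847)
#' enrichmentScore(ct)
#' @export
contingencyTable <- function(A, B, C, D) {
    # slots assigned individually: an argument named `C` would otherwise
    # partially match new()'s `Class` formal
    obj <- new("ContingencyTable")
    obj@A <- as.integer(A); obj@B <- as.integer(B)
    obj@C <- as.integer(C); obj@D <- as.integer(D)
    validObject(obj)
    obj
}

#' @describeIn ContingencyTable-class table with ES and Fisher p
#' @param object a `ContingencyTable`
#' @export
setMethod("show", "ContingencyTable", function(object) {
    cat(sprintf("ContingencyTable A=%d B=%d C=%d D=%d  ES=%s  p=%.3g\n",
        object@A, object@B, object@C, object@D,
        format(round(enrichmentScore(object), 1), nsmall = 1),
        fisherP(object)))
})
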