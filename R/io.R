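# Plain-text serialization of the simulated study bundle. All interval
# files use 0-based half-open coordinates (BED convention, and txStart /
# txEnd in the gene-model table); in-memory GRanges are 1-based closed.

grToBed <- function(gr, extra = NULL) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
        start = start(gr) - 1L, end = end(gr))
    if (!is.null(extra)) df <- cbind(df, extra)
    df
}

bedToGr <- function(df, seqlen = NULL) {
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    if (!is.null(seqlen)) seqlengths(gr) <- seqlen
    gr
}

writeTsv <- function(df, path, col.names = TRUE) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = col.names)
}

#' Write a simulated study bundle to plain-text files
#'
#' Serializes everything downstream modules consume: `counts.tsv`,
#' `fpkm.tsv`, `samples.tsv` (RNA sample sheet), `genes.tsv` (gene models
#' with 0-based `txStart`), `window_counts.tsv` (chrom, start, end, one
#' column per ChIP sample), `chip_samples.tsv`, `windows.bed`,
#' `peaks.bed` (0-based half-open BED3), `truth_genes.tsv` and
#' `truth_windows.tsv`.
#'
#' @param bundle output of [simulateStudy()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
writeFixtureBundle <- function(bundle, outdir) {
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory ", outdir)
    le <- bundle$expression
    paths <- c(
        counts = file.path(outdir, "counts.tsv"),
        fpkm = file.path(outdir, "fpkm.tsv"),
        samples = file.path(outdir, "samples.tsv"),
        genes = file.path(outdir, "genes.tsv"),
        window_counts = file.path(outdir, "window_counts.tsv"),
        chip_samples = file.path(outdir, "chip_samples.tsv"),
        windows = file.path(outdir, "windows.bed"),
        peaks = file.path(outdir, "peaks.bed"),
        truth_genes = file.path(outdir, "truth_genes.tsv"),
        truth_windows = file.path(outdir, "truth_windows.tsv"))
    writeTsv(data.frame(gene = rownames(le), assay(le, "counts")),
        paths["counts"])
    writeTsv(data.frame(gene = rownames(le),
        signif(assay(le, "fpkm"), 8)), paths["fpkm"])
    writeTsv(data.frame(sample = colnames(le),
        as.data.frame(colData(le))), paths["samples"])
    g <- bundle$genes
    writeTsv(data.frame(gene_id = g$gene_id,
        chrom = as.character(seqnames(g)),
        strand = as.character(strand(g)),
        txStart = start(g) - 1L, txEnd = end(g),
        chromLength = seqlengths(g)[as.character(seqnames(g))]),
        paths["genes"])
    wc <- bundle$windows
    writeTsv(cbind(grToBed(rowRanges(wc)), assay(wc, "counts")),
        paths["window_counts"])
    writeTsv(data.frame(sample = colnames(wc),
        as.data.frame(colData(wc))), paths["chip_samples"])
    writeTsv(grToBed(rowRanges(wc)), paths["windows"], col.names = FALSE)
    writeTsv(grToBed(bundle$peaks), paths["peaks"], col.names = FALSE)
    writeTsv(bundle$truth, paths["truth_genes"])
    writeTsv(data.frame(region = bundle$regions$region_id,
        status = bundle$regions$status,
        chrom = as.character(seqnames(bundle$regions)),
        start = start(bundle$regions) - 1L,
        end = end(bundle$regions),
        anchor_gene = bundle$regions$anchor_gene,
        chromLength = seqlengths(bundle$regions)[
            as.character(seqnames(bundle$regions))]),
        paths["truth_windows"])
    invisible(paths)
}

#' Load a study bundle written by [writeFixtureBundle()]
#'
#' @param dir directory holding the bundle files.
#' @return list with the same shape as [simulateStudy()] output (minus
#'   FPKM rounding noise below 1e-8 relative).
#' @export
readFixtureBundle <- function(dir) {
    counts <- read.delim(file.path(dir, "counts.tsv"),
        check.names = FALSE)
    cts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(cts) <- counts$gene
    samples <- read.delim(file.path(dir, "samples.tsv"))
    genes <- read.delim(file.path(dir, "genes.tsv"))
    gr <- GRanges(genes$chrom, IRanges(genes$txStart + 1L, genes$txEnd),
        strand = genes$strand)
    mcols(gr)$gene_id <- genes$gene_id
    seqlengths(gr) <- vapply(split(genes$chromLength, genes$chrom),
        max, numeric(1))[seqlevels(gr)]
    le <- LiverExpression(cts, sex = samples$sex,
        genotype = samples$genotype, replicate = samples$replicate,
        length = width(gr)[match(rownames(cts), gr$gene_id)])
    wcounts <- read.delim(file.path(dir, "window_counts.tsv"),
        check.names = FALSE)
    chipSamples <- read.delim(file.path(dir, "chip_samples.tsv"))
    bins <- bedToGr(wcounts)
    m <- as.matrix(wcounts[, -(1:3), drop = FALSE])
    wc <- WindowCounts(bins, m, sex = chipSamples$sex,
        genotype = chipSamples$genotype,
        totalReads = chipSamples$totalReads)
    peaksDf <- read.delim(file.path(dir, "peaks.bed"), header = FALSE,
        col.names = c("chrom", "start", "end"))
    truthW <- read.delim(file.path(dir, "truth_windows.tsv"))
    sl <- vapply(split(truthW$chromLength, truthW$chrom), max,
        numeric(1))
    regions <- GRanges(truthW$chrom,
        IRanges(truthW$start + 1L, truthW$end))
    seqlengths(regions) <- sl[seqlevels(regions)]
    mcols(regions)$status <- truthW$status
    mcols(regions)$region_id <- truthW$region
    mcols(regions)$anchor_gene <- truthW$anchor_gene
    list(expression = le,
        truth = read.delim(file.path(dir, "truth_genes.tsv")),
        genes = gr, windows = wc, regions = regions,
        peaks = bedToGr(peaksDf))
}
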