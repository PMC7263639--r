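#' Trimmed-mean-of-ratios normalization factors
#'
#' Computes per-sample scaling factors from a count matrix by the
#' trimmed-mean-of-M-values idea: pairwise log ratios (M) against a
#' reference sample are trimmed (30% each tail), as are the most extreme
#' average intensities (A, 5% each tail), and the factor is the weighted
#' mean of the surviving ratios. Factors are rescaled to have geometric
#' mean 1, so effective library size = library size x factor.
#'
#' @param counts gene-by-sample matrix of raw counts.
#' @param libSize per-sample library sizes (defaults to column sums).
#' @param trimM,trimA two-tail trim fractions for log-ratios and average
#'   log-intensities.
#' @return numeric vector of normalization factors, one per sample.
#' @export
tmmFactors <- function(counts, libSize = colSums(counts),
        trimM = 0.3, trimA = 0.05) {
    counts <- as.matrix(counts)
    if (any(libSize <= 0)) stop("library sizes must be positive")
    cpm <- t(t(counts) / libSize)
    # reference: sample whose upper-quartile CPM is closest to the mean
    uq <- apply(cpm, 2L, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
        if (j == ref) return(1)
        keep <- counts[, j] > 0 & counts[, ref] > 0
        if (!any(keep)) return(1)
        pj <- cpm[keep, j]; pr <- cpm[keep, ref]
        M <- log2(pj / pr)
        A <- (log2(pj) + log2(pr)) / 2
        # asymptotic variance of each M value (delta method, binomial reads)
        w <- (1 - pj) / (counts[keep, j]) + (1 - pr) / (counts[keep, ref])
        loM <- quantile(M, trimM); hiM <- quantile(M, 1 - trimM)
        loA <- quantile(A, trimA); hiA <- quantile(A, 1 - trimA)
        use <- M >= loM & M <= hiM & A >= loA & A <= hiA
        if (!any(use)) return(1)
        2^(sum(M[use] / w[use]) / sum(1 / w[use]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

# Pseudo-counts on a common effective library scale: counts rescaled so all
# samples share the geometric-mean effective library size.
pseudoCounts <- function(counts, libSize, normFactors) {
    eff <- libSize * normFactors
    common <- exp(mean(log(eff)))
    t(t(counts) * (common / eff))
}

# Moment estimate of the NB dispersion per gene from group-wise means and
# variances of (pseudo-)counts: var = mu + phi mu^2 within each group.
momentDispersion <- function(y, groups) {
    est <- vapply(seq_len(nrow(y)), function(g) {
        num <- 0; den <- 0
        for (idx in groups) {
            v <- y[g, idx]
            m <- mean(v)
            if (m <= 0 || length(v) < 2L) next
            s2 <- var(v)
            df <- length(v) - 1L
            num <- num + df * (s2 - m) / m^2
            den <- den + df
        }
        if (den == 0) NA_real_ else num / den
    }, numeric(1))
    pmax(est, 0)
}

#' Estimate common and tagwise NB dispersions
#'
#' A per-gene moment estimator (within-group variance vs mean on
#' pseudo-counts) is pooled into a common dispersion, then each gene's
#' estimate is shrunk toward the common value with a fixed prior weight of
#' 10 residual degrees of freedom. This mirrors the behaviour of
#' moderated-dispersion exact tests without reproducing any one package's
#' estimator exactly.
#'
#' @param y pseudo-count matrix.
#' @param groups list of column-index vectors, one per group.
#' @param priorDf prior degrees of freedom for shrinkage toward the common
#'   dispersion.
#' @return list with `common` (scalar) and `tagwise` (per-gene vector).
#' @export
estimateDispersion <- function(y, groups, priorDf = 10) {
    perGene <- momentDispersion(y, groups)
    ok <- !is.na(perGene)
    common <- if (any(ok)) {
        m <- rowMeans(y)
        w <- pmin(m[ok], median(m[ok]))  # damp the influence of huge genes
        max(sum(perGene[ok] * w) / sum(w), 1e-6)
    } else 0.1
    df <- sum(lengths(groups)) - length(groups)
    tagwise <- ifelse(ok, (df * perGene + priorDf * common) / (df + priorDf),
        common)
    list(common = common, tagwise = pmax(tagwise, 1e-6))
}

#' Exact negative-binomial two-group p-value
#'
#' Conditional exact test for equality of NB means between two groups,
#' given the per-group sums of (pseudo-)counts. Conditioning is on the
#' total: the probability of every split of the total between the groups is
#' computed from the NB distribution of group sums (size \eqn{n/\phi}), and
#' the two-sided p-value is the total probability of splits no more likely
#' than the observed one. In the Poisson limit (\eqn{\phi = 0}) this is the
#' exact binomial split test.
#'
#' @param sumA,sumB rounded sums of counts in the two groups.
#' @param nA,nB number of libraries per group.
#' @param phi NB dispersion.
#' @return two-sided p-value.
#' @examples
#' exactNbPvalue(8, 2, 1, 1, 0)   # binomial(10, 1/2) double tail
#' @export
exactNbPvalue <- function(sumA, sumB, nA, nB, phi) {
    sumA <- round(sumA); sumB <- round(sumB)
    s <- sumA + sumB
    if (s == 0) return(1)
    a <- 0:s
    if (phi < 1e-10) {
        probs <- dbinom(a, s, nA / (nA + nB), log = TRUE)
    } else {
        mu <- s / (nA + nB)
        probs <- dnbinom(a, size = nA / phi, mu = nA * mu, log = TRUE) +
            dnbinom(s - a, size = nB / phi, mu = nB * mu, log = TRUE)
    }
    probs <- probs - max(probs)
    p <- exp(probs)
    obs <- p[sumA + 1L]
    min(sum(p[p <= obs * (1 + 1e-8)]) / sum(p), 1)
}

#' Negative-binomial exact test for differential expression
#'
#' The package's differential expression engine: trimmed-mean
#' normalization, pseudo-counts on a common library scale, moderated
#' moment-based dispersion, and a conditional NB exact test per gene
#' ([exactNbPvalue()]). The reported `logFC` is
#' \eqn{\log_2}(mean of group B / mean of group A) with a pseudo-count of
#' 0.5 reads per library, and `FDR` is the Benjamini-Hochberg adjustment
#' over all tested genes.
#'
#' @param object a [LiverExpression-class] object (or raw count matrix).
#' @param groupA,groupB for a `LiverExpression`, named lists selecting
#'   samples (e.g. `list(sex = "M", genotype = "control")`); for a matrix,
#'   column index vectors. Each group needs at least 2 samples.
#' @param dispersion optional fixed dispersion overriding estimation.
#' @param normFactors optional per-sample normalization factors (all
#'   samples); computed by [tmmFactors()] when `NULL`.
#' @param length,libSize for the matrix method: optional gene lengths and
#'   library sizes.
#' @return data.frame with one row per gene: `logFC`, `PValue`, `FDR`,
#'   normalized group means (`meanA`, `meanB`), and mean group FPKM
#'   (`fpkmA`, `fpkmB`) when FPKM is available. All-zero genes get
#'   `logFC = 0`, `PValue = 1` by convention.
#' @examples
#' cfg <- simConfig(nGenes = 100, seed = 3)
#' sim <- simulateExpression(cfg)
#' de <- nbExactTest(sim$expression,
#'     list(sex = "M", genotype = "control"),
#'     list(sex = "F", genotype = "control"))
#' head(de)
#' @export
nbExactTest <- function(object, groupA, groupB, dispersion = NULL,
        normFactors = NULL, length = NULL, libSize = NULL) {
    if (is(object, "SummarizedExperiment")) {
        counts <- assay(object, "counts")
        idxA <- groupColumns(object, groupA)
        idxB <- groupColumns(object, groupB)
        fpkm <- if ("fpkm" %in% assayNames(object)) assay(object, "fpkm")
        libSize <- colSums(counts)
    } else {
        counts <- as.matrix(object)
        idxA <- groupA; idxB <- groupB
        fpkm <- NULL
        if (is.null(libSize)) libSize <- colSums(counts)
    }
    if (length(idxA) < 2L || length(idxB) < 2L)
        stop("each group needs at least 2 replicates")
    if (any(libSize <= 0)) stop("library sizes must be positive")
    use <- c(idxA, idxB)
    cts <- counts[, use, drop = FALSE]
    ls <- libSize[use]
    nf <- if (is.null(normFactors)) tmmFactors(cts, ls) else normFactors[use]
    y <- pseudoCounts(cts, ls, nf)
    jA <- seq_along(idxA); jB <- length(idxA) + seq_along(idxB)
    if (is.null(dispersion)) {
        disp <- estimateDispersion(y, list(jA, jB))$tagwise
    } else {
        disp <- rep_len(dispersion, nrow(y))
    }
    sA <- rowSums(y[, jA, drop = FALSE])
    sB <- rowSums(y[, jB, drop = FALSE])
    nA <- length(jA); nB <- length(jB)
    pval <- vapply(seq_len(nrow(y)), function(g) {
        if (sA[g] + sB[g] < 0.5) return(1)
        exactNbPvalue(sA[g], sB[g], nA, nB, disp[g])
    }, numeric(1))
    mA <- sA / nA; mB <- sB / nB
    logFC <- ifelse(sA + sB < 0.5, 0, log2((mB + 0.5) / (mA + 0.5)))
    out <- data.frame(gene = rownames(counts), logFC = logFC,
        PValue = pval, FDR = p.adjust(pval, "BH"),
        meanA = mA, meanB = mB, dispersion = disp,
        row.names = rownames(counts), stringsAsFactors = FALSE)
    if (!is.null(fpkm)) {
        out$fpkmA <- rowMeans(fpkm[, idxA, drop = FALSE])
        out$fpkmB <- rowMeans(fpkm[, idxB, drop = FALSE])
    }
    out
}
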