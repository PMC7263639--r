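#' Simulate a four-group liver expression experiment
#'
#' Generates gene-level counts for the sex-by-genotype design (control and
#' knockout, male and female) with negative-binomial replicate noise
#' (variance \eqn{\mu + \phi\mu^2}, dispersion shared across genes) and
#' log-normal library-size factors (sdlog 0.1). Gene categories:
#' \itemize{
#'   \item female-biased genes: control female mean = control male mean
#'     \eqn{\times 2^{sexbiasLog2fc}}; a fraction
#'     (`fracBiasedKoResponsive`) are de-repressed to the female level in
#'     knockout male liver;
#'   \item male-biased genes: control male mean elevated instead; the
#'     responsive fraction falls to the female level in knockout males;
#'   \item sex-independent knockout responders: shifted by `koLog2fc` in
#'     knockout liver of both sexes (70% up, 30% down);
#'   \item the remainder is null.
#' }
#' FPKM is computed from counts, gene length and per-sample total counts.
#' The same seed always reproduces bit-identical output.
#'
#' @param config a [SimConfig-class] object.
#' @return list with `expression` (a [LiverExpression-class]), `truth`
#'   (data.frame: gene, sex_bias, ko_response_M, ko_response_F, baseline
#'   mean, true log2 sex fold-change) and `genes` (gene-model `GRanges`
#'   laid out head-to-tail on a synthetic chromosome).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 50, seed = 1))
#' sim$expression
#' @export
simulateExpression <- function(config) {
    validObject(config)
    withSeed(config@seed, {
        n <- config@nGenes
        ids <- sprintf("gene%05d", seq_len(n))
        lens <- round(runif(n, config@geneLengthRange[1L],
            config@geneLengthRange[2L]))

        nF <- round(config@fracFemaleBiased * n)
        nM <- round(config@fracMaleBiased * n)
        nK <- round(config@fracKoResponsive * n)
        lab <- rep("none", n)
        perm <- sample.int(n)
        lab[perm[seq_len(nF)]] <- "female"
        if (nM > 0) lab[perm[nF + seq_len(nM)]] <- "male"
        koIdx <- if (nK > 0) perm[nF + nM + seq_len(nK)] else integer(0)

        mu0 <- rlnorm(n, log(config@baselineMean) - 0.5, 1)
        target <- if (is.na(config@librarySize))
            n * config@baselineMean else config@librarySize
        mu0 <- mu0 * target / sum(mu0)

        s <- 2^config@sexbiasLog2fc
        muM <- mu0 * ifelse(lab == "male", s, 1)
        muF <- mu0 * ifelse(lab == "female", s, 1)

        respBiased <- runif(n) < config@fracBiasedKoResponsive
        koM <- rep("ns", n); koF <- rep("ns", n)
        muKoM <- muM; muKoF <- muF
        femResp <- lab == "female" & respBiased
        muKoM[femResp] <- muF[femResp]      # de-repressed to female level
        koM[femResp] <- "up"
        maleResp <- lab == "male" & respBiased
        muKoM[maleResp] <- muF[maleResp]    # falls to the unbiased level
        koM[maleResp] <- "down"
        if (length(koIdx)) {
            up <- koIdx[seq_len(round(0.7 * length(koIdx)))]
            dn <- setdiff(koIdx, up)
            k <- 2^config@koLog2fc
            muKoM[up] <- muM[up] * k; muKoF[up] <- muF[up] * k
            muKoM[dn] <- muM[dn] / k; muKoF[dn] <- muF[dn] / k
            koM[koIdx] <- koF[koIdx] <- ifelse(koIdx %in% up, "up", "down")
        }

        r <- config@repsPerGroup
        groups <- data.frame(
            sex = rep(c("M", "F", "M", "F"), each = r),
            genotype = rep(c("control", "control", "KO", "KO"), each = r),
            replicate = rep(seq_len(r), 4L))
        mu <- cbind(matrix(muM, n, r), matrix(muF, n, r),
            matrix(muKoM, n, r), matrix(muKoF, n, r))
        sj <- rlnorm(4L * r, 0, 0.1)
        mu <- t(t(mu) * sj)
        counts <- if (config@dispersion == 0) {
            matrix(rpois(length(mu), mu), n)
        } else {
            matrix(rnbinom(length(mu), size = 1 / config@dispersion,
                mu = mu), n)
        }
        storage.mode(counts) <- "integer"
        dimnames(counts) <- list(ids, paste0(
            ifelse(groups$genotype == "KO", "ko", "ctrl"), "_",
            tolower(groups$sex), "_", groups$replicate))

        le <- LiverExpression(counts, sex = groups$sex,
            genotype = groups$genotype, replicate = groups$replicate,
            length = lens)
        truth <- data.frame(gene = ids, sex_bias = lab,
            ko_response_M = koM, ko_response_F = koF,
            baseline_mean = mu0,
            true_log2_sex_fc = ifelse(lab == "female",
                config@sexbiasLog2fc,
                ifelse(lab == "male", -config@sexbiasLog2fc, 0)),
            row.names = ids, stringsAsFactors = FALSE)
        # head-to-tail gene models with 5 kb spacing (a gene-dense
        # cluster, so the window track spans a useful number of genes)
        starts <- cumsum(c(1, head(lens, -1) + 5000L))
        genes <- GRanges("chrG", IRanges(starts, width = lens),
            strand = rep(c("+", "-"), length.out = n))
        mcols(genes)$gene_id <- ids
        seqlengths(genes) <- max(end(genes)) + 5000L
        list(expression = le, truth = truth, genes = genes)
    })
}

#' Simulate a ChIP-seq window count track
#'
#' Lays out peak regions of four kinds on a background of uniform bins,
#' then draws NB counts for the 16-sample design (4 groups x
#' `chipRepsPerGroup`):
#' \itemize{
#'   \item static regions: high signal (`staticMean` per bin) identical in
#'     all groups -- the normalization anchors;
#'   \item male-biased regions: high in males, \eqn{2^{chipLog2fc}}-fold
#'     lower in females (the sex-biased repressive-mark pattern);
#'   \item knockout-lost regions: high in controls, lower by the same
#'     fold in knockouts of both sexes;
#'   \item weak regions: modest uniform signal, emulating the bulk of
#'     unremarkable peaks;
#'   \item background bins carry `windowBackgroundMean` reads.
#' }
#' When gene models and a gene truth table are supplied (as
#' [simulateStudy()] does), the track is placed on the gene chromosome and
#' knockout-lost regions are anchored on the bodies of de-repressed
#' female-biased genes falling inside the track span, so that mark loss and
#' gene de-repression co-occur as they do in liver; remaining regions are
#' placed in the gaps. Regions keep at least 5 background bins of
#' separation. Per-sample library factors are log-normal (sdlog 0.1) and
#' total mapped reads are depth-proportional (~80% of reads in the
#' analysed bins), since sequencing depth does not shrink when a sample
#' loses mark signal.
#'
#' @param config a [SimConfig-class] object.
#' @param genes optional gene-model `GRanges` (with `gene_id`) to anchor
#'   knockout-lost regions on.
#' @param geneTruth optional truth table from [simulateExpression()]
#'   (rownames = gene ids) used to pick the anchor genes.
#' @return list with `windows` (a [WindowCounts-class]), `truth`
#'   (data.frame of per-region labels), `regions` (`GRanges` with `status`
#'   and `anchor_gene` columns) and `peaks` (`GRanges`: the merged
#'   non-background regions).
#' @export
simulateWindowCounts <- function(config, genes = NULL, geneTruth = NULL) {
    validObject(config)
    withSeed(config@seed + 1L, {
        nb <- config@nWindows
        bw <- config@binWidth
        rb <- config@regionBins
        span <- nb * bw
        chrom <- if (is.null(genes)) "chrW" else
            as.character(seqnames(genes)[1L])
        bins <- GRanges(chrom,
            IRanges(start = (seq_len(nb) - 1L) * bw + 1L, width = bw))
        sl <- if (is.null(genes)) span else
            max(seqlengths(genes)[chrom], span, na.rm = TRUE)
        seqlengths(bins) <- setNames(sl, chrom)

        occ <- rep(FALSE, nb)
        kinds <- character(0); startBin <- integer(0)
        anchor <- character(0)
        if (!is.null(genes) && !is.null(geneTruth)) {
            tr <- geneTruth[genes$gene_id, , drop = FALSE]
            cand <- genes[tr$sex_bias == "female" &
                tr$ko_response_M == "up"]
            cand <- cand[start(cand) >= 6L * bw &
                end(cand) <= span - (rb + 6L) * bw]
            nAnchor <- min(length(cand), config@nKoLostRegions)
            for (i in seq_len(nAnchor)) {
                sb <- min(max((start(cand)[i] - 1L) %/% bw + 1L, 6L),
                    nb - rb - 4L)
                idx <- sb:(sb + rb - 1L)
                guard <- max(idx[1L] - 5L, 1L):min(idx[rb] + 5L, nb)
                if (any(occ[guard])) next
                occ[guard] <- TRUE
                kinds <- c(kinds, "koLost")
                startBin <- c(startBin, sb)
                anchor <- c(anchor, cand$gene_id[i])
            }
        }
        remaining <- c(rep("static", config@nStaticRegions),
            rep("maleBiased", config@nMaleBiasedRegions),
            rep("koLost", config@nKoLostRegions - sum(kinds == "koLost")),
            rep("weak", config@nWeakRegions))
        remaining <- sample(remaining)
        nRem <- length(remaining)
        slack <- max(nb - (nRem + length(kinds)) * (rb + 5L) - 10L, 0L)
        extra <- if (nRem > 0 && slack > 0) {
            u <- runif(nRem)
            floor(slack * u / sum(u))
        } else integer(nRem)
        pos <- 6L
        for (i in seq_len(nRem)) {
            target <- pos + extra[i]
            repeat {
                if (target > nb - rb - 4L)
                    stop("window track too small to place all regions")
                idx <- target:(target + rb - 1L)
                guard <- max(idx[1L] - 5L, 1L):min(idx[rb] + 5L, nb)
                if (!any(occ[guard])) break
                target <- target + 1L
            }
            occ[target:(target + rb - 1L)] <- TRUE
            kinds <- c(kinds, remaining[i])
            startBin <- c(startBin, target)
            anchor <- c(anchor, NA_character_)
            pos <- target + rb + 5L
        }
        o <- order(startBin)
        kinds <- kinds[o]; startBin <- startBin[o]; anchor <- anchor[o]
        nReg <- length(kinds)
        regionBinIdx <- lapply(seq_len(nReg), function(i)
            startBin[i]:(startBin[i] + rb - 1L))

        r <- config@chipRepsPerGroup
        groups <- data.frame(
            sex = rep(c("M", "F", "M", "F"), each = r),
            genotype = rep(c("control", "control", "KO", "KO"), each = r))
        nSamp <- 4L * r
        hi <- config@staticMean
        lo <- hi / 2^config@chipLog2fc
        mu <- matrix(config@windowBackgroundMean, nb, nSamp)
        for (i in seq_len(nReg)) {
            idx <- regionBinIdx[[i]]
            m <- switch(kinds[i],
                static = rep(hi, nSamp),
                weak = rep(hi / 4, nSamp),
                maleBiased = ifelse(groups$sex == "M", hi, lo),
                koLost = ifelse(groups$genotype == "control", hi, lo))
            mu[idx, ] <- matrix(m, length(idx), nSamp, byrow = TRUE)
        }
        sj <- rlnorm(nSamp, 0, 0.1)
        mu <- t(t(mu) * sj)
        # Poisson-gamma noise with the gamma multiplier shared by all
        # bins of a block (a truth region, or a regionBins-sized chunk of
        # background) within each sample: the marginal bin distribution
        # is exactly NB(mu, phi), and window aggregates keep the same
        # dispersion instead of averaging it away, as replicate-level
        # signal variability does in real ChIP data
        blockId <- (seq_len(nb) - 1L) %/% rb + 1L
        nBg <- max(blockId)
        for (i in seq_len(nReg)) blockId[regionBinIdx[[i]]] <- nBg + i
        phi <- config@chipDispersion
        counts <- if (phi == 0) {
            matrix(rpois(length(mu), mu), nb)
        } else {
            g <- matrix(rgamma(max(blockId) * nSamp, shape = 1 / phi,
                rate = 1 / phi), max(blockId), nSamp)
            matrix(rpois(length(mu), mu * g[blockId, ]), nb)
        }
        colnames(counts) <- paste0(
            ifelse(groups$genotype == "KO", "ko", "ctrl"), "_",
            tolower(groups$sex), "_chip", rep(seq_len(r), 4L))
        # total mapped reads track sequencing depth, not in-peak signal:
        # groups that lose mark signal keep their depth (reads simply
        # fall elsewhere in the genome), with ~80% of reads in the
        # analysed bins for an average sample
        storage.mode(counts) <- "integer"
        depth <- mean(colSums(mu) / sj)
        totals <- as.integer(pmax(round(depth * sj / 0.8),
            colSums(counts)))
        wc <- WindowCounts(bins, counts, sex = groups$sex,
            genotype = groups$genotype, totalReads = totals)

        regions <- GRanges(chrom, IRanges(
            start = (startBin - 1L) * bw + 1L, width = rb * bw),
            seqlengths = setNames(sl, chrom))
        mcols(regions)$status <- kinds
        mcols(regions)$region_id <- sprintf("region%03d", seq_len(nReg))
        mcols(regions)$anchor_gene <- anchor
        binStatus <- rep("background", nb)
        for (i in seq_len(nReg)) binStatus[regionBinIdx[[i]]] <- kinds[i]
        truth <- data.frame(region = regions$region_id,
            status = kinds,
            chrom = chrom,
            start = start(regions) - 1L, end = end(regions),
            anchor_gene = anchor,
            stringsAsFactors = FALSE)
        peaks <- GenomicRanges::reduce(regions, min.gapwidth = 1L)
        list(windows = wc, truth = truth, regions = regions,
            peaks = peaks, binStatus = binStatus)
    })
}

#' Simulate the full study bundle
#'
#' Runs [simulateExpression()] and [simulateWindowCounts()] under one
#' configuration.
#'
#' The window track is placed on the gene chromosome with knockout-lost
#' regions anchored on de-repressed female-biased gene bodies, so the
#' integration stage sees coherent coordinates.
#'
#' @param config a [SimConfig-class].
#' @return list combining both generators' outputs.
#' @export
simulateStudy <- function(config) {
    expr <- simulateExpression(config)
    win <- simulateWindowCounts(config, genes = expr$genes,
        geneTruth = expr$truth)
    c(expr, win)
}
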