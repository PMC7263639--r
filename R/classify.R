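#' Flag liver-expressed genes
#'
#' A gene is liver-expressed when its mean FPKM exceeds 1 in at least one of
#' the four sex-genotype groups (strict `> 1`).
#'
#' @param le a [LiverExpression-class] object with all four groups present.
#' @param threshold FPKM threshold (default 1).
#' @return named logical vector, one flag per gene.
#' @export
classifyLiverExpressed <- function(le, threshold = 1) {
    gm <- groupMeanFpkm(le)
    if (ncol(gm) < 4L)
        stop("all four sex-genotype groups are required")
    setNames(apply(gm, 1L, max) > threshold, rownames(gm))
}

#' Call sex-biased genes
#'
#' Female- or male-biased calls from a male-vs-female differential test:
#' a gene is called when `FDR < 0.01` and it is liver-expressed; direction
#' follows the sign of the female/male fold-change.
#'
#' @param de result of [nbExactTest()] with `groupA` = males and
#'   `groupB` = females, so `logFC > 0` means female-biased.
#' @param expressed logical liver-expressed flags (same gene order).
#' @param fdrCutoff FDR threshold (strict `<`).
#' @return character vector in `c("female", "male", "none")`.
#' @export
classifySexBias <- function(de, expressed, fdrCutoff = 0.01) {
    call <- rep("none", nrow(de))
    sig <- de$FDR < fdrCutoff & expressed
    call[sig & de$logFC > 0] <- "female"
    call[sig & de$logFC < 0] <- "male"
    setNames(call, de$gene)
}

#' Flag stringently sex-independent genes
#'
#' Liver-expressed genes whose male-female comparison shows
#' `|fold-change| < 1.2` and `FDR > 0.1` (both strict).
#'
#' @inheritParams classifySexBias
#' @param fcMax,fdrMin the fold-change ceiling and FDR floor.
#' @return named logical vector.
#' @export
classifyStringentIndependent <- function(de, expressed, fcMax = 1.2,
        fdrMin = 0.1) {
    setNames(expressed & abs(de$logFC) < log2(fcMax) & de$FDR > fdrMin,
        de$gene)
}

#' Call knockout response per sex
#'
#' Up/down/not-significant calls at `|fold-change| > 1.5` and `FDR < 0.05`
#' from knockout-vs-control tests run within each sex.
#'
#' @param deM,deF results of [nbExactTest()] with `groupA` = control,
#'   `groupB` = knockout, for males and females respectively.
#' @param fcCutoff,fdrCutoff thresholds (strict inequalities).
#' @return data.frame with columns `gene`, `ko_response_M`, `ko_response_F`,
#'   each in `c("up", "down", "ns")`.
#' @export
classifyKoResponse <- function(deM, deF, fcCutoff = 1.5, fdrCutoff = 0.05) {
    callOne <- function(de) {
        call <- rep("ns", nrow(de))
        sig <- de$FDR < fdrCutoff & abs(de$logFC) > log2(fcCutoff)
        call[sig & de$logFC > 0] <- "up"
        call[sig & de$logFC < 0] <- "down"
        call
    }
    stopifnot(identical(deM$gene, deF$gene))
    data.frame(gene = deM$gene, ko_response_M = callOne(deM),
        ko_response_F = callOne(deF), row.names = deM$gene,
        stringsAsFactors = FALSE)
}

#' Classify sex-specificity transitions in the knockout
#'
#' Compares the sex-bias call made in the control background with the call
#' made in the knockout background, for knockout-responsive genes:
#' `lose` (biased to none), `maintain` (same direction), `gain` (none to
#' biased), `reverse` (direction flips). Non-responsive genes get `"n/a"`.
#'
#' @param biasControl,biasKo character vectors in
#'   `c("female", "male", "none")` from [classifySexBias()] run on the two
#'   genotype backgrounds.
#' @param koResponsive logical: responds to the knockout in either sex.
#' @return character vector in `c("lose", "maintain", "gain", "reverse",
#'   "n/a")`.
#' @export
classifyTransition <- function(biasControl, biasKo, koResponsive) {
    out <- rep("n/a", length(biasControl))
    idx <- which(koResponsive)
    bc <- biasControl[idx]; bk <- biasKo[idx]
    res <- ifelse(bc == bk & bc != "none", "maintain",
        ifelse(bc != "none" & bk == "none", "lose",
        ifelse(bc == "none" & bk != "none", "gain",
        ifelse(bc != "none" & bk != "none" & bc != bk, "reverse",
            "n/a"))))
    out[idx] <- res
    setNames(out, names(biasControl))
}

#' Robust female-biased gene set across three cohorts
#'
#' Genes with a female/male expression ratio above `ratioCutoff` in every
#' supplied control cohort, liver-expressed, and significant
#' (`FDR < fdrCutoff`) in the reference (first) cohort.
#'
#' @param deList list of male-vs-female [nbExactTest()] results (first is
#'   the reference cohort); `logFC > 0` means female-biased.
#' @param expressed liver-expressed flags aligned with the first result.
#' @param ratioCutoff female/male ratio that must be exceeded in every
#'   cohort (strict `>`, default 2).
#' @param fdrCutoff FDR cutoff applied to the reference cohort.
#' @return character vector of gene ids.
#' @export
robustFemaleSet <- function(deList, expressed, ratioCutoff = 2,
        fdrCutoff = 0.01) {
    stopifnot(length(deList) >= 2L)
    genes <- deList[[1L]]$gene
    pass <- expressed & deList[[1L]]$FDR < fdrCutoff
    for (de in deList) {
        stopifnot(identical(de$gene, genes))
        pass <- pass & de$logFC > log2(ratioCutoff)
    }
    genes[pass]
}

#' Full gene classification table
#'
#' Runs every per-gene classification on a four-group experiment:
#' liver-expressed, sex-bias in control and knockout backgrounds,
#' stringent sex-independence, knockout response per sex, and the
#' sex-specificity transition.
#'
#' @param le a [LiverExpression-class] object.
#' @param dispersion optional fixed dispersion passed to the tests.
#' @return list with the four differential tables (`deSex`, `deSexKo`,
#'   `deKoM`, `deKoF`) and a `classification` data.frame.
#' @export
classifyGenes <- function(le, dispersion = NULL) {
    deSex <- nbExactTest(le, list(sex = "M", genotype = "control"),
        list(sex = "F", genotype = "control"), dispersion = dispersion)
    deSexKo <- nbExactTest(le, list(sex = "M", genotype = "KO"),
        list(sex = "F", genotype = "KO"), dispersion = dispersion)
    deKoM <- nbExactTest(le, list(sex = "M", genotype = "control"),
        list(sex = "M", genotype = "KO"), dispersion = dispersion)
    deKoF <- nbExactTest(le, list(sex = "F", genotype = "control"),
        list(sex = "F", genotype = "KO"), dispersion = dispersion)
    expressed <- classifyLiverExpressed(le)
    expressed <- expressed[deSex$gene]
    bias <- classifySexBias(deSex, expressed)
    biasKo <- classifySexBias(deSexKo, expressed)
    ko <- classifyKoResponse(deKoM, deKoF)
    responsive <- ko$ko_response_M != "ns" | ko$ko_response_F != "ns"
    cls <- data.frame(
        gene = deSex$gene,
        liver_expressed = unname(expressed),
        sex_bias = unname(bias),
        sex_bias_ko = unname(biasKo),
        stringent_independent =
            unname(classifyStringentIndependent(deSex, expressed)),
        ko_response_M = ko$ko_response_M,
        ko_response_F = ko$ko_response_F,
        transition = unname(classifyTransition(bias, biasKo, responsive)),
        row.names = deSex$gene, stringsAsFactors = FALSE)
    list(deSex = deSex, deSexKo = deSexKo, deKoM = deKoM, deKoF = deKoF,
        classification = cls)
}
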