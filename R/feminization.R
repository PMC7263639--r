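#' Percent feminization of male expression
#'
#' How far a treatment moves a male's expression of a gene toward the
#' female level:
#' \deqn{100 \cdot \frac{FPKM(treated\ male) - FPKM(control\ male)}
#'   {FPKM(control\ female) - FPKM(control\ male)}}
#' The value is 0% when the treated male stays at the control male level
#' and 100% when it reaches the control female level; values below 0 or
#' above 100 are reported as-is. When control female and male levels are
#' closer than `eps` the index is undefined and `NA` is returned with
#' `defined = FALSE`.
#'
#' @param ctrlM,ctrlF,treatedM FPKM of the gene in control male, control
#'   female and treated male liver (vectors recycle).
#' @param eps minimum |female - male| denominator, in FPKM (default 0.25,
#'   below expression-calling resolution).
#' @return data.frame with columns `percent` and `defined`.
#' @examples
#' percentFeminization(2, 12, 7)$percent   # 50
#' @export
percentFeminization <- function(ctrlM, ctrlF, treatedM, eps = 0.25) {
    n <- max(length(ctrlM), length(ctrlF), length(treatedM))
    ctrlM <- rep_len(ctrlM, n); ctrlF <- rep_len(ctrlF, n)
    treatedM <- rep_len(treatedM, n)
    if (any(c(ctrlM, ctrlF, treatedM) < 0))
        stop("FPKM values must be non-negative")
    defined <- abs(ctrlF - ctrlM) >= eps
    percent <- ifelse(defined,
        100 * (treatedM - ctrlM) / (ctrlF - ctrlM), NA_real_)
    data.frame(percent = percent, defined = defined)
}

#' Hypophysectomy response classes for female-biased genes
#'
#' Class I genes depend on the female plasma growth-hormone pattern:
#' hypophysectomy significantly represses them in female liver. Class II
#' genes are repressed by the male pituitary hormone profile:
#' hypophysectomy de-represses (induces) them in male liver. Genes doing
#' neither are `NR` (not responsive). Significance reuses the knockout
#' response thresholds (`|fold-change| > 1.5`, `FDR < 0.05`).
#'
#' @param hypoxDeM,hypoxDeF differential results for hypophysectomized vs
#'   intact liver (`logFC > 0` = up after hypophysectomy), in males and
#'   females.
#' @param genes gene ids to classify (default: genes of `hypoxDeF`).
#' @param fcCutoff,fdrCutoff significance thresholds.
#' @return named character vector in `c("I", "II", "NR")`. Genes missing
#'   from either table are `NR` with a warning.
#' @export
classifyHypox <- function(hypoxDeM, hypoxDeF, genes = hypoxDeF$gene,
        fcCutoff = 1.5, fdrCutoff = 0.05) {
    cls <- setNames(rep("NR", length(genes)), genes)
    iM <- match(genes, hypoxDeM$gene)
    iF <- match(genes, hypoxDeF$gene)
    if (anyNA(iM) || anyNA(iF))
        warning("genes absent from a hypox table are classified NR: ",
            paste(genes[is.na(iM) | is.na(iF)], collapse = ", "))
    lfc <- log2(fcCutoff)
    downF <- !is.na(iF) & hypoxDeF$FDR[iF] < fdrCutoff &
        hypoxDeF$logFC[iF] < -lfc
    upM <- !is.na(iM) & hypoxDeM$FDR[iM] < fdrCutoff &
        hypoxDeM$logFC[iM] > lfc
    # class II takes precedence for the rare gene qualifying for both:
    # de-repression in male liver is the class-defining observation
    cls[downF] <- "I"
    cls[upM] <- "II"
    cls
}

#' Summarize feminization across treatment models
#'
#' Per-model medians/means of the feminization index, per-gene flags for
#' feminization above 50% (strict), and the cross-model membership
#' partition of genes feminized in each combination of models.
#'
#' @param records data.frame with columns `gene`, `model`, `percent`
#'   (e.g. built from [percentFeminization()] per model).
#' @param threshold feminization percentage that must be exceeded for a
#'   gene to count as feminized in a model (default 50).
#' @return list with `perModel` (model, n, median, mean), `flags` (gene,
#'   model, feminized), and `venn` (named membership counts, one entry per
#'   non-empty model combination).
#' @export
summarizeFeminization <- function(records, threshold = 50) {
    stopifnot(all(c("gene", "model", "percent") %in% colnames(records)))
    perModel <- do.call(rbind, lapply(split(records, records$model),
        function(d) data.frame(model = d$model[1L], n = nrow(d),
            median = median(d$percent, na.rm = TRUE),
            mean = mean(d$percent, na.rm = TRUE))))
    rownames(perModel) <- NULL
    flags <- data.frame(gene = records$gene, model = records$model,
        feminized = !is.na(records$percent) & records$percent > threshold)
    fem <- flags[flags$feminized, ]
    combos <- vapply(split(fem$model, fem$gene), function(m)
        paste(sort(unique(m)), collapse = "&"), character(1))
    venn <- table(combos)
    list(perModel = perModel, flags = flags,
        venn = setNames(as.integer(venn), names(venn)))
}
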