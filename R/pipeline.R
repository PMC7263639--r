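#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates the whole analysis in dependency order from a single
#' configuration: simulate the study, write the fixture bundle,
#' differential expression and gene classification, feminization of
#' female-biased genes in the knockout model, RiPPM and static-site
#' normalization, differential histone-mark site discovery, site-to-gene
#' integration with pattern groups, and the enrichment report. Every
#' stage writes plain-text outputs under `outdir` and the run ends with
#' a manifest of file checksums, so identical configurations reproduce
#' identical runs.
#'
#' @param config a [SimConfig-class]; its `seed` drives all randomness.
#' @param outdir output directory.
#' @param stages character vector of stages to run, in
#'   `c("simulate", "diffexpr", "feminization", "chipnorm", "diffsites",
#'   "integration", "enrichment")`. Later stages require earlier ones in
#'   the same call; a missing dependency aborts with the stage name.
#' @return invisibly, a list with the stage outputs and the `manifest`
#'   data.frame (file, md5).
#' @export
runPipeline <- function(config = simConfig(), outdir = tempfile("sexdim"),
        stages = c("simulate", "diffexpr", "feminization", "chipnorm",
            "diffsites", "integration", "enrichment")) {
    all <- c("simulate", "diffexpr", "feminization", "chipnorm",
        "diffsites", "integration", "enrichment")
    stages <- match.arg(stages, all, several.ok = TRUE)
    deps <- list(diffexpr = "simulate", feminization = "diffexpr",
        chipnorm = "simulate", diffsites = "chipnorm",
        integration = c("diffexpr", "diffsites"),
        enrichment = c("diffexpr", "integration"))
    for (s in stages)
        if (!all(deps[[s]] %in% stages))
            stop("stage '", s, "' requires stage(s) ",
                paste(setdiff(deps[[s]], stages), collapse = ", "))
    if (!dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    out <- list(config = config, outdir = outdir)
    log <- function(...) message("[sexdim] ", ...)

    if ("simulate" %in% stages) {
        log("simulate: generating study bundle")
        out$bundle <- simulateStudy(config)
        writeFixtureBundle(out$bundle, file.path(outdir, "bundle"))
    }
    if ("diffexpr" %in% stages) {
        log("diffexpr: differential expression and classification")
        out$genesClassified <- classifyGenes(out$bundle$expression)
        for (nm in c("deSex", "deSexKo", "deKoM", "deKoF"))
            writeTsv(out$genesClassified[[nm]],
                file.path(outdir, paste0(nm, ".tsv")))
        writeTsv(out$genesClassified$classification,
            file.path(outdir, "classification.tsv"))
    }
    if ("feminization" %in% stages) {
        log("feminization: percent feminization, knockout model")
        cls <- out$genesClassified
        fem <- cls$classification[cls$classification$sex_bias == "female", ]
        de <- cls$deSex
        # group-mean FPKM: control male, control female, knockout male
        gm <- groupMeanFpkm(out$bundle$expression)
        pf <- percentFeminization(gm[fem$gene, "control_M"],
            gm[fem$gene, "control_F"], gm[fem$gene, "KO_M"])
        out$feminization <- data.frame(gene = fem$gene, model = "ko",
            percent = pf$percent, defined = pf$defined)
        writeTsv(out$feminization, file.path(outdir, "feminization.tsv"))
    }
    if ("chipnorm" %in% stages) {
        log("chipnorm: RiPPM and static-site normalization")
        wc <- out$bundle$windows
        peaks <- out$bundle$peaks
        out$rippm <- rippmFactors(wc, mergePeakUnion(peaks))
        scanM <- scanDifferentialWindows(wc,
            list(sex = "M", genotype = "control"),
            list(sex = "M", genotype = "KO"), windowSizes = 1000L)
        scanF <- scanDifferentialWindows(wc,
            list(sex = "F", genotype = "control"),
            list(sex = "F", genotype = "KO"), windowSizes = 1000L)
        out$static <- identifyStaticSites(
            stringentNondiffSites(scanM, peaks),
            stringentNondiffSites(scanF, peaks), wc)
        writeTsv(auditLog(out$static),
            file.path(outdir, "static_audit.tsv"))
        writeTsv(grToBed(staticSites(out$static)),
            file.path(outdir, "static_sites.bed"), col.names = FALSE)
    }
    if ("diffsites" %in% stages) {
        log("diffsites: differential histone-mark sites")
        wc <- out$bundle$windows
        # site discovery under standard depth normalization; the
        # static-site factors are used as the validation normalization
        # (peak-composition bias makes in-peak factors unsuitable here)
        out$sites <- list(
            sex = differentialSites(wc,
                list(sex = "F", genotype = "control"),
                list(sex = "M", genotype = "control")),
            koM = differentialSites(wc,
                list(sex = "M", genotype = "control"),
                list(sex = "M", genotype = "KO")),
            koF = differentialSites(wc,
                list(sex = "F", genotype = "control"),
                list(sex = "F", genotype = "KO")))
        koMStatic <- differentialSites(wc,
            list(sex = "M", genotype = "control"),
            list(sex = "M", genotype = "KO"),
            normFactors = scalingFactors(out$static))
        out$normOverlap <- compareNormalizations(out$sites$koM, koMStatic)
        out$sexBiasedSiteCounts <- callSexBiasedSites(out$sites$sex)
        for (nm in names(out$sites))
            writeTsv(grToBed(out$sites[[nm]],
                as.data.frame(mcols(out$sites[[nm]]))),
                file.path(outdir, paste0("sites_", nm, ".tsv")))
    }
    if ("integration" %in% stages) {
        log("integration: mapping sites to genes, pattern groups")
        genes <- out$bundle$genes
        domains <- buildRegulatoryDomains(genes)
        cls <- out$genesClassified$classification
        upM <- cls$gene[cls$ko_response_M == "up"]
        # the simulated track carries one repressive mark; enhancer-mark
        # site lists are empty here, exercising groups 1 and 5
        down <- out$sites$koM
        mf <- geneMarkFlags(upM, down, GRanges(), GRanges(),
            genes, domains)
        out$markFlags <- mf
        writeTsv(mf$flags, file.path(outdir, "mark_groups.tsv"))
    }
    if ("enrichment" %in% stages) {
        log("enrichment: gene-set enrichment report")
        cls <- out$genesClassified$classification
        universe <- cls$gene[cls$liver_expressed]
        femBiased <- intersect(cls$gene[cls$sex_bias == "female"], universe)
        upM <- intersect(cls$gene[cls$ko_response_M == "up"], universe)
        indep <- intersect(cls$gene[cls$stringent_independent], universe)
        out$enrichment <- enrichmentReport(list(
            female_biased_in_upKO_male = list(focal = femBiased,
                property = upM, universe = universe,
                background = "liver-expressed"),
            independent_in_upKO_male = list(focal = indep,
                property = upM, universe = universe,
                background = "liver-expressed")))
        writeTsv(out$enrichment, file.path(outdir, "enrichment.tsv"))
    }
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    out$manifest <- data.frame(
        file = sub(paste0("^", outdir, "/?"), "", files),
        md5 = unname(tools::md5sum(files)))
    writeTsv(out$manifest, file.path(outdir, "manifest.tsv"))
    invisible(out)
}
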