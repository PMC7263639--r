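# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched, so simulations are reproducible without side
# effects on the session.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
            inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Column indices of samples belonging to a sex/genotype group.
# `group` is either a logical/integer index vector or a named spec like
# list(sex = "M", genotype = "control").
groupColumns <- function(se, group) {
    if (is.list(group)) {
        cd <- colData(se)
        keep <- rep(TRUE, ncol(se))
        for (nm in names(group)) keep <- keep & cd[[nm]] %in% group[[nm]]
        which(keep)
    } else if (is.character(group)) {
        match(group, colnames(se))
    } else {
        which(seq_len(ncol(se)) %in% seq_len(ncol(se))[group])
    }
}

# Group-mean FPKM matrix (genes x 4 groups) for a LiverExpression object.
groupMeanFpkm <- function(le) {
    cd <- colData(le)
    grp <- paste(cd$genotype, cd$sex, sep = "_")
    fp <- assay(le, "fpkm")
    sapply(split(seq_len(ncol(le)), grp), function(j)
        rowMeans(fp[, j, drop = FALSE]))
}

stopifnotScalarProb <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
        stop(name, " must be a probability in (0, 1)")
}

# resize that clips at chromosome bounds without the out-of-bound warning
# GRanges emits for transient ranges near sequence ends
resizeTrim <- function(gr, width, fix) {
    suppressWarnings(GenomicRanges::trim(resize(gr, width, fix = fix)))
}
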