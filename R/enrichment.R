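#' Build a contingency table from gene sets
#'
#' Partitions the universe by membership in the focal set and the
#' property set: `A` = focal genes with the property, `B` = non-focal
#' genes with the property, `C` = focal genes without it, `D` = genes in
#' neither set. Both sets must be subsets of the universe.
#'
#' @param focal,property,universe character vectors of gene ids.
#' @return a [ContingencyTable-class].
#' @export
buildTable <- function(focal, property, universe) {
    focal <- unique(focal); property <- unique(property)
    universe <- unique(universe)
    if (!all(focal %in% universe) || !all(property %in% universe))
        stop("focal and property sets must be subsets of the universe")
    A <- length(intersect(focal, property))
    B <- length(setdiff(property, focal))
    C <- length(setdiff(focal, property))
    D <- length(universe) - A - B - C
    contingencyTable(A, B, C, D)
}

#' Enrichment score of a contingency table
#'
#' \eqn{ES = (A/B) / (C/D)}: how over-represented the property is in the
#' focal set relative to the rest of the background. Undefined (NA, with
#' a `direction` attribute noting infinite enrichment or depletion) when
#' B, C or D is zero.
#'
#' @param table a [ContingencyTable-class].
#' @return numeric scalar (full precision; display convention is one
#'   decimal).
#' @examples
#' enrichmentScore(contingencyTable(240, 602, 404, 10847))   # 10.70386
#' @export
enrichmentScore <- function(table) {
    A <- table@A; B <- table@B; C <- table@C; D <- table@D
    if (B == 0L || C == 0L || D == 0L) {
        es <- NA_real_
        attr(es, "direction") <- if (C == 0L && A > 0L)
            "infinite enrichment" else if (B == 0L && D > 0L)
            "infinite enrichment" else "undefined"
        return(es)
    }
    (A / B) / (C / D)
}

#' Two-sided Fisher exact p-value
#'
#' Exact two-sided p-value for independence of the 2x2 table, computed by
#' direct enumeration of the conditional hypergeometric distribution in
#' log space: the p-value is the total probability of all tables (with
#' the observed margins) no more probable than the observed one.
#'
#' @param table a [ContingencyTable-class], or the count `A` when the
#'   remaining counts are given.
#' @param B,C,D optional counts when `table` is given as a number.
#' @return p-value in (0, 1].
#' @export
fisherP <- function(table, B = NULL, C = NULL, D = NULL) {
    if (is(table, "ContingencyTable")) {
        A <- table@A; B <- table@B; C <- table@C; D <- table@D
    } else {
        A <- table
    }
    m <- A + B          # genes with the property
    n <- C + D          # genes without it
    k <- A + C          # focal-set size
    lo <- max(0L, k - n); hi <- min(k, m)
    if (lo == hi) return(1)
    x <- lo:hi
    lp <- dhyper(x, m, n, k, log = TRUE)
    lobs <- lp[A - lo + 1L]
    p <- sum(exp(lp[lp <= lobs + 1e-7]))
    min(p, 1)
}

#' Enrichment report over named gene-set comparisons
#'
#' One row per comparison of a focal set against a property set over a
#' background universe: the four counts, the enrichment score, the
#' percentage of focal genes carrying the property, and the Fisher exact
#' p-value. Comparisons with an empty focal set are flagged and get no
#' score.
#'
#' @param comparisons named list; each element is a list with elements
#'   `focal`, `property`, `universe` (character vectors of gene ids) and
#'   optionally `background` (a label for the report).
#' @return data.frame with columns `comparison`, `A`, `B`, `C`, `D`,
#'   `ES`, `percent`, `p`, `background`, `flag`.
#' @export
enrichmentReport <- function(comparisons) {
    rows <- lapply(names(comparisons), function(nm) {
        cmp <- comparisons[[nm]]
        bg <- if (!is.null(cmp$background)) cmp$background else "universe"
        if (length(cmp$focal) == 0L)
            return(data.frame(comparison = nm, A = 0L, B = NA_integer_,
                C = NA_integer_, D = NA_integer_, ES = NA_real_,
                percent = NA_real_, p = NA_real_, background = bg,
                flag = "empty focal set"))
        ct <- buildTable(cmp$focal, cmp$property, cmp$universe)
        es <- enrichmentScore(ct)
        data.frame(comparison = nm, A = ct@A, B = ct@B, C = ct@C,
            D = ct@D, ES = as.numeric(es),
            percent = 100 * ct@A / (ct@A + ct@C),
            p = fisherP(ct), background = bg, flag = "")
    })
    do.call(rbind, rows)
}
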