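#' Overrepresentation analysis (ORA) of two gene sets
#'
#' Fisher's exact test on the 2x2 membership table (in-AGS x in-FGS) over
#' a gene universe. The odds ratio is the conditional maximum-likelihood
#' estimate from the exact test (the sample odds ratio is available via
#' `estimator = "sample"`). The reported score is
#' `ln(odds_ratio + 0.1)`, so zero overlap gives `ln(0.1)`.
#'
#' @param ags,fgs [GeneSet-class] objects or character vectors; members
#'   outside the universe are dropped with a warning.
#' @param universe character vector of gene symbols defining the table
#'   margin. When running alongside network enrichment, pass the network
#'   node set for comparability.
#' @param alternative Fisher sidedness, default `"two.sided"`;
#'   `"greater"` gives the enrichment-only variant.
#' @param estimator `"cmle"` (default) or `"sample"`.
#' @return list with `p`, `odds_ratio`, `score`, `overlap`, and the table
#'   counts `n_ags`, `n_fgs`, `n_universe`.
#' @export
ora <- function(ags, fgs, universe,
                alternative = c("two.sided", "greater", "less"),
                estimator = c("cmle", "sample")) {
    alternative <- match.arg(alternative)
    estimator <- match.arg(estimator)
    if (is(ags, "GeneSet")) ags <- geneIds(ags)
    if (is(fgs, "GeneSet")) fgs <- geneIds(fgs)
    universe <- unique(as.character(universe))
    if (length(universe) == 0L)
        stop("empty universe")
    a0 <- unique(as.character(ags))
    f0 <- unique(as.character(fgs))
    ags <- intersect(a0, universe)
    fgs <- intersect(f0, universe)
    if (length(ags) < length(a0) || length(fgs) < length(f0))
        warning(length(a0) - length(ags), " AGS and ",
                length(f0) - length(fgs),
                " FGS member(s) outside the universe dropped",
                call. = FALSE)
    if (length(ags) == 0L || length(fgs) == 0L)
        stop("empty gene set after intersecting with the universe")
    a <- length(intersect(ags, fgs))
    b <- length(ags) - a
    c <- length(fgs) - a
    d <- length(universe) - a - b - c
    tab <- matrix(c(a, b, c, d), nrow = 2L)
    ft <- stats::fisher.test(tab, alternative = alternative)
    or <- if (estimator == "cmle") unname(ft$estimate) else {
        if (b * c == 0) {
            if (a * d == 0) NaN else Inf
        } else a * d / (b * c)
    }
    list(p = ft$p.value, odds_ratio = or, score = log(or + 0.1),
         overlap = a, n_ags = length(ags), n_fgs = length(fgs),
         n_universe = length(universe))
}

# shared ranking core: named weights, ordered decreasing with
# lexicographic tie-break on the gene symbol
.rankedList <- function(weights) {
    weights <- weights[!is.na(weights)]
    ord <- order(-weights, names(weights))
    weights[ord]
}

#' Rank a sample's genes by absolute expression (ssGSEA convention)
#'
#' Orders genes by `|expression|` descending, ties broken by symbol.
#' Note that ubiquitously high expressors (housekeeping genes) rank top
#' in every sample under this convention, which motivates the
#' cohort-standardized alternative [rankZgsea()].
#'
#' @param m omics matrix, genes x samples.
#' @param sample sample (column) identifier.
#' @return Named numeric vector of weights (`|value|`), sorted
#'   decreasingly; the names are the ranked gene list.
#' @export
rankSsgsea <- function(m, sample) {
    if (!sample %in% colnames(m))
        stop("sample '", sample, "' not found")
    .rankedList(abs(m[, sample]))
}

#' Rank a sample's genes by cohort-standardized deviation (ZGSEA)
#'
#' Orders genes by the absolute one-sample z-score, i.e. the deviation
#' from the gene's cohort mean in standard-deviation units, so
#' sample-specific alterations outrank constitutively high expression.
#'
#' @inheritParams rankSsgsea
#' @return Named numeric vector of weights (`|z|`), sorted decreasingly.
#' @export
rankZgsea <- function(m, sample) {
    z <- oneSampleZ(m)
    if (!sample %in% colnames(z))
        stop("sample '", sample, "' not found")
    .rankedList(abs(z[, sample]))
}

#' GSEA core enrichment score on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum: walking down the ranked list,
#' hits add `w^alpha / sum_hits(w^alpha)` and misses subtract a constant
#' step; the ES is the running-sum value of maximal absolute magnitude.
#' The default miss step is `1/N` (`missWeight = "uniform"`); the
#' `"complement"` option uses `1/(N - N_hits)`, under which the running
#' sum always returns to zero. Only the core ES is computed -- no
#' permutation machinery. FGS members absent from the ranked list are
#' dropped before scoring (logged); a set covering the whole list scores
#' 1 by convention (no misses).
#'
#' @param rankedList named numeric weight vector from [rankSsgsea()] /
#'   [rankZgsea()] (sorted decreasingly).
#' @param fgs [GeneSet-class] or character vector; at least one member
#'   must be present in the list.
#' @param weightExponent alpha, default 1 (classic weighted scheme);
#'   0 gives the unweighted KS statistic.
#' @param missWeight `"uniform"` (default) or `"complement"`.
#' @return ES in `[-1, 1]`.
#' @export
gseaES <- function(rankedList, fgs, weightExponent = 1,
                   missWeight = c("uniform", "complement")) {
    missWeight <- match.arg(missWeight)
    if (is(fgs, "GeneSet")) fgs <- geneIds(fgs)
    genes <- names(rankedList)
    hit <- genes %in% fgs
    nAbsent <- length(setdiff(fgs, genes))
    if (nAbsent > 0)
        message(nAbsent, " FGS member(s) absent from the ranked list dropped")
    if (!any(hit))
        stop("no FGS member present in the ranked list")
    n <- length(genes)
    nh <- sum(hit)
    if (nh == n)
        return(1)
    w <- abs(rankedList)^weightExponent
    inc <- numeric(n)
    inc[hit] <- w[hit] / sum(w[hit])
    missStep <- if (missWeight == "uniform") 1 / n else 1 / (n - nh)
    inc[!hit] <- -missStep
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
}
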