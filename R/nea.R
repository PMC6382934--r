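#' Expected number of connecting edges under the null
#'
#' The connectivity-normalized null: two sets with cumulative
#' connectivities `connAgs` and `connFgs` in a network of `nTotal` edges
#' are expected to share `connAgs * connFgs / (2 * nTotal)` edges if
#' member degrees were the only structure.
#'
#' @param connAgs,connFgs cumulative connectivities (sums of member
#'   degrees), non-negative.
#' @param nTotal total number of network edges, positive.
#' @return Expected edge count (non-negative number).
#' @export
expectedEdges <- function(connAgs, connFgs, nTotal) {
    if (nTotal <= 0)
        stop("'nTotal' must be positive")
    if (connAgs < 0 || connFgs < 0)
        stop("connectivities must be non-negative")
    connAgs * connFgs / (2 * nTotal)
}

#' Chi-squared statistic for network enrichment
#'
#' Two-cell goodness-of-fit on connecting vs non-connecting edges:
#' `(nObs - nExp)^2 / nExp + ((nTotal - nObs) - (nTotal - nExp))^2 /
#' (nTotal - nExp)`. One degree of freedom.
#'
#' @param nObs observed connecting edges.
#' @param nExp expected connecting edges; must satisfy `0 < nExp < nTotal`
#'   (`nExp == 0` is the degenerate null the caller maps to z = 0).
#' @param nTotal total network edges.
#' @return The chi-squared value (non-negative).
#' @export
neaChi2 <- function(nObs, nExp, nTotal) {
    if (nExp == 0)
        stop("degenerate null: nExp is zero (map to z = 0 upstream)")
    if (nExp >= nTotal)
        stop("'nExp' must be smaller than 'nTotal'")
    d <- nObs - nExp
    d^2 / nExp + d^2 / (nTotal - nExp)
}

#' Signed z-score from the enrichment chi-squared
#'
#' Maps the 1-df upper-tail probability `p` of `chi2` to a normal score
#' and signs it by the direction of deviation: depleted pairs
#' (`nObs < nExp`) get negative z. The default `mapping = "halved"` uses
#' `z = s * qnorm(1 - p/2)`, which equals `s * sqrt(chi2)` exactly and
#' maps chi2 = 0 to z = 0; `"onetailed"` is the literal one-tailed
#' reading `z = s * qnorm(1 - p)`. Tail probabilities are computed in
#' log-space so extreme statistics stay accurate, and |z| is capped at
#' `zMax` to keep matrices finite and orderable.
#'
#' @param chi2 non-negative chi-squared value(s); vectorized.
#' @param nObs,nExp observed and expected edge counts (define the sign).
#' @param mapping `"halved"` (default) or `"onetailed"`.
#' @param zMax cap on |z|, default 40.
#' @return Signed z-score(s).
#' @export
neaZ <- function(chi2, nObs, nExp, mapping = c("halved", "onetailed"),
                 zMax = 40) {
    mapping <- match.arg(mapping)
    stopifnot(all(chi2 >= 0))
    s <- ifelse(nObs >= nExp, 1, -1)
    logp <- stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
    if (mapping == "halved")
        logp <- logp - log(2)
    z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
    z <- pmin(pmax(z, -zMax), zMax)
    unname(s * pmax(z, 0))
}

#' Network enrichment score for one AGS-FGS pair
#'
#' Composes the primitives: counts connecting edges, sums member
#' connectivities, forms the expected count, the chi-squared statistic,
#' and the signed z-score. Symmetric in its two set arguments. A pair
#' where one set has zero connectivity after intersection with the
#' network yields a flagged `z = 0` result instead of an error so matrix
#' jobs complete; both sets entirely absent is an error.
#'
#' @param net a [GeneNetwork-class].
#' @param ags,fgs [GeneSet-class] objects or character vectors.
#' @param mapping,zMax passed to [neaZ()].
#' @return An [NEAResult-class].
#' @examples
#' net <- networkFromEdges(c("A", "B", "A"), c("B", "C", "C"))
#' neaScore(net, "A", c("B", "C"))
#' @export
neaScore <- function(net, ags, fgs, mapping = "halved", zMax = 40) {
    agsId <- if (is(ags, "GeneSet")) setName(ags) else "AGS"
    fgsId <- if (is(fgs, "GeneSet")) setName(fgs) else "FGS"
    if (is(ags, "GeneSet")) ags <- geneIds(ags)
    if (is(fgs, "GeneSet")) fgs <- geneIds(fgs)
    inA <- .nodeLogical(net, ags)
    inF <- .nodeLogical(net, fgs)
    if (!any(inA) && !any(inF))
        stop("both gene sets are entirely absent from the network")
    nTot <- nrow(net@edgeMat)
    connA <- sum(as.double(net@degree[inA]))
    connF <- sum(as.double(net@degree[inF]))
    nObs <- .edgeCountLogical(net, inA, inF)
    nExp <- expectedEdges(connA, connF, nTot)
    if (nExp == 0) {
        return(new("NEAResult", agsId = agsId, fgsId = fgsId,
                   nObs = as.numeric(nObs), nExp = 0, connAgs = connA,
                   connFgs = connF, chi2 = 0, p = 1, z = 0,
                   flag = "degenerate"))
    }
    chi2 <- neaChi2(nObs, nExp, nTot)
    z <- neaZ(chi2, nObs, nExp, mapping = mapping, zMax = zMax)
    new("NEAResult", agsId = agsId, fgsId = fgsId, nObs = as.numeric(nObs),
        nExp = nExp, connAgs = connA, connFgs = connF, chi2 = chi2,
        p = stats::pchisq(chi2, 1, lower.tail = FALSE), z = z, flag = "ok")
}

setMethod("show", "NEAResult", function(object) {
    cat(sprintf("NEAResult %s vs %s: n_obs = %g, n_exp = %.3f, z = %.3f%s\n",
                object@agsId, object@fgsId, object@nObs, object@nExp,
                object@z,
                if (object@flag != "ok")
                    paste0(" [", object@flag, "]") else ""))
})

#' Coerce an NEAResult to a one-row data.frame
#'
#' @param x an [NEAResult-class].
#' @param ... unused.
#' @export
setMethod("as.data.frame", "NEAResult", function(x, ...) {
    data.frame(ags = x@agsId, fgs = x@fgsId, n_obs = x@nObs, n_exp = x@nExp,
               conn_ags = x@connAgs, conn_fgs = x@connFgs, chi2 = x@chi2,
               p = x@p, z = x@z, flag = x@flag, stringsAsFactors = FALSE)
})

#' Pathway-level NEA score matrix (PWNEA)
#'
#' Scores every AGS against every FGS; rows follow the AGS collection
#' order, columns the FGS collection order. Degenerate or empty cells are
#' flagged in the result, never silently dropped.
#'
#' @param net a [GeneNetwork-class].
#' @param agsCollection,fgsCollection non-empty
#'   [GeneSetCollection-class] objects.
#' @param mapping,zMax passed to [neaZ()].
#' @return An [EnrichmentMatrix-class] with `mode = "pwnea"`.
#' @export
pwnea <- function(net, agsCollection, fgsCollection, mapping = "halved",
                  zMax = 40) {
    if (length(agsCollection) == 0L || length(fgsCollection) == 0L)
        stop("collections must be non-empty")
    nTot <- nrow(net@edgeMat)
    fgsInfo <- lapply(geneSets(fgsCollection), function(f) {
        inF <- .nodeLogical(net, geneIds(f))
        list(inF = inF, conn = sum(as.double(net@degree[inF])))
    })
    z <- matrix(0, nrow = length(agsCollection), ncol = length(fgsCollection),
                dimnames = list(names(agsCollection), names(fgsCollection)))
    flags <- list()
    for (a in names(agsCollection)) {
        inA <- .nodeLogical(net, geneIds(agsCollection[[a]]))
        connA <- sum(as.double(net@degree[inA]))
        for (f in names(fgsCollection)) {
            fi <- fgsInfo[[f]]
            nExp <- connA * fi$conn / (2 * nTot)
            if (nExp == 0) {
                flags[[length(flags) + 1L]] <-
                    data.frame(ags = a, fgs = f, flag = "degenerate")
                next
            }
            nObs <- .edgeCountLogical(net, inA, fi$inF)
            z[a, f] <- neaZ(neaChi2(nObs, nExp, nTot), nObs, nExp,
                            mapping = mapping, zMax = zMax)
        }
    }
    flags <- if (length(flags)) do.call(rbind, flags) else
        data.frame(ags = character(0), fgs = character(0),
                   flag = character(0))
    new("EnrichmentMatrix", zscores = z, mode = "pwnea", flags = flags)
}

#' Gene-node-level NEA score matrix (GNEA)
#'
#' Treats every network node (or a supplied subset) as a single-gene FGS
#' and scores each AGS against all of them; equivalent to [pwnea()]
#' against singleton sets, computed with a vectorized per-node edge
#' tally. When an AGS has no edge to a node, the score is negative and
#' driven by the expected count, so hubs are penalized more than
#' low-degree nodes.
#'
#' @param net a [GeneNetwork-class].
#' @param agsCollection non-empty [GeneSetCollection-class].
#' @param geneNodes optional character vector of nodes to use as
#'   single-gene FGS; defaults to all network nodes.
#' @param mapping,zMax passed to [neaZ()].
#' @return An [EnrichmentMatrix-class] with `mode = "gnea"`.
#' @export
gnea <- function(net, agsCollection, geneNodes = NULL, mapping = "halved",
                 zMax = 40) {
    if (length(agsCollection) == 0L)
        stop("AGS collection must be non-empty")
    if (is.null(geneNodes))
        geneNodes <- net@nodes
    idx <- match(geneNodes, net@nodes)
    if (anyNA(idx))
        stop("geneNodes absent from network: ",
             paste(utils::head(geneNodes[is.na(idx)], 5L), collapse = ", "))
    nTot <- nrow(net@edgeMat)
    deg <- as.double(net@degree[idx])
    z <- matrix(0, nrow = length(agsCollection), ncol = length(geneNodes),
                dimnames = list(names(agsCollection), geneNodes))
    flags <- list()
    for (a in names(agsCollection)) {
        inA <- .nodeLogical(net, geneIds(agsCollection[[a]]))
        connA <- sum(as.double(net@degree[inA]))
        if (connA == 0) {
            flags[[length(flags) + 1L]] <-
                data.frame(ags = a, fgs = "*", flag = "degenerate")
            next
        }
        nObs <- .incidentCounts(net, inA)[idx]
        nExp <- connA * deg / (2 * nTot)
        d <- nObs - nExp
        chi2 <- d^2 / nExp + d^2 / (nTot - nExp)
        z[a, ] <- neaZ(chi2, nObs, nExp, mapping = mapping, zMax = zMax)
    }
    flags <- if (length(flags)) do.call(rbind, flags) else
        data.frame(ags = character(0), fgs = character(0),
                   flag = character(0))
    new("EnrichmentMatrix", zscores = z, mode = "gnea", flags = flags)
}

#' @name EnrichmentMatrix-accessors
#' @title Accessors for EnrichmentMatrix objects
#' @param object an [EnrichmentMatrix-class].
NULL

#' @rdname EnrichmentMatrix-accessors
#' @export
setMethod("zScores", "EnrichmentMatrix", function(object) object@zscores)

#' @rdname EnrichmentMatrix-accessors
#' @export
setMethod("scoreMode", "EnrichmentMatrix", function(object) object@mode)

#' @rdname EnrichmentMatrix-accessors
#' @export
setMethod("scoreFlags", "EnrichmentMatrix", function(object) object@flags)

#' @rdname EnrichmentMatrix-accessors
#' @param x an [EnrichmentMatrix-class].
#' @export
setMethod("dim", "EnrichmentMatrix", function(x) dim(x@zscores))

#' @rdname EnrichmentMatrix-accessors
#' @param ... unused.
#' @export
setMethod("as.matrix", "EnrichmentMatrix", function(x, ...) x@zscores)

setMethod("show", "EnrichmentMatrix", function(object) {
    cat("EnrichmentMatrix [", object@mode, "]: ",
        nrow(object@zscores), " AGS x ", ncol(object@zscores),
        " features; ", nrow(object@flags), " flagged cell(s)\n", sep = "")
})
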