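#' @import methods
NULL

#' Undirected gene interaction network
#'
#' Simple (no self-loops, no duplicate edges), unweighted, undirected graph
#' over gene symbols. Edges are stored as an integer matrix indexing into
#' `nodes`, with the smaller index in column 1; per-node degrees are
#' pre-computed because every enrichment score depends on them.
#'
#' @slot nodes character vector of gene symbols (case-sensitive, unique).
#' @slot edgeMat integer matrix with two columns; each row one edge,
#'   `edgeMat[, 1] < edgeMat[, 2]`.
#' @slot degree integer vector aligned with `nodes`; number of incident
#'   edges per node. Every stored node has degree >= 1.
#'
#' @seealso [readEdgeList()], [simNetwork()], [countConnectingEdges()]
#' @exportClass GeneNetwork
setClass("GeneNetwork",
    representation(nodes = "character", edgeMat = "matrix",
                   degree = "integer"))

setValidity("GeneNetwork", function(object) {
    msg <- character()
    n <- length(object@nodes)
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node symbols must be unique")
    em <- object@edgeMat
    if (!is.integer(em) || ncol(em) != 2L)
        msg <- c(msg, "edgeMat must be an integer matrix with two columns")
    else {
        if (nrow(em) == 0L)
            msg <- c(msg, "network must contain at least one edge")
        if (any(em < 1L) || any(em > n))
            msg <- c(msg, "edge indices out of range")
        if (any(em[, 1L] >= em[, 2L]))
            msg <- c(msg, "edges must be canonical (col1 < col2): no self-loops")
        key <- (em[, 1L] - 1) * as.double(n) + em[, 2L]
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate edges are not allowed")
        deg <- tabulate(c(em[, 1L], em[, 2L]), nbins = n)
        if (!identical(as.integer(deg), object@degree))
            msg <- c(msg, "degree slot inconsistent with edge matrix")
        if (any(deg == 0L))
            msg <- c(msg, "zero-degree nodes must not be stored")
    }
    if (length(object@degree) != n)
        msg <- c(msg, "degree must align with nodes")
    if (length(msg)) msg else TRUE
})

#' A named gene set (AGS or FGS)
#'
#' @slot setName identifier, unique within a collection. For per-sample
#'   altered gene sets this is the sample identifier.
#' @slot geneIds unique member gene symbols.
#' @slot className free-text class label, e.g. `"top.200"`,
#'   `"significant.filtered.mini"`, `"mutations.mgs"` or `"fgs"`.
#' @slot description optional free text (GMT column 2).
#'
#' @exportClass GeneSet
setClass("GeneSet",
    representation(setName = "character", geneIds = "character",
                   className = "character", description = "character"),
    prototype(className = "", description = ""))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@setName) != 1L || !nzchar(object@setName))
        msg <- c(msg, "setName must be a single non-empty string")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "geneIds must be unique")
    if (length(msg)) msg else TRUE
})

#' Collection of gene sets
#'
#' Thin list container enforcing unique set names. Supports `length()`,
#' `names()`, `[`, `[[` and `lapply()` via [geneSets()].
#'
#' @slot sets list of [GeneSet-class] objects, named by their `setName`.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    ok <- vapply(object@sets, is, logical(1), class2 = "GeneSet")
    if (!all(ok))
        msg <- c(msg, "all elements must be GeneSet objects")
    else {
        nm <- unname(vapply(object@sets, function(s) s@setName,
                            character(1)))
        if (anyDuplicated(nm))
            msg <- c(msg, "set names must be unique within a collection")
        if (!identical(names(object@sets), nm))
            msg <- c(msg, "list names must equal the contained setNames")
    }
    if (length(msg)) msg else TRUE
})

#' Network enrichment result for one AGS-FGS pair
#'
#' @slot agsId,fgsId identifiers of the two sets.
#' @slot nObs observed number of network edges connecting the two sets.
#' @slot nExp number of connecting edges expected under the null,
#'   `connAgs * connFgs / (2 * N_total)`.
#' @slot connAgs,connFgs cumulative connectivity (sum of member degrees).
#' @slot chi2 the 1-df goodness-of-fit statistic on the edge 2-cell table.
#' @slot p upper-tail chi-squared probability of `chi2`.
#' @slot z signed normal score; negative when the pair is depleted
#'   (`nObs < nExp`).
#' @slot flag `"ok"` or `"degenerate"` (expected edges zero, z forced to 0).
#' @exportClass NEAResult
setClass("NEAResult",
    representation(agsId = "character", fgsId = "character",
                   nObs = "numeric", nExp = "numeric",
                   connAgs = "numeric", connFgs = "numeric",
                   chi2 = "numeric", p = "numeric", z = "numeric",
                   flag = "character"),
    prototype(flag = "ok"))

setValidity("NEAResult", function(object) {
    msg <- character()
    if (object@chi2 < 0) msg <- c(msg, "chi2 must be non-negative")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
    if (object@nExp < 0) msg <- c(msg, "nExp must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Matrix of enrichment z-scores
#'
#' Rows are AGS (one per sample), columns are FGS (pathways for PWNEA,
#' single network genes for GNEA). Cells that could not be scored
#' normally are listed in `flags` rather than silently dropped.
#'
#' @slot zscores numeric matrix of signed z-scores with dimnames.
#' @slot mode `"pwnea"` or `"gnea"`.
#' @slot flags data.frame with columns `ags`, `fgs`, `flag` for annotated
#'   cells (z set to 0 there).
#' @exportClass EnrichmentMatrix
setClass("EnrichmentMatrix",
    representation(zscores = "matrix", mode = "character",
                   flags = "data.frame"))

setValidity("EnrichmentMatrix", function(object) {
    msg <- character()
    if (!object@mode %in% c("pwnea", "gnea"))
        msg <- c(msg, "mode must be 'pwnea' or 'gnea'")
    if (is.null(rownames(object@zscores)) || is.null(colnames(object@zscores)))
        msg <- c(msg, "zscores must carry row and column names")
    if (any(!is.finite(object@zscores)))
        msg <- c(msg, "z-scores must be finite (capped)")
    if (length(msg)) msg else TRUE
})

#' Drug screen response table
#'
#' Samples x drugs response values plus the screen's orientation: whether
#' larger values mean more sensitive. Screens disagree on this (the CTD
#' convention is inverted relative to CCLE/CGP), so the flag is mandatory
#' and consumed before any cross-screen comparison.
#'
#' @slot response numeric matrix, samples in rows, drugs in columns.
#' @slot higherIsSensitive single logical; the screen-wide orientation.
#' @slot screenName identifier.
#' @exportClass DrugScreen
setClass("DrugScreen",
    representation(response = "matrix", higherIsSensitive = "logical",
                   screenName = "character"),
    prototype(screenName = "screen"))

setValidity("DrugScreen", function(object) {
    msg <- character()
    if (length(object@higherIsSensitive) != 1L ||
        is.na(object@higherIsSensitive))
        msg <- c(msg, "higherIsSensitive must be TRUE or FALSE (mandatory)")
    if (is.null(rownames(object@response)) || is.null(colnames(object@response)))
        msg <- c(msg, "response must carry sample and drug names")
    if (length(msg)) msg else TRUE
})
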