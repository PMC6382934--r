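#' Build a GeneNetwork from two endpoint vectors
#'
#' Symmetrizes and deduplicates the edges, drops self-loops, and
#' pre-computes node degrees. Nodes are whatever symbols appear in at least
#' one retained edge, so every stored node has degree >= 1. Identifiers are
#' case-sensitive opaque strings; no alias mapping is attempted.
#'
#' @param from,to character vectors of equal length; one edge per position.
#' @return A [GeneNetwork-class].
#' @examples
#' net <- networkFromEdges(c("A", "B", "A"), c("B", "C", "C"))
#' totalEdges(net)
#' @export
networkFromEdges <- function(from, to) {
    from <- as.character(from)
    to <- as.character(to)
    if (length(from) != length(to))
        stop("'from' and 'to' must have equal length")
    keep <- from != to
    nSelf <- sum(!keep)
    if (nSelf > 0)
        message(nSelf, " self-loop(s) dropped")
    from <- from[keep]
    to <- to[keep]
    if (length(from) == 0L)
        stop("no valid edges (all were self-loops or input was empty)")
    nodes <- sort(unique(c(from, to)))
    i <- match(from, nodes)
    j <- match(to, nodes)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    key <- (lo - 1) * as.double(length(nodes)) + hi
    first <- !duplicated(key)
    nDup <- sum(!first)
    if (nDup > 0)
        message(nDup, " duplicate edge(s) collapsed")
    em <- cbind(lo[first], hi[first])
    storage.mode(em) <- "integer"
    deg <- tabulate(c(em[, 1L], em[, 2L]), nbins = length(nodes))
    new("GeneNetwork", nodes = nodes, edgeMat = em, degree = as.integer(deg))
}

#' Read a gene interaction network from a delimited edge list
#'
#' Reads a two-(or more-)column delimited text file, one edge per line.
#' Lines starting with `#` are comments. Columns beyond the first two
#' (e.g. confidence scores) are ignored with a note: the enrichment
#' statistic uses only edge counts, so the network is unweighted. Edges
#' are deduplicated regardless of orientation and self-loops are dropped
#' (their count is reported).
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, TAB by default.
#' @return A [GeneNetwork-class].
#' @export
readEdgeList <- function(path, delimiter = "\t") {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    if (!any(keep))
        stop("no edges found in ", path)
    idx <- which(keep)
    fields <- strsplit(lines[idx], delimiter, fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L))
        stop("malformed line ", idx[which(nf < 2L)[1L]],
             ": fewer than 2 fields")
    if (any(nf > 2L))
        message("extra columns ignored on ", sum(nf > 2L),
                " line(s); network treated as unweighted")
    from <- vapply(fields, `[[`, character(1), 1L)
    to <- vapply(fields, `[[`, character(1), 2L)
    net <- networkFromEdges(from, to)
    message("network: ", length(nodes(net)), " nodes, ",
            totalEdges(net), " edges")
    net
}

#' @name GeneNetwork-accessors
#' @title Accessors for GeneNetwork objects
#' @param object a [GeneNetwork-class].
#' @param genes optional gene symbols; degrees are returned for those
#'   (0 for genes absent from the network).
#' @param ... unused.
#' @return `nodes`: character vector; `nodeDegree`: named integer vector;
#'   `totalEdges`: single integer; `edgeList`: two-column character matrix.
NULL

#' @rdname GeneNetwork-accessors
#' @export
setMethod("nodes", "GeneNetwork", function(object, ...) object@nodes)

#' @rdname GeneNetwork-accessors
#' @export
setMethod("nodeDegree", "GeneNetwork", function(object, genes, ...) {
    deg <- structure(object@degree, names = object@nodes)
    if (missing(genes))
        return(deg)
    out <- structure(integer(length(genes)), names = genes)
    hit <- genes %in% object@nodes
    out[hit] <- deg[genes[hit]]
    out
})

#' @rdname GeneNetwork-accessors
#' @export
setMethod("totalEdges", "GeneNetwork",
          function(object) nrow(object@edgeMat))

#' @rdname GeneNetwork-accessors
#' @export
setMethod("edgeList", "GeneNetwork", function(object) {
    cbind(object@nodes[object@edgeMat[, 1L]],
          object@nodes[object@edgeMat[, 2L]])
})

setMethod("show", "GeneNetwork", function(object) {
    deg <- object@degree
    cat("GeneNetwork with", length(object@nodes), "nodes and",
        nrow(object@edgeMat), "edges\n")
    cat("  degree: min", min(deg), "| median", stats::median(deg),
        "| max", max(deg), "\n")
})

# logical membership vector over network nodes; warns about absentees
# through `warnAbsent` ("" disables)
.nodeLogical <- function(net, genes, warnAbsent = "") {
    genes <- unique(as.character(genes))
    i <- match(genes, net@nodes)
    if (anyNA(i) && nzchar(warnAbsent)) {
        absent <- genes[is.na(i)]
        warning(warnAbsent, ": ", length(absent),
                " gene(s) absent from network: ",
                paste(utils::head(absent, 5L), collapse = ", "),
                if (length(absent) > 5L) ", ..." else "",
                call. = FALSE)
    }
    v <- logical(length(net@nodes))
    v[i[!is.na(i)]] <- TRUE
    v
}

# number of edges from each node to the set flagged in `inSet`
# (per node g: edges (g, v) with v in the set; no self-loops exist)
.incidentCounts <- function(net, inSet) {
    em <- net@edgeMat
    idx <- c(em[inSet[em[, 1L]], 2L], em[inSet[em[, 2L]], 1L])
    tabulate(idx, nbins = length(net@nodes))
}

# edge count between two logical node sets
.edgeCountLogical <- function(net, in1, in2) {
    em <- net@edgeMat
    u <- em[, 1L]
    v <- em[, 2L]
    sum((in1[u] & in2[v]) | (in2[u] & in1[v]))
}

#' Cumulative connectivity of a gene set
#'
#' Sum of network degrees over the members present in the network
#' (the null model's N_AGS / N_FGS). Members absent from the network
#' contribute zero and are reported via a warning.
#'
#' @param net a [GeneNetwork-class].
#' @param genes character vector of gene symbols, or a [GeneSet-class].
#' @return A single non-negative number.
#' @export
cumulativeConnectivity <- function(net, genes) {
    if (is(genes, "GeneSet")) genes <- geneIds(genes)
    inSet <- .nodeLogical(net, genes, warnAbsent = "cumulativeConnectivity")
    sum(as.double(net@degree[inSet]))
}

#' Count network edges connecting two gene sets
#'
#' Number of distinct network edges with one endpoint in `set1` and the
#' other in `set2`. Each edge is counted at most once; edges internal to
#' one set only do not count. An edge with both endpoints in the
#' intersection of the two sets satisfies the predicate and counts once
#' (the overlap convention).
#'
#' @param net a [GeneNetwork-class].
#' @param set1,set2 character vectors of gene symbols or [GeneSet-class]
#'   objects. Genes absent from the network are ignored.
#' @return A single non-negative integer.
#' @examples
#' net <- networkFromEdges(c("A", "B", "A"), c("B", "C", "C"))
#' countConnectingEdges(net, "A", c("B", "C"))  # 2
#' @export
countConnectingEdges <- function(net, set1, set2) {
    if (is(set1, "GeneSet")) set1 <- geneIds(set1)
    if (is(set2, "GeneSet")) set2 <- geneIds(set2)
    in1 <- .nodeLogical(net, set1)
    in2 <- .nodeLogical(net, set2)
    .edgeCountLogical(net, in1, in2)
}
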