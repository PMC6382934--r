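# Generics for the package's S4 accessors. Named to avoid clashing with
# igraph's S3 degree()/edges().

#' @rdname GeneNetwork-accessors
#' @export
setGeneric("nodes", function(object, ...) standardGeneric("nodes"))

#' @rdname GeneNetwork-accessors
#' @export
setGeneric("nodeDegree", function(object, genes, ...)
    standardGeneric("nodeDegree"))

#' @rdname GeneNetwork-accessors
#' @export
setGeneric("totalEdges", function(object) standardGeneric("totalEdges"))

#' @rdname GeneNetwork-accessors
#' @export
setGeneric("edgeList", function(object) standardGeneric("edgeList"))

#' @rdname GeneSet-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneSet-accessors
#' @export
setGeneric("setName", function(object) standardGeneric("setName"))

#' @rdname GeneSet-accessors
#' @export
setGeneric("className", function(object) standardGeneric("className"))

#' @rdname GeneSetCollection-methods
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname EnrichmentMatrix-accessors
#' @export
setGeneric("zScores", function(object) standardGeneric("zScores"))

#' @rdname EnrichmentMatrix-accessors
#' @export
setGeneric("scoreMode", function(object) standardGeneric("scoreMode"))

#' @rdname EnrichmentMatrix-accessors
#' @export
setGeneric("scoreFlags", function(object) standardGeneric("scoreFlags"))

#' @rdname DrugScreen-accessors
#' @export
setGeneric("responseMatrix", function(object) standardGeneric("responseMatrix"))

#' @rdname DrugScreen-accessors
#' @export
setGeneric("higherIsSensitive", function(object)
    standardGeneric("higherIsSensitive"))
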