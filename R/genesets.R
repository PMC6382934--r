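#' Construct a GeneSet
#'
#' @param setName identifier (for per-sample AGS: the sample id).
#' @param geneIds member gene symbols; duplicates removed with a warning.
#' @param className class label (e.g. `"top.200"`, `"fgs"`).
#' @param description optional free text.
#' @return A [GeneSet-class].
#' @export
geneSet <- function(setName, geneIds, className = "", description = "") {
    geneIds <- as.character(geneIds)
    if (anyDuplicated(geneIds)) {
        warning("duplicate members in set '", setName, "' removed",
                call. = FALSE)
        geneIds <- unique(geneIds)
    }
    new("GeneSet", setName = as.character(setName), geneIds = geneIds,
        className = className, description = description)
}

#' Construct a GeneSetCollection
#'
#' @param sets list of [GeneSet-class] objects.
#' @return A [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets) {
    names(sets) <- vapply(sets, function(s) s@setName, character(1))
    new("GeneSetCollection", sets = sets)
}

#' @name GeneSet-accessors
#' @title Accessors for GeneSet objects
#' @param object a [GeneSet-class].
NULL

#' @rdname GeneSet-accessors
#' @export
setMethod("geneIds", "GeneSet", function(object) object@geneIds)

#' @rdname GeneSet-accessors
#' @export
setMethod("setName", "GeneSet", function(object) object@setName)

#' @rdname GeneSet-accessors
#' @export
setMethod("className", "GeneSet", function(object) object@className)

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@setName, "'", sep = "")
    if (nzchar(object@className)) cat(" [", object@className, "]", sep = "")
    cat(": ", length(object@geneIds), " genes\n", sep = "")
})

#' @name GeneSetCollection-methods
#' @title Methods for GeneSetCollection objects
#' @param object,x a [GeneSetCollection-class].
#' @param i index or name.
NULL

#' @rdname GeneSetCollection-methods
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @rdname GeneSetCollection-methods
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-methods
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-methods
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @rdname GeneSetCollection-methods
#' @export
setMethod("[", "GeneSetCollection",
          function(x, i) geneSetCollection(x@sets[i]))

setMethod("show", "GeneSetCollection", function(object) {
    sizes <- vapply(object@sets, function(s) length(s@geneIds), integer(1))
    cat("GeneSetCollection of", length(object@sets), "sets")
    if (length(sizes))
        cat(" (sizes ", min(sizes), "..", max(sizes), ")", sep = "")
    cat("\n")
})

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, TAB-separated `name`, `description`,
#' then member symbols. Duplicate members within a line are dropped with
#' a warning; duplicate set names or lines with fewer than three fields
#' are errors. `writeGmt` followed by `readGmt` is an identity on
#' membership.
#'
#' @param path file path.
#' @param className class label attached to every set read.
#' @return `readGmt`: a [GeneSetCollection-class]; `writeGmt`: invisibly,
#'   the path.
#' @export
readGmt <- function(path, className = "") {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    keep <- which(nzchar(trimws(lines)))
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("malformed GMT line ", keep[which(nf < 3L)[1L]],
             ": fewer than 3 fields")
    nm <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate set name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    sets <- lapply(fields, function(f)
        geneSet(f[[1L]], f[-c(1L, 2L)], className = className,
                description = f[[2L]]))
    geneSetCollection(sets)
}

#' @rdname readGmt
#' @param collection a [GeneSetCollection-class] to write.
#' @export
writeGmt <- function(collection, path) {
    lines <- vapply(geneSets(collection), function(s) {
        desc <- if (nzchar(s@description)) s@description else
            if (nzchar(s@className)) s@className else "na"
        paste(c(s@setName, desc, s@geneIds), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' One-sample z-scores of an omics matrix
#'
#' Standardizes each gene against its cohort: `z = (x - mean) / sd`, with
#' mean and sample standard deviation (n - 1) taken across all samples.
#' Genes with zero cohort variance get `NA` rows and are thereby excluded
#' from any downstream ranking.
#'
#' @param m numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns. At least 3 samples are required for cohort
#'   statistics.
#' @return A matrix of z-scores with the shape of `m`.
#' @export
oneSampleZ <- function(m) {
    if (!is.matrix(m) || !is.numeric(m))
        stop("'m' must be a numeric matrix")
    if (ncol(m) < 3L)
        stop("cohort statistics need at least 3 samples")
    mu <- rowMeans(m)
    sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
    z <- (m - mu) / sdv
    z[sdv == 0, ] <- NA_real_
    z
}

#' Fixed-size AGS: top-N most deviating genes per sample
#'
#' For each sample, the `n` genes with the largest absolute one-sample
#' z-score, regardless of formal significance. Ties at the cutoff are
#' broken by lexicographic gene symbol for determinism. Genes with
#' undefined z (constant cohort rows) are excluded.
#'
#' @param m omics matrix, genes x samples.
#' @param n set size; actual size is `min(n, usable genes)`.
#' @return A [GeneSetCollection-class] with one set per sample, class
#'   label `"top.<n>"`.
#' @export
buildTopN <- function(m, n) {
    stopifnot(n >= 1)
    z <- oneSampleZ(m)
    lab <- paste0("top.", n)
    sets <- lapply(colnames(z), function(s) {
        zi <- z[, s]
        zi <- zi[!is.na(zi)]
        ord <- order(-abs(zi), names(zi))
        geneSet(s, names(zi)[utils::head(ord, n)], className = lab)
    })
    geneSetCollection(sets)
}

#' Variable-size AGS: genes significantly deviating from the cohort mean
#'
#' Two-sided normal p-values from the one-sample z-scores are
#' Benjamini-Hochberg adjusted across genes within each sample; genes
#' with adjusted p below `alpha` form the sample's set. Sizes vary with
#' the signal.
#'
#' @param m omics matrix, genes x samples.
#' @param alpha FDR threshold, default 0.05.
#' @return A [GeneSetCollection-class], class label `"significant"`.
#' @export
buildSignificant <- function(m, alpha = 0.05) {
    z <- oneSampleZ(m)
    sets <- lapply(colnames(z), function(s) {
        zi <- z[, s]
        zi <- zi[!is.na(zi)]
        p <- 2 * stats::pnorm(-abs(zi))
        q <- bhAdjust(p)
        hit <- names(zi)[q < alpha]
        geneSet(s, sort(hit), className = "significant")
    })
    geneSetCollection(sets)
}

# Single-gene enrichment p-values for a roster of genes against one
# filter set: p_enrich = upper-tail normal probability of the signed z of
# AGS = {g} vs the filter set. Vectorized over genes via pre-computed
# incident counts.
.singleGeneEnrichP <- function(net, geneIdx, inFilter, connFilter,
                               excludeSelfDegree = FALSE) {
    nTot <- nrow(net@edgeMat)
    t <- .incidentCounts(net, inFilter)
    nObs <- t[geneIdx]
    deg <- as.double(net@degree[geneIdx])
    cf <- rep(connFilter, length(geneIdx))
    if (excludeSelfDegree) {
        self <- inFilter[geneIdx]
        cf[self] <- cf[self] - deg[self]
    }
    nExp <- deg * cf / (2 * nTot)
    z <- vapply(seq_along(nObs), function(k) {
        if (nExp[k] <= 0) return(0)
        neaZ(neaChi2(nObs[k], nExp[k], nTot), nObs[k], nExp[k])
    }, numeric(1))
    stats::pnorm(z, lower.tail = FALSE)
}

#' Network-filter an AGS collection (mini / maxi classes)
#'
#' Retains a member gene iff its single-gene network enrichment against at
#' least one filter FGS -- or against the same sample's companion set, if
#' given -- passes the Benjamini-Hochberg FDR threshold. BH is applied
#' within each sample over all member x filter-set tests (companion tests
#' included in the same family). Genes absent from the network can never
#' pass and are dropped.
#'
#' @param collection AGS collection to filter (e.g. class `"significant"`).
#' @param net scoring [GeneNetwork-class].
#' @param filterFgs [GeneSetCollection-class] of filter pathways: the
#'   cancer-pathway set for the `mini` variant, a signaling-pathway
#'   collection for `maxi`.
#' @param companion optional [GeneSetCollection-class] keyed by sample
#'   (e.g. the same samples' `mutations.mgs` sets).
#' @param fdr FDR threshold, default 0.05.
#' @param variant `"mini"` or `"maxi"`; only affects the output class
#'   label, `<parent>.filtered.<variant>`.
#' @return A filtered [GeneSetCollection-class]; each output set is a
#'   subset of its parent.
#' @export
filterAgsByNea <- function(collection, net, filterFgs, companion = NULL,
                           fdr = 0.05, variant = c("mini", "maxi")) {
    variant <- match.arg(variant)
    if (length(filterFgs) == 0L)
        stop("empty filter collection")
    filt <- lapply(geneSets(filterFgs), function(f) {
        inF <- .nodeLogical(net, geneIds(f))
        list(inF = inF, conn = sum(as.double(net@degree[inF])))
    })
    sets <- lapply(geneSets(collection), function(ags) {
        members <- geneIds(ags)
        idx <- match(members, net@nodes)
        present <- !is.na(idx)
        idx <- idx[present]
        lab <- paste0(if (nzchar(className(ags))) className(ags) else
                      "significant", ".filtered.", variant)
        if (length(idx) == 0L)
            return(geneSet(setName(ags), character(0), className = lab))
        pmat <- vapply(filt, function(f)
            .singleGeneEnrichP(net, idx, f$inF, f$conn), numeric(length(idx)))
        pmat <- matrix(pmat, nrow = length(idx))
        if (!is.null(companion) && setName(ags) %in% names(companion)) {
            comp <- geneIds(companion[[setName(ags)]])
            inC <- .nodeLogical(net, comp)
            pc <- .singleGeneEnrichP(net, idx, inC,
                                     sum(as.double(net@degree[inC])),
                                     excludeSelfDegree = TRUE)
            pmat <- cbind(pmat, pc)
        }
        q <- matrix(bhAdjust(as.vector(pmat)), nrow = nrow(pmat))
        keep <- apply(q < fdr, 1L, any)
        geneSet(setName(ags), sort(members[present][keep]), className = lab)
    })
    geneSetCollection(sets)
}

#' Mutation-based AGS (mutations.mgs)
#'
#' Per sample, starts from all point-mutated genes and retains a gene iff
#' its single-gene network enrichment against the cancer pathway set or
#' against the rest of the sample's mutated genes (the gene itself
#' excluded, so its own edges cannot inflate the score) passes BH FDR.
#' This separates putative drivers, which cluster in the network around
#' cancer pathways and each other, from randomly scattered passengers.
#'
#' @param mm binary mutation matrix, genes x samples (values 0/1).
#' @param net scoring [GeneNetwork-class].
#' @param cancerFgs [GeneSet-class]: the cancer reference pathway.
#' @param fdr FDR threshold, default 0.05. BH is applied within each
#'   sample over both test families.
#' @return A [GeneSetCollection-class], class label `"mutations.mgs"`.
#'   Samples with no mutations give empty sets with a warning.
#' @export
buildMutationMgs <- function(mm, net, cancerFgs, fdr = 0.05) {
    if (!all(mm %in% c(0, 1)))
        stop("mutation matrix must be binary")
    inCancer <- .nodeLogical(net, geneIds(cancerFgs))
    connCancer <- sum(as.double(net@degree[inCancer]))
    sets <- lapply(colnames(mm), function(s) {
        mut <- rownames(mm)[mm[, s] == 1]
        if (length(mut) == 0L) {
            warning("sample '", s, "' has no mutations", call. = FALSE)
            return(geneSet(s, character(0), className = "mutations.mgs"))
        }
        idx <- match(mut, net@nodes)
        present <- !is.na(idx)
        idx <- idx[present]
        if (length(idx) == 0L)
            return(geneSet(s, character(0), className = "mutations.mgs"))
        inMut <- .nodeLogical(net, mut)
        p1 <- .singleGeneEnrichP(net, idx, inCancer, connCancer)
        p2 <- .singleGeneEnrichP(net, idx, inMut,
                                 sum(as.double(net@degree[inMut])),
                                 excludeSelfDegree = TRUE)
        q <- matrix(bhAdjust(c(p1, p2)), ncol = 2L)
        keep <- q[, 1L] < fdr | q[, 2L] < fdr
        geneSet(s, sort(mut[present][keep]), className = "mutations.mgs")
    })
    geneSetCollection(sets)
}

#' Combine platform-specific AGS collections
#'
#' Per sample, the deduplicated union of members across the supplied
#' collections, restricted to samples shared by all of them.
#'
#' @param collections list of [GeneSetCollection-class] objects sharing
#'   sample identifiers (set names).
#' @return A [GeneSetCollection-class], class label `"combined"`.
#' @export
combineAgs <- function(collections) {
    stopifnot(length(collections) >= 1L)
    shared <- Reduce(intersect, lapply(collections, names))
    if (length(shared) == 0L)
        stop("collections share no sample identifiers")
    sets <- lapply(shared, function(s) {
        members <- unique(unlist(lapply(collections,
                                        function(cc) geneIds(cc[[s]]))))
        geneSet(s, sort(members), className = "combined")
    })
    geneSetCollection(sets)
}
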