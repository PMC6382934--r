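#' Generate a synthetic gene interaction network
#'
#' Connected simple undirected graph at desk scale, emulating the shape
#' of a dense integrated functional-coupling network. Two degree models:
#' `"preferential"` (Barabasi-Albert attachment, heavy-tailed degrees
#' with hubs) and `"erdos"` (G(n, m), near-Poisson degrees; redrawn up
#' to 100 times until connected). Deterministic per seed.
#'
#' @param nNodes number of genes, at least 10.
#' @param meanDegree target mean degree (edges ~ nNodes * meanDegree / 2).
#' @param model `"preferential"` (default) or `"erdos"`.
#' @param seed RNG seed (mandatory).
#' @return A [GeneNetwork-class] with nodes named `g0001`, `g0002`, ...
#' @export
simNetwork <- function(nNodes, meanDegree = 20,
                       model = c("preferential", "erdos"), seed) {
    model <- match.arg(model)
    if (nNodes < 10)
        stop("'nNodes' must be at least 10")
    if (meanDegree < 2 || meanDegree >= nNodes)
        stop("infeasible mean degree")
    g <- .withSeed(seed, {
        if (model == "preferential") {
            igraph::sample_pa(nNodes, m = max(1L, round(meanDegree / 2)),
                              directed = FALSE)
        } else {
            m <- round(nNodes * meanDegree / 2)
            if (m > choose(nNodes, 2))
                stop("infeasible edge count")
            gg <- NULL
            for (try in seq_len(100L)) {
                gg <- igraph::sample_gnm(nNodes, m)
                if (igraph::is_connected(gg)) break
                gg <- NULL
            }
            if (is.null(gg))
                stop("could not draw a connected graph; raise meanDegree")
            gg
        }
    })
    el <- igraph::as_edgelist(g, names = FALSE)
    nm <- sprintf("g%04d", seq_len(nNodes))
    networkFromEdges(nm[el[, 1L]], nm[el[, 2L]])
}

#' Plant a functional gene set
#'
#' Uniform sample of network nodes, serving as ground-truth FGS.
#'
#' @param net a [GeneNetwork-class].
#' @param size set size, below the node count.
#' @param seed RNG seed.
#' @param setName,className labels for the resulting [GeneSet-class].
#' @return A [GeneSet-class].
#' @export
plantFgs <- function(net, size, seed, setName = "FGS", className = "fgs") {
    if (size >= length(net@nodes))
        stop("'size' must be below the node count")
    members <- .withSeed(seed, sample(net@nodes, size))
    geneSet(setName, sort(members), className = className)
}

#' Generate an AGS with planted excess connectivity to an FGS
#'
#' Samples nodes without replacement with probability weight
#' `1 + bias * edgesToFgs(node)`, so `bias = 0` reduces to uniform
#' (null) sampling and larger bias plants enrichment toward the FGS.
#' Overlap with the FGS is allowed unless `disjoint = TRUE`.
#'
#' @param net a [GeneNetwork-class].
#' @param fgs target [GeneSet-class] or character vector.
#' @param size AGS size.
#' @param bias non-negative connectivity bias.
#' @param seed RNG seed.
#' @param disjoint exclude FGS members from the candidate pool.
#' @param setName label for the resulting set.
#' @return A [GeneSet-class] with class label `"synthetic.ags"`.
#' @export
simEnrichedAgs <- function(net, fgs, size, bias, seed, disjoint = FALSE,
                           setName = "AGS") {
    if (bias < 0)
        stop("'bias' must be non-negative")
    if (is(fgs, "GeneSet")) fgs <- geneIds(fgs)
    inF <- .nodeLogical(net, fgs)
    w <- 1 + bias * .incidentCounts(net, inF)
    cand <- seq_along(net@nodes)
    if (disjoint)
        cand <- cand[!inF]
    if (size > length(cand))
        stop("'size' infeasible for the candidate pool")
    members <- .withSeed(seed,
        sample(net@nodes[cand], size, prob = w[cand]))
    geneSet(setName, sort(members), className = "synthetic.ags")
}

#' Generate a synthetic omics matrix with planted alterations
#'
#' Background values are i.i.d. standard normal; for each sample, the
#' planted genes are shifted by `effectSize` standard deviations in a
#' random direction per (sample, gene), emulating genes altered either
#' way. Deterministic per seed.
#'
#' @param genes gene symbols (rows).
#' @param samples sample identifiers (columns).
#' @param planted named list mapping sample -> character vector of
#'   planted genes (subset of `genes`); NULL for a pure null matrix.
#' @param effectSize alteration magnitude in cohort-sd units.
#' @param seed RNG seed.
#' @return Numeric genes x samples matrix.
#' @export
simOmics <- function(genes, samples, planted = NULL, effectSize = 0, seed) {
    m <- .withSeed(seed, {
        mm <- matrix(stats::rnorm(length(genes) * length(samples)),
                     nrow = length(genes),
                     dimnames = list(genes, samples))
        if (!is.null(planted) && effectSize != 0) {
            for (s in names(planted)) {
                pg <- intersect(planted[[s]], genes)
                if (length(pg))
                    mm[pg, s] <- mm[pg, s] +
                        effectSize * sample(c(-1, 1), length(pg),
                                            replace = TRUE)
            }
        }
        mm
    })
    m
}

#' Generate a synthetic binary mutation matrix
#'
#' Background mutations are i.i.d. Bernoulli(`backgroundRate`); planted
#' genes are set to 1 in their samples.
#'
#' @param genes,samples dimnames.
#' @param backgroundRate per-cell passenger mutation probability.
#' @param planted named list mapping sample -> mutated genes.
#' @param seed RNG seed.
#' @return Binary genes x samples matrix.
#' @export
simMutations <- function(genes, samples, backgroundRate = 0.02,
                         planted = NULL, seed) {
    .withSeed(seed, {
        mm <- matrix(stats::rbinom(length(genes) * length(samples), 1,
                                   backgroundRate),
                     nrow = length(genes),
                     dimnames = list(genes, samples))
        if (!is.null(planted)) {
            for (s in names(planted))
                mm[intersect(planted[[s]], genes), s] <- 1L
        }
        mm
    })
}

#' Generate a drug-response vector from one feature
#'
#' The linear response model `S = beta * F + epsilon` with
#' `epsilon ~ N(0, noiseSd)`. With `higherIsSensitive = FALSE` the scale
#' is negated, emulating screens whose response units are inverted.
#'
#' @param feature numeric feature vector F.
#' @param beta response slope.
#' @param noiseSd residual standard deviation, positive.
#' @param seed RNG seed.
#' @param higherIsSensitive orientation of the produced scale.
#' @return Numeric response vector (names preserved).
#' @export
simDrugResponse <- function(feature, beta, noiseSd, seed,
                            higherIsSensitive = TRUE) {
    if (noiseSd <= 0)
        stop("'noiseSd' must be positive")
    s <- .withSeed(seed,
        beta * feature + stats::rnorm(length(feature), 0, noiseSd))
    if (!higherIsSensitive)
        s <- -s
    names(s) <- names(feature)
    s
}

#' Empirical enrichment z from the degree-preserving rewiring null
#'
#' The oracle for the analytic null: double-edge swaps (rejecting
#' self-loops and duplicates, so the degree sequence is preserved
#' exactly) produce `nReps` rewired networks; the empirical z is
#' `(n_obs - mean(n*)) / sd(n*)` over the rewired connecting-edge
#' counts. This conditions on node degrees exactly like the closed-form
#' expected count, but makes no distributional assumption.
#'
#' @param net a [GeneNetwork-class].
#' @param ags,fgs gene sets (objects or character vectors).
#' @param nSwaps swap attempts per replicate; at least 5x the edge count.
#' @param nReps number of rewired replicates, at least 50.
#' @param seed RNG seed.
#' @return list with `z`, `nObs`, `nullMean`, `nullSd`, `nullCounts`,
#'   `flag` (`"ok"`, or `"degenerate"` when sd(n*) = 0, z NA).
#' @export
rewiringNullZ <- function(net, ags, fgs, nSwaps = 5 * totalEdges(net),
                          nReps = 100, seed) {
    if (nReps < 50)
        stop("'nReps' must be at least 50")
    if (nSwaps < 5 * totalEdges(net))
        stop("'nSwaps' must be at least 5x the edge count")
    if (is(ags, "GeneSet")) ags <- geneIds(ags)
    if (is(fgs, "GeneSet")) fgs <- geneIds(fgs)
    in1 <- .nodeLogical(net, ags)
    in2 <- .nodeLogical(net, fgs)
    nObs <- .edgeCountLogical(net, in1, in2)
    g0 <- igraph::graph_from_edgelist(net@edgeMat, directed = FALSE)
    counts <- .withSeed(seed, {
        vapply(seq_len(nReps), function(k) {
            gk <- igraph::rewire(g0, igraph::keeping_degseq(niter = nSwaps))
            em <- igraph::as_edgelist(gk, names = FALSE)
            u <- em[, 1L]
            v <- em[, 2L]
            sum((in1[u] & in2[v]) | (in2[u] & in1[v]))
        }, numeric(1))
    })
    sdv <- stats::sd(counts)
    if (sdv == 0)
        return(list(z = NA_real_, nObs = nObs, nullMean = mean(counts),
                    nullSd = 0, nullCounts = counts, flag = "degenerate"))
    list(z = (nObs - mean(counts)) / sdv, nObs = nObs,
         nullMean = mean(counts), nullSd = sdv, nullCounts = counts,
         flag = "ok")
}

#' Simulate a two-screen drug-sensitivity study with pathway-level truth
#'
#' The study-conditions generator behind the cross-screen robustness
#' evaluations. Each sample (cell line) has a latent pathway activity
#' `a ~ Uniform(0, 1)` toward one target FGS. Its altered genes are
#' drawn with weight `1 + biasScale * a * edgesToFgs(gene)`, so active
#' samples alter different individual genes but the same network
#' neighborhood -- the disparate-genes / confluent-pathway structure
#' that motivates pathway-level scoring. Each screen then measures
#' expression independently (planted genes shifted by `effectSize` sd,
#' independent noise per screen) and a drug response
#' `S = beta * a + epsilon` with screen-specific noise and orientation.
#'
#' @param net a [GeneNetwork-class]; expression genes are its nodes.
#' @param fgs target [GeneSet-class].
#' @param nSamples cell lines per screen (shared panel).
#' @param nAltered planted altered genes per sample.
#' @param effectSize expression shift of planted genes (sd units).
#' @param beta response slope on the latent activity.
#' @param noiseSd residual response sd per screen.
#' @param biasScale connectivity bias multiplier for planted genes.
#' @param orientations logical vector, `higherIsSensitive` per screen.
#' @param seed RNG seed.
#' @return list with `activity`, `planted`, and per screen `expr`
#'   (genes x samples) and `response` (a [DrugScreen-class] with one
#'   drug, `"drug1"`).
#' @export
simDrugStudy <- function(net, fgs, nSamples = 40, nAltered = 25,
                         effectSize = 4, beta = 2, noiseSd = 1,
                         biasScale = 8, orientations = c(TRUE, TRUE),
                         seed) {
    genes <- nodes(net)
    samples <- sprintf("s%03d", seq_len(nSamples))
    activity <- .withSeed(seed, stats::runif(nSamples))
    names(activity) <- samples
    planted <- lapply(seq_len(nSamples), function(i)
        geneIds(simEnrichedAgs(net, fgs, nAltered,
                               bias = biasScale * activity[i],
                               seed = seed + 1000L + i)))
    names(planted) <- samples
    screens <- lapply(seq_along(orientations), function(k) {
        expr <- simOmics(genes, samples, planted = planted,
                         effectSize = effectSize,
                         seed = seed + 2000L * k)
        resp <- simDrugResponse(activity, beta, noiseSd,
                                seed = seed + 3000L * k,
                                higherIsSensitive = orientations[k])
        list(expr = expr,
             response = drugScreen(matrix(resp, ncol = 1L,
                                          dimnames = list(samples, "drug1")),
                                   higherIsSensitive = orientations[k],
                                   screenName = paste0("screen", k)))
    })
    names(screens) <- paste0("screen", seq_along(screens))
    list(activity = activity, planted = planted, screens = screens)
}
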