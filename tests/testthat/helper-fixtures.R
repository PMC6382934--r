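# Shared fixtures and independent oracles for the suite.

triangleNet <- function() {
    suppressMessages(networkFromEdges(c("A", "B", "A"), c("B", "C", "C")))
}

# the standard desk-scale scoring fixture (memoised per session)
fixtureNet <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simNetwork(500, meanDegree = 20, model = "erdos",
                                 seed = 20260901)
        cache
    }
})

# Independent oracle: brute-force double loop over the edge list under the
# stated predicate (one endpoint in each set).
bruteCountEdges <- function(net, set1, set2) {
    el <- edgeList(net)
    n <- 0L
    for (k in seq_len(nrow(el))) {
        u <- el[k, 1L]
        v <- el[k, 2L]
        if ((u %in% set1 && v %in% set2) || (u %in% set2 && v %in% set1))
            n <- n + 1L
    }
    n
}

# Independent oracle: textbook BH step-up written directly from the
# definition (sort, p * m / rank, cumulative minimum from the largest p).
bhOracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- p[ord] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[ord] <- adj
    out
}

# Independent oracle: exhaustive two-sided Fisher p by enumerating every
# 2x2 table with the observed margins and summing hypergeometric
# probabilities not exceeding the observed one.
fisherOracle <- function(a, b, c, d) {
    m <- a + b        # AGS size
    n <- c + d        # complement
    k <- a + c        # FGS size
    kk <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(kk, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

.withSeedTest <- function(seed, expr) withr::with_seed(seed, expr)

# random small network + set pair for the edge-count property
randomEdgeCase <- function(seed) {
    nNodes <- 20 + (seed %% 180)
    net <- simNetwork(nNodes, meanDegree = 6, model = "erdos", seed = seed)
    nd <- nodes(net)
    s1 <- sample(nd, sample(2:15, 1))
    s2 <- sample(nd, sample(2:15, 1))
    list(net = net, s1 = s1, s2 = s2)
}
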