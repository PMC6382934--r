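test_that("generators are pure functions of their seed", {
    n1 <- simNetwork(120, 10, seed = 5)
    n2 <- simNetwork(120, 10, seed = 5)
    expect_identical(edgeList(n1), edgeList(n2))
    expect_false(identical(edgeList(n1),
                           edgeList(simNetwork(120, 10, seed = 6))))
    f1 <- plantFgs(n1, 10, seed = 2)
    expect_identical(geneIds(f1), geneIds(plantFgs(n1, 10, seed = 2)))
    a1 <- simEnrichedAgs(n1, f1, 15, bias = 3, seed = 9)
    expect_identical(geneIds(a1),
                     geneIds(simEnrichedAgs(n1, f1, 15, bias = 3, seed = 9)))
    m1 <- simOmics(letters, paste0("s", 1:5), seed = 4)
    expect_identical(m1, simOmics(letters, paste0("s", 1:5), seed = 4))
    expect_identical(simMutations(letters, "s1", seed = 3),
                     simMutations(letters, "s1", seed = 3))
    expect_identical(simDrugResponse(1:10, 1, 1, seed = 8),
                     simDrugResponse(1:10, 1, 1, seed = 8))
})

test_that("generated networks satisfy the degree model", {
    net <- simNetwork(500, 20, seed = 1)
    deg <- nodeDegree(net)
    expect_equal(sum(deg), 2 * totalEdges(net))
    expect_true(all(deg >= 1))
    # preferential attachment gives heavy-tailed degrees
    expect_gt(max(deg), 3 * median(deg))
    # Erdos-Renyi stays connected and near the requested density
    er <- simNetwork(200, 10, model = "erdos", seed = 2)
    expect_equal(totalEdges(er), 1000L)
    expect_error(simNetwork(5, 2, seed = 1), "at least 10")
    expect_error(simNetwork(100, 200, seed = 1), "infeasible")
})

test_that("bias-0 planting reduces to the exchangeable null", {
    net <- fixtureNet()
    fgs <- plantFgs(net, 40, seed = 3)
    z <- vapply(1:200, function(k)
        neaScore(net, simEnrichedAgs(net, fgs, 30, bias = 0, seed = k),
                 fgs)@z, numeric(1))
    expect_lt(abs(mean(z)), 0.25)
    expect_lt(abs(median(z)), 0.3)
})

test_that("planted connectivity bias produces detectable enrichment", {
    net <- fixtureNet()
    fgs <- plantFgs(net, 40, seed = 3)
    z <- vapply(1:40, function(k)
        neaScore(net, simEnrichedAgs(net, fgs, 30, bias = 5,
                                     seed = 10000 + k), fgs)@z, numeric(1))
    expect_gt(median(z), 2)
    # disjoint planting is honored
    aD <- simEnrichedAgs(net, fgs, 30, bias = 5, seed = 4, disjoint = TRUE)
    expect_length(intersect(geneIds(aD), geneIds(fgs)), 0L)
})

test_that("planted omics alterations are recovered by AGS construction", {
    net <- fixtureNet()
    genes <- nodes(net)
    samples <- sprintf("s%02d", 1:50)
    planted <- lapply(seq_along(samples), function(i)
        .withSeedTest(800 + i, sample(genes, 30)))
    names(planted) <- samples
    m <- simOmics(genes, samples, planted = planted, effectSize = 6,
                  seed = 13)
    top <- buildTopN(m, 200)
    rec <- vapply(samples, function(s)
        mean(planted[[s]] %in% geneIds(top[[s]])), numeric(1))
    expect_gte(min(rec), 0.95)
    # no effect: significance-based sets are (near-)empty
    m0 <- simOmics(genes, samples, planted = planted, effectSize = 0,
                   seed = 13)
    sizes <- vapply(geneSets(buildSignificant(m0)),
                    function(s) length(geneIds(s)), integer(1))
    expect_gte(mean(sizes == 0), 0.9)
})

test_that("drug-response generator honors slope, noise and orientation", {
    f <- .withSeedTest(5, rnorm(60))
    # beta = 0: null correlation
    s0 <- simDrugResponse(f, beta = 0, noiseSd = 1, seed = 6)
    expect_lt(abs(cor(f, s0, method = "spearman")), 0.35)
    # noise -> 0: correlation -> sign(beta)
    s1 <- simDrugResponse(f, beta = -2, noiseSd = 1e-9, seed = 7)
    expect_equal(cor(f, s1, method = "spearman"), -1)
    # orientation flag negates the scale
    sA <- simDrugResponse(f, beta = 1, noiseSd = 0.5, seed = 8)
    sB <- simDrugResponse(f, beta = 1, noiseSd = 0.5, seed = 8,
                          higherIsSensitive = FALSE)
    expect_equal(sA, -sB)
})

test_that("rewiring preserves the degree sequence exactly", {
    net <- simNetwork(150, 8, seed = 40)
    ags <- plantFgs(net, 20, seed = 41, setName = "a")
    fgs <- plantFgs(net, 20, seed = 42)
    rw <- rewiringNullZ(net, ags, fgs, nSwaps = 10000, nReps = 50, seed = 43)
    expect_length(rw$nullCounts, 50L)
    expect_false(is.na(rw$z))
    # degree preservation: rebuild one rewired replicate and compare
    g0 <- igraph::graph_from_edgelist(
        matrix(match(edgeList(net), nodes(net)), ncol = 2), directed = FALSE)
    gk <- .withSeedTest(99,
        igraph::rewire(g0, igraph::keeping_degseq(niter = 10000)))
    expect_identical(as.integer(sort(igraph::degree(gk))),
                     sort(unname(nodeDegree(net))))
    expect_error(rewiringNullZ(net, ags, fgs, nReps = 10, seed = 1), "50")
})

test_that("null AGS stay within the empirical rewiring band", {
    net <- fixtureNet()
    fgs <- plantFgs(net, 40, seed = 50)
    zs <- vapply(1:8, function(k) {
        ags <- simEnrichedAgs(net, fgs, 25, bias = 0, seed = 60 + k)
        rewiringNullZ(net, ags, fgs, nReps = 60, seed = 70 + k)$z
    }, numeric(1))
    expect_gte(mean(abs(zs) < 3), 7 / 8)
})

test_that("rewiring-null mean agrees with the analytic expected count", {
    net <- fixtureNet()
    fgs <- plantFgs(net, 40, seed = 80)
    ags <- simEnrichedAgs(net, fgs, 30, bias = 2, seed = 81)
    r <- neaScore(net, ags, fgs)
    expect_gte(r@connAgs, 50)
    rw <- rewiringNullZ(net, ags, fgs, nReps = 80, seed = 82)
    expect_lt(abs(rw$nullMean - r@nExp) / r@nExp, 0.15)
})

test_that("two-screen study generator exposes its ground truth", {
    net <- simNetwork(200, 12, seed = 90)
    fgs <- plantFgs(net, 25, seed = 91)
    st <- simDrugStudy(net, fgs, nSamples = 100, seed = 92,
                       orientations = c(TRUE, FALSE))
    expect_named(st$screens, c("screen1", "screen2"))
    expect_length(st$activity, 100L)
    expect_identical(dim(st$screens$screen1$expr), c(200L, 100L))
    expect_false(higherIsSensitive(st$screens$screen2$response))
    # response tracks activity after orientation harmonization
    r1 <- responseMatrix(st$screens$screen1$response)[, 1]
    r2 <- responseMatrix(st$screens$screen2$response)[, 1]
    expect_gt(cor(st$activity, r1, method = "spearman"), 0.2)
    expect_lt(cor(st$activity, r2, method = "spearman"), -0.2)
})
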