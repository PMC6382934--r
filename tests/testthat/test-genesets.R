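test_that("GMT IO round-trips and validates", {
    f <- withr::local_tempfile(fileext = ".gmt")
    writeLines(c("S1\tdesc\tg1\tg2\tg3", "S2\tdesc\tg2\tg4"), f)
    col <- readGmt(f)
    expect_length(col, 2L)
    expect_setequal(geneIds(col[["S2"]]), c("g2", "g4"))

    writeGmt(col, f)
    col2 <- readGmt(f)
    expect_identical(lapply(geneSets(col2), geneIds),
                     lapply(geneSets(col), geneIds))

    writeLines("S\td\tg1\tg1\tg2", f)
    expect_warning(col3 <- readGmt(f), "duplicate")
    expect_setequal(geneIds(col3[["S"]]), c("g1", "g2"))

    writeLines(c("S\td\tg1", "S\td\tg2"), f)
    expect_error(readGmt(f), "duplicate set name")
    writeLines("S\td", f)
    expect_error(readGmt(f), "line 1")
})

test_that("one-sample z standardizes against the cohort", {
    m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(0, 1, 5))
    colnames(m) <- paste0("s", 1:3)
    z <- oneSampleZ(m)
    expect_equal(unname(z["g1", ]), c(-1, 0, 1))
    expect_true(all(is.na(z["g2", ])))
    expect_error(oneSampleZ(m[, 1:2]), "3 samples")
    # i.i.d. nulls: ~5% of |z| beyond 1.96 (binomial tolerance at 1e4 draws)
    mm <- simOmics(sprintf("g%04d", 1:200), sprintf("s%02d", 1:50), seed = 9)
    zz <- oneSampleZ(mm)
    frac <- mean(abs(zz) > 1.96)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(zz)) + 0.004)
})

test_that("top-N sets have fixed size with deterministic tie-breaking", {
    m <- rbind(ga = c(3, 0, 0), gb = c(-2, 0, 0), gc = c(1, 0, 0),
               gd = c(0, 1, -1), ge = c(0, -1, 1))
    colnames(m) <- paste0("s", 1:3)
    # hand z for s1: ga ~ +1.155, gb ~ -1.155, gc ~ 1.155 (sd differs per row)
    col <- buildTopN(m, 2)
    expect_identical(className(col[["s1"]]), "top.2")
    expect_length(geneIds(col[["s1"]]), 2L)
    # n larger than usable genes
    colAll <- buildTopN(m, 10)
    expect_length(geneIds(colAll[["s1"]]), 5L)
    # deterministic lexicographic tie-break: gd and ge tie in every sample
    m2 <- rbind(gd = c(0, 1, -1), ge = c(0, -1, 1), gz = c(0, 0.1, -0.1))
    colnames(m2) <- paste0("s", 1:3)
    col2 <- buildTopN(m2, 1)
    expect_identical(geneIds(col2[["s2"]]), "gd")
})

test_that("significance-based sets respond to signal and alpha", {
    genes <- sprintf("g%03d", 1:101)
    m <- simOmics(genes, sprintf("s%02d", 1:30), seed = 3)
    m["g001", "s01"] <- mean(m["g001", ]) + 10 * sd(m["g001", ])
    col <- buildSignificant(m)
    expect_true("g001" %in% geneIds(col[["s01"]]))
    expect_lte(length(geneIds(col[["s01"]])), 3L)
    # alpha = 1 keeps every gene with defined z
    colAll <- buildSignificant(m, alpha = 1.01)
    expect_length(geneIds(colAll[["s05"]]), length(genes))
    # null matrices give (near-)empty sets in most samples
    sizes <- vapply(geneSets(buildSignificant(
        simOmics(genes, sprintf("s%02d", 1:30), seed = 4))),
        function(s) length(geneIds(s)), integer(1))
    expect_gte(mean(sizes == 0), 0.95)
})

test_that("network filtering keeps wired members and drops isolated ones", {
    net <- fixtureNet()
    deg <- nodeDegree(net)
    # filter FGS around a hub so its neighbors are genuinely wired to it
    hub <- names(which.max(deg))
    el <- edgeList(net)
    nb <- unique(c(el[el[, 1] == hub, 2], el[el[, 2] == hub, 1]))
    fgs <- geneSet("cancer", c(hub, nb[1:30]), className = "fgs")
    filterC <- geneSetCollection(list(fgs))
    # AGS: the hub (wired to the whole FGS), plus genes picked far from it
    far <- setdiff(nodes(net), c(hub, nb))[1:5]
    ags <- geneSetCollection(list(geneSet("s1", c(hub, far),
                                          className = "significant")))
    out <- filterAgsByNea(ags, net, filterC, fdr = 0.05, variant = "mini")
    expect_identical(className(out[["s1"]]), "significant.filtered.mini")
    expect_true(hub %in% geneIds(out[["s1"]]))
    expect_true(all(geneIds(out[["s1"]]) %in% geneIds(ags[["s1"]])))
    # member with no edge to any filter set can never pass
    zeroEdge <- Filter(function(g)
        countConnectingEdges(net, g, geneIds(fgs)) == 0, far)
    expect_false(any(zeroEdge %in% geneIds(out[["s1"]])))
    # empty input AGS stays empty; empty filter collection errors
    outE <- filterAgsByNea(
        geneSetCollection(list(geneSet("s1", character(0)))),
        net, filterC)
    expect_length(geneIds(outE[["s1"]]), 0L)
    expect_error(filterAgsByNea(ags, net, geneSetCollection(list())),
                 "empty filter")
})

test_that("mutation AGS retains planted drivers and sheds passengers", {
    net <- fixtureNet()
    deg <- nodeDegree(net)
    el <- edgeList(net)
    # driver: a mid-degree gene wired to half of a 20-gene cancer set
    driver <- names(deg)[deg >= 12 & deg <= 20][1]
    nb <- unique(c(el[el[, 1] == driver, 2], el[el[, 2] == driver, 1]))
    others <- .withSeedTest(1,
        sample(setdiff(names(deg)[deg <= 25], c(driver, nb)), 10))
    cancerFgs <- geneSet("cancer", c(nb[1:10], others))
    retained <- 0L
    passengerDropOk <- 0L
    reps <- 10L
    for (k in seq_len(reps)) {
        passengers <- .withSeedTest(500 + k,
            sample(setdiff(nodes(net), c(driver, geneIds(cancerFgs))), 20))
        mm <- simMutations(nodes(net), "s1", backgroundRate = 0,
                           planted = list(s1 = c(driver, passengers)),
                           seed = 600 + k)
        out <- buildMutationMgs(mm, net, cancerFgs)
        keep <- geneIds(out[["s1"]])
        if (driver %in% keep) retained <- retained + 1L
        if (sum(passengers %in% keep) <= 4L)
            passengerDropOk <- passengerDropOk + 1L
    }
    expect_gte(retained / reps, 0.9)
    expect_gte(passengerDropOk / reps, 0.9)
    # zero-mutation sample: empty set plus warning
    mm0 <- matrix(0, nrow = 3, ncol = 1,
                  dimnames = list(nodes(net)[1:3], "s1"))
    expect_warning(out0 <- buildMutationMgs(mm0, net, cancerFgs),
                   "no mutations")
    expect_length(geneIds(out0[["s1"]]), 0L)
    # a mutated gene absent from the network yields an empty set
    mmX <- matrix(1, nrow = 1, ncol = 1, dimnames = list("XX", "s1"))
    outX <- suppressWarnings(buildMutationMgs(mmX, net, cancerFgs))
    expect_length(geneIds(outX[["s1"]]), 0L)
})

test_that("combining collections unions members over shared samples", {
    a <- geneSetCollection(list(geneSet("s1", c("A", "B")),
                                geneSet("s2", "C")))
    b <- geneSetCollection(list(geneSet("s1", c("B", "C")),
                                geneSet("s3", "D")))
    comb <- combineAgs(list(a, b))
    expect_identical(names(comb), "s1")
    expect_setequal(geneIds(comb[["s1"]]), c("A", "B", "C"))
    expect_identical(className(comb[["s1"]]), "combined")
    # single collection passes through (relabeled)
    one <- combineAgs(list(a))
    expect_setequal(geneIds(one[["s1"]]), c("A", "B"))
    expect_error(combineAgs(list(a, geneSetCollection(list(
        geneSet("zz", "A"))))), "share no sample")
})

test_that("filtered sets are subsets and significant sets respect top ordering", {
    net <- fixtureNet()
    genes <- nodes(net)
    planted <- list(s1 = genes[1:10], s2 = genes[11:20], s3 = genes[21:30])
    m <- simOmics(genes, names(planted), planted = planted,
                  effectSize = 6, seed = 12)
    sig <- buildSignificant(m)
    topN <- buildTopN(m, 200)
    for (s in names(planted)) {
        expect_true(all(geneIds(sig[[s]]) %in% geneIds(topN[[s]])))
        expect_length(geneIds(topN[[s]]), 200L)
    }
})
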