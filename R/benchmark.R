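#' Cross-screen robustness benchmark: pathway scores vs original profiles
#'
#' End-to-end seeded evaluation of the package's central claim at desk
#' scale: enrichment features discovered in one drug screen replicate
#' better in a second, independent screen than per-gene features do.
#' Each batch draws a fresh network and FGS collection; for each of
#' `nDrugs` drugs (each targeting a different FGS) a two-screen study is
#' simulated via [simDrugStudy()]. Per screen, per-sample AGS are built
#' with [buildTopN()], scored with [pwnea()], and both the pathway
#' z-scores and the raw expression profiles are correlated with the
#' drug response ([associateContinuous()]). The batch summary is the
#' median cross-screen consistency ([crossScreenConsistency()]) across
#' drugs and the permutation true discovery rate ([permutationTdr()])
#' over the pooled (feature, drug) p-value pairs, for each feature type.
#'
#' @param nBatches number of replicate batches.
#' @param nDrugs drugs per batch.
#' @param nSamples cell lines per screen.
#' @param nNodes,meanDegree network size per batch (Erdős–Rényi model).
#' @param nFgs,fgsSize FGS collection shape.
#' @param agsSize AGS size for [buildTopN()].
#' @param nPerm,pCut permutation-TDR settings.
#' @param seed RNG seed; every draw in the benchmark derives from it.
#' @return data.frame, one row per batch: `rho_pwnea`, `rho_gene`
#'   (median cross-screen Spearman rho), `tdr_pwnea`, `tdr_gene`.
#' @export
crossScreenBenchmark <- function(nBatches = 10, nDrugs = 3, nSamples = 100,
                                 nNodes = 300, meanDegree = 16, nFgs = 15,
                                 fgsSize = 20, agsSize = 40, nPerm = 200,
                                 pCut = 0.01, seed) {
    one <- function(b) {
        net <- simNetwork(nNodes, meanDegree, model = "erdos",
                          seed = seed + b)
        fgsC <- geneSetCollection(lapply(seq_len(nFgs), function(j)
            plantFgs(net, fgsSize, seed = seed + 100L * b + j,
                     setName = paste0("F", j))))
        rhoPw <- rhoGe <- numeric(nDrugs)
        pPw <- pGe <- list()
        for (d in seq_len(nDrugs)) {
            st <- simDrugStudy(net, fgsC[[d]], nSamples = nSamples,
                               seed = seed + 999L * d + b)
            assoc <- lapply(st$screens, function(sc) {
                zm <- zScores(pwnea(net, buildTopN(sc$expr, agsSize), fgsC))
                resp <- responseMatrix(sc$response)[, 1L]
                list(pw = associateContinuous(zm, resp),
                     ge = associateContinuous(t(sc$expr), resp))
            })
            vecs <- function(res) stats::setNames(res$statistic, res$feature)
            rhoPw[d] <- crossScreenConsistency(vecs(assoc[[1L]]$pw),
                                               vecs(assoc[[2L]]$pw))$rho
            rhoGe[d] <- crossScreenConsistency(vecs(assoc[[1L]]$ge),
                                               vecs(assoc[[2L]]$ge))$rho
            pPw[[d]] <- cbind(assoc[[1L]]$pw$p, assoc[[2L]]$pw$p)
            pGe[[d]] <- cbind(assoc[[1L]]$ge$p, assoc[[2L]]$ge$p)
        }
        pPw <- do.call(rbind, pPw)
        pGe <- do.call(rbind, pGe)
        data.frame(
            batch = b,
            rho_pwnea = stats::median(rhoPw),
            rho_gene = stats::median(rhoGe),
            tdr_pwnea = permutationTdr(pPw[, 1L], pPw[, 2L], nPerm = nPerm,
                                       pCut = pCut, seed = seed + b)$tdr,
            tdr_gene = permutationTdr(pGe[, 1L], pGe[, 2L], nPerm = nPerm,
                                      pCut = pCut, seed = seed + b)$tdr)
    }
    do.call(rbind, lapply(seq_len(nBatches), one))
}
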