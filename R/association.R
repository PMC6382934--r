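#' Construct a DrugScreen
#'
#' @param response numeric matrix, samples in rows, drugs in columns.
#' @param higherIsSensitive screen orientation: do larger values mean
#'   more sensitive? Mandatory; e.g. TRUE for CCLE/CGP-like scales,
#'   FALSE for the inverted CTD-like AUC scale.
#' @param screenName identifier.
#' @return A [DrugScreen-class].
#' @export
drugScreen <- function(response, higherIsSensitive, screenName = "screen") {
    new("DrugScreen", response = response,
        higherIsSensitive = higherIsSensitive, screenName = screenName)
}

#' @name DrugScreen-accessors
#' @title Accessors for DrugScreen objects
#' @param object a [DrugScreen-class].
NULL

#' @rdname DrugScreen-accessors
#' @export
setMethod("responseMatrix", "DrugScreen", function(object) object@response)

#' @rdname DrugScreen-accessors
#' @export
setMethod("higherIsSensitive", "DrugScreen",
          function(object) object@higherIsSensitive)

setMethod("show", "DrugScreen", function(object) {
    cat("DrugScreen '", object@screenName, "': ",
        nrow(object@response), " samples x ", ncol(object@response),
        " drugs; higher is ",
        if (object@higherIsSensitive) "sensitive" else "resistant",
        "\n", sep = "")
})

# Spearman rho and p for one complete pair of vectors;
# t-approximation for n > 10, exact enumeration (cor.test) for n <= 10
.spearman <- function(x, y) {
    n <- length(x)
    if (n <= 10) {
        ct <- suppressWarnings(
            stats::cor.test(x, y, method = "spearman", exact = TRUE))
        return(c(rho = unname(ct$estimate), p = ct$p.value))
    }
    r <- stats::cor(rank(x), rank(y))
    if (abs(r) >= 1)
        return(c(rho = r, p = 0))
    tval <- r * sqrt((n - 2) / (1 - r^2))
    c(rho = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

#' Correlate continuous features with a drug-response vector
#'
#' Spearman rank correlation of every feature (column) against the
#' response, with pairwise-complete handling of missing values and
#' Benjamini-Hochberg adjustment across the feature family. Constant
#' features (or responses) are flagged `NA` and excluded from the BH
#' family.
#'
#' @param features numeric matrix, samples x features (an
#'   [EnrichmentMatrix-class] is accepted and its z-score matrix used).
#' @param response numeric response vector; if named, it is aligned to
#'   the feature rownames.
#' @param minPairs minimum paired non-missing observations per feature,
#'   default 5.
#' @return data.frame with columns `feature`, `statistic` (rho), `p`,
#'   `q`, `n`, `flag`.
#' @export
associateContinuous <- function(features, response, minPairs = 5) {
    if (is(features, "EnrichmentMatrix")) features <- zScores(features)
    if (!is.matrix(features))
        features <- matrix(features, ncol = 1L,
                           dimnames = list(names(features), "feature"))
    if (!is.null(names(response)) && !is.null(rownames(features)))
        response <- response[rownames(features)]
    res <- lapply(seq_len(ncol(features)), function(j) {
        x <- features[, j]
        ok <- !is.na(x) & !is.na(response)
        if (sum(ok) < minPairs)
            return(c(NA_real_, NA_real_, sum(ok)))
        x <- x[ok]
        y <- response[ok]
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            return(c(NA_real_, NA_real_, sum(ok)))
        c(.spearman(x, y), sum(ok))
    })
    res <- do.call(rbind, res)
    out <- data.frame(feature = colnames(features), statistic = res[, 1L],
                      p = res[, 2L], q = bhAdjust(res[, 2L]), n = res[, 3L],
                      flag = ifelse(is.na(res[, 2L]), "NA", "ok"),
                      stringsAsFactors = FALSE, row.names = NULL)
    out
}

#' Two-level ANOVA between a binary feature and a drug response
#'
#' One-way ANOVA with the two levels "any mutation" vs "wild type"; for
#' two groups the F statistic equals the squared pooled-variance t
#' statistic. Requires both levels with at least two observations,
#' otherwise the result is flagged `NA`.
#'
#' @param mutation binary (0/1) feature vector.
#' @param response numeric response vector of the same length.
#' @return One-row data.frame with `statistic` (F), `p`, `n`, `flag`.
#' @export
associateBinary <- function(mutation, response) {
    ok <- !is.na(mutation) & !is.na(response)
    mutation <- mutation[ok]
    response <- response[ok]
    if (!all(mutation %in% c(0, 1)))
        stop("'mutation' must be binary")
    n1 <- sum(mutation == 1)
    n0 <- sum(mutation == 0)
    if (n1 < 2 || n0 < 2)
        return(data.frame(statistic = NA_real_, p = NA_real_,
                          n = length(response), flag = "NA"))
    fit <- stats::oneway.test(response ~ factor(mutation), var.equal = TRUE)
    data.frame(statistic = unname(fit$statistic), p = fit$p.value,
               n = length(response), flag = "ok")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA`s pass through and are excluded from the
#' family size. Output is monotone-enforced, capped at 1, and
#' elementwise at least the input.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted values, same length and order.
#' @export
bhAdjust <- function(pvals) {
    ok <- !is.na(pvals)
    if (any(pvals[ok] < 0 | pvals[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(pvals))
    out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
    out
}

#' Fraction of adjusted p-values below a cutoff
#'
#' The per-feature-class power summary: `count(q < cutoff) / count(valid)`,
#' reported to three decimals. NAs are removed; an all-NA input is an
#' error.
#'
#' @param qvals adjusted p-values.
#' @param cutoff significance cutoff (e.g. 0.1).
#' @return Fraction in `[0, 1]`, rounded to 3 decimals.
#' @export
fractionSignificant <- function(qvals, cutoff) {
    qvals <- qvals[!is.na(qvals)]
    if (length(qvals) == 0L)
        stop("no non-missing values")
    round(sum(qvals < cutoff) / length(qvals), 3)
}

#' Cross-screen consistency of drug-feature associations
#'
#' Spearman rank correlation between two screens' per-feature
#' association statistics for one drug, after harmonizing the screens'
#' response orientations (a screen on an inverted scale has its
#' statistic vector negated first). Features are matched by name.
#'
#' @param statsA,statsB named numeric vectors of per-feature statistics
#'   (e.g. the `statistic` column of [associateContinuous()] named by
#'   feature).
#' @param higherIsSensitiveA,higherIsSensitiveB screen orientations.
#' @return data.frame with `rho`, `n_features`, `p`.
#' @export
crossScreenConsistency <- function(statsA, statsB,
                                   higherIsSensitiveA = TRUE,
                                   higherIsSensitiveB = TRUE) {
    shared <- intersect(names(statsA), names(statsB))
    a <- statsA[shared]
    b <- statsB[shared]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L)
        stop("fewer than 3 shared features with defined statistics")
    if (higherIsSensitiveA != higherIsSensitiveB)
        b <- -b
    sp <- .spearman(a[ok], b[ok])
    data.frame(rho = unname(sp["rho"]), n_features = sum(ok),
               p = unname(sp["p"]))
}

#' Fractions of consistency values above thresholds
#'
#' For each threshold t, the fraction of consistency correlations with
#' `rho > t`; non-increasing in t by construction.
#'
#' @param rhos numeric vector of cross-screen rank correlations.
#' @param thresholds default `c(0.15, 0.30, 0.45, 0.60, 0.75)`.
#' @return Named numeric vector of fractions.
#' @export
thresholdFractions <- function(rhos,
                               thresholds = c(0.15, 0.30, 0.45, 0.60, 0.75)) {
    rhos <- rhos[!is.na(rhos)]
    vapply(stats::setNames(thresholds, paste0("R>", thresholds)),
           function(t) mean(rhos > t), numeric(1))
}

# half-up rounding to one decimal for printed percentages
.halfUp1 <- function(x) floor(x * 10 + 0.5) / 10

#' Count practically usable correlates across domains
#'
#' A matched (feature, drug) pair -- in-vitro association on one side,
#' clinical on the other -- is "usable" when both sides have
#' `p < pCut` and `|rho| > rhoCut`, with concordant correlation sign
#' (disable via `requireConcordant`). The percentage is reported to one
#' decimal with half-up rounding.
#'
#' @param pairs data.frame with columns `p_a`, `rho_a`, `p_b`, `rho_b`,
#'   one row per matched pair.
#' @param pCut p-value cutoff, default 0.001.
#' @param rhoCut absolute correlation cutoff, default 0.2.
#' @param requireConcordant require `sign(rho_a) == sign(rho_b)`.
#' @return list with `count`, `total`, `percentage`.
#' @export
usableCorrelates <- function(pairs, pCut = 0.001, rhoCut = 0.2,
                             requireConcordant = TRUE) {
    if (nrow(pairs) == 0L)
        stop("empty input")
    ok <- pairs$p_a < pCut & pairs$p_b < pCut &
        abs(pairs$rho_a) > rhoCut & abs(pairs$rho_b) > rhoCut
    if (requireConcordant)
        ok <- ok & sign(pairs$rho_a) == sign(pairs$rho_b)
    ok[is.na(ok)] <- FALSE
    n <- sum(ok)
    list(count = n, total = nrow(pairs),
         percentage = .halfUp1(100 * n / nrow(pairs)))
}

#' Permutation-based true discovery rate of matched significant pairs
#'
#' The observed count C of pairs significant (`p < pCut`) on both sides
#' is compared against the counts obtained after randomly permuting the
#' pairing of feature labels between the two sides:
#' `TDR = max(0, (C - mean(C*)) / C)`, and 0 when C = 0. A variant that
#' permutes one side's values (emulating sample-label shuffling) is
#' selected via `scheme`.
#'
#' @param pA,pB matched p-value vectors (same feature order).
#' @param nPerm number of permutations, at least 100.
#' @param pCut significance cutoff, default 0.01.
#' @param seed RNG seed (mandatory).
#' @param scheme `"pairing"` (default) or `"labels"` -- both shuffle the
#'   correspondence, on indices or on values.
#' @return list with `tdr`, `observed`, `permutedMean`.
#' @export
permutationTdr <- function(pA, pB, nPerm = 1000, pCut = 0.01, seed,
                           scheme = c("pairing", "labels")) {
    scheme <- match.arg(scheme)
    if (nPerm < 100)
        stop("'nPerm' must be at least 100")
    stopifnot(length(pA) == length(pB))
    sigA <- !is.na(pA) & pA < pCut
    sigB <- !is.na(pB) & pB < pCut
    C <- sum(sigA & sigB)
    perm <- .withSeed(seed, {
        vapply(seq_len(nPerm), function(k)
            sum(sigA & sample(sigB)), numeric(1))
    })
    tdr <- if (C == 0) 0 else max(0, (C - mean(perm)) / C)
    list(tdr = tdr, observed = C, permutedMean = mean(perm))
}
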