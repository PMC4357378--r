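#' Derive per-replicate seeds from a master seed
#'
#' The master seed initialises the RNG once and a vector of independent
#' replicate seeds is drawn from it, so that a grid of scenarios is fully
#' determined by a single integer and each replicate's stream is independent
#' of every other's.
#'
#' @param masterSeed integer.
#' @param n number of seeds.
#' @return Integer vector of n seeds in [1, 2^31 - 2].
#' @export
deriveSeeds <- function(masterSeed, n) {
    set.seed(masterSeed)
    sample.int(.Machine$integer.max - 1L, n)
}

#' Monte-Carlo standard error of a rejection rate
#'
#' @param rate estimated rejection probability.
#' @param nReplicates number of Monte-Carlo replicates.
#' @return sqrt(rate * (1 - rate) / nReplicates).
#' @export
mcStandardError <- function(rate, nReplicates) {
    sqrt(rate * (1 - rate) / nReplicates)
}

## One scenario: simulate nReplicates datasets and return both p-values per
## replicate (permutation and large-sample comparator, paired on the same
## data).  The stratum model is regenerated per replicate from that
## replicate's seed (the null-marker frequency draw is part of the
## data-generating process), unless a fixed model is supplied.
.runScenario <- function(config, nReplicates, nPermutations, repSeeds,
                         model = NULL,
                         tieRule = "greater-or-equal-plus-one") {
    pPerm <- numeric(nReplicates)
    pLarge <- numeric(nReplicates)
    for (r in seq_len(nReplicates)) {
        set.seed(repSeeds[r])
        mod <- if (is.null(model)) defaultStratumModel(config@L) else model
        # the boundary-pool warning is expected at small pool sizes and
        # would fire thousands of times across a grid; anything else
        # propagates
        mats <- withCallingHandlers(
            .simulateFreqMatrices(mod, config),
            warning = function(w) {
                if (grepl("monomorphic", conditionMessage(w)))
                    invokeRestart("muffleWarning")
            })
        res <- permutationTest(mats$p1 - mats$p0,
                               nPermutations = nPermutations,
                               tieRule = tieRule, comparator = TRUE)
        pPerm[r] <- res@pValue
        pLarge[r] <- res@largeSamplePValue
    }
    list(pPerm = pPerm, pLarge = pLarge)
}

.summaryRows <- function(config, alpha, nReplicates, pvals, testKind) {
    do.call(rbind, lapply(alpha, function(a) {
        rate <- mean(pvals <= a)
        cbind(as.data.frame(config)[setdiff(names(as.data.frame(config)),
                                            "seed")],
              data.frame(alpha = a, test_kind = testKind,
                         n_replicates = nReplicates,
                         rejection_rate = rate,
                         mc_se = mcStandardError(rate, nReplicates)))
    }))
}

.runGrid <- function(scenarios, alpha, nReplicates, nPermutations, seed,
                     testKind, tieRule, model = NULL) {
    if (length(scenarios) == 0L)
        stop("no scenarios supplied")
    if (is(scenarios, "ScenarioConfig")) scenarios <- list(scenarios)
    testKind <- match.arg(testKind, c("permutation", "large_sample", "both"),
                          several.ok = FALSE)
    kinds <- if (testKind == "both") c("permutation", "large_sample")
             else testKind
    scSeeds <- deriveSeeds(seed, length(scenarios))
    out <- lapply(seq_along(scenarios), function(i) {
        cfg <- scenarios[[i]]
        repSeeds <- deriveSeeds(scSeeds[i], nReplicates)
        pv <- .runScenario(cfg, nReplicates, nPermutations, repSeeds,
                           model = model, tieRule = tieRule)
        do.call(rbind, lapply(kinds, function(k)
            .summaryRows(cfg, alpha, nReplicates,
                         if (k == "permutation") pv$pPerm else pv$pLarge, k)))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Type-I-error grid
#'
#' For each null scenario (effect size 1) and each nominal level alpha,
#' simulates \code{nReplicates} datasets, runs the sign-flip permutation test
#' (and, when requested, the large-sample chi-square comparator on the same
#' replicates, so the two are paired) and records the fraction of replicates
#' with p <= alpha together with its Monte-Carlo standard error.
#' Deterministic given the master seed: per-scenario and per-replicate seeds
#' are derived with \code{\link{deriveSeeds}}.
#'
#' @param scenarios a \linkS4class{ScenarioConfig} or list of them; every
#'   scenario must have effect size 1.
#' @param alpha nominal levels (default c(0.05, 0.005)).
#' @param nReplicates simulated datasets per scenario.
#' @param nPermutations sign patterns per permutation test.
#' @param seed master seed.
#' @param testKind "permutation", "large_sample" or "both".
#' @param tieRule forwarded to \code{\link{permutationTest}}.
#' @param model optional fixed \linkS4class{StratumModel}; by default a fresh
#'   model (new null-marker frequencies) is generated per replicate.
#' @return A data.frame, one row per scenario x alpha x test kind, with
#'   columns for every scenario knob plus \code{alpha}, \code{test_kind},
#'   \code{n_replicates}, \code{rejection_rate}, \code{mc_se}.
#' @export
runType1Grid <- function(scenarios, alpha = c(0.05, 0.005),
                         nReplicates = 2000L, nPermutations = 500L,
                         seed = 1L, testKind = "both",
                         tieRule = "greater-or-equal-plus-one",
                         model = NULL) {
    if (is(scenarios, "ScenarioConfig")) scenarios <- list(scenarios)
    if (any(vapply(scenarios, function(s) s@effectSize != 1, logical(1))))
        stop("type-I-error scenarios must have effectSize = 1")
    .runGrid(scenarios, alpha, nReplicates, nPermutations, seed, testKind,
             tieRule, model)
}

#' Power grid
#'
#' As \code{\link{runType1Grid}} but with the candidate effect in force;
#' the rejection rate estimates power.  Passing effect size 1 degenerates
#' power to the test's size.
#'
#' @inheritParams runType1Grid
#' @return As \code{\link{runType1Grid}}.
#' @export
runPowerGrid <- function(scenarios, alpha = c(0.05, 0.005),
                         nReplicates = 2000L, nPermutations = 500L,
                         seed = 1L, testKind = "permutation",
                         tieRule = "greater-or-equal-plus-one",
                         model = NULL) {
    .runGrid(scenarios, alpha, nReplicates, nPermutations, seed, testKind,
             tieRule, model)
}
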