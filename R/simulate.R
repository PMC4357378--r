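#' Construct a StratumModel
#'
#' @param weights stratum population proportions (normalised to sum to 1).
#' @param alleleFreqs (L+1) x nStrata matrix of true allele frequencies in
#'   (0, 1); row 1 is the candidate marker.
#' @param diseaseRisk per-stratum baseline disease probability.
#' @return A \linkS4class{StratumModel}.
#' @seealso \code{\link{defaultStratumModel}} for the stock confounded model.
#' @export
stratumModel <- function(weights, alleleFreqs, diseaseRisk) {
    new("StratumModel",
        weights = weights / sum(weights),
        alleleFreqs = as.matrix(alleleFreqs),
        diseaseRisk = diseaseRisk)
}

#' The stock five-stratum confounded population
#'
#' Builds the default source population used in the simulation studies: five
#' equal-weight hidden strata whose candidate-marker allele frequency rises
#' from 0.2 to 0.6 while the baseline disease risk rises from 0.02 to 0.10 --
#' opposed gradients that confound allele frequency with disease risk and so
#' generate population stratification bias when matching is imperfect.  Null
#' markers receive independent Uniform(0.1, 0.9) allele frequencies per
#' (marker, stratum), drawn from the current RNG stream: callers wanting
#' reproducibility set the seed first (as \code{\link{simulateDataset}} and
#' the experiment drivers do).
#'
#' @param L number of null markers.
#' @param nStrata number of hidden strata (default 5).
#' @param candidateFreqRange range of the candidate-frequency gradient.
#' @param riskRange range of the baseline-disease-risk gradient.
#' @return A \linkS4class{StratumModel}.
#' @export
defaultStratumModel <- function(L, nStrata = 5L,
                                candidateFreqRange = c(0.2, 0.6),
                                riskRange = c(0.02, 0.10)) {
    stopifnot(L >= 1L, nStrata >= 1L)
    cand <- seq(candidateFreqRange[1], candidateFreqRange[2],
                length.out = nStrata)
    nulls <- matrix(runif(L * nStrata, 0.1, 0.9), nrow = L)
    stratumModel(
        weights = rep(1 / nStrata, nStrata),
        alleleFreqs = rbind(cand, nulls, deparse.level = 0),
        diseaseRisk = seq(riskRange[1], riskRange[2], length.out = nStrata))
}

#' Construct a ScenarioConfig
#'
#' Defaults are the baseline simulation scenario: 900 cases, 1:1 matching,
#' J = 10 pooling sets, L = 10 null markers, mismatch index 0.1, measurement
#' error 0.01, per-marker amplification coefficient uniform on [1, 2], and no
#' candidate effect (type-I-error configuration).
#'
#' @param nCases,m,J,L,delta,sigma,kappaRange,effectSize,seed see
#'   \linkS4class{ScenarioConfig}.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(nCases = 900L, m = 1L, J = 10L, L = 10L,
                           delta = 0.1, sigma = 0.01, kappaRange = c(1, 2),
                           effectSize = 1, seed = NA) {
    new("ScenarioConfig",
        nCases = as.integer(nCases), m = as.integer(m), J = as.integer(J),
        L = as.integer(L), delta = as.numeric(delta),
        sigma = as.numeric(sigma), kappaRange = as.numeric(kappaRange),
        effectSize = as.numeric(effectSize),
        seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}

## Case-pool allele frequency at the candidate under a per-allele
## multiplicative odds model: within a stratum with population frequency p,
## case genotypes are Binom(2, p*psi / (p*psi + 1 - p)).
.tiltFreq <- function(p, psi) p * psi / (p * psi + 1 - p)

#' Draw stratum-matched case-control sets with genotypes
#'
#' Samples nCases matched sets from the hidden-stratum population.  Each
#' case's stratum is drawn from the case stratum distribution -- the
#' population weights tilted by the per-stratum disease risk and, at the
#' candidate marker, by the per-allele odds effect.  Each of the m matched
#' controls is, independently, a perfect stratum match with probability
#' 1 - delta or a random draw from the population with probability delta.
#' Every individual carries genotypes (0/1/2 copies) at all L+1 markers,
#' binomially from their stratum's allele frequencies; case genotypes at the
#' candidate marker reflect the effect size through the tilted frequency.
#'
#' Draws come from the current RNG stream; set a seed beforehand for
#' reproducibility.
#'
#' @param model a \linkS4class{StratumModel}.
#' @param config a \linkS4class{ScenarioConfig}; its L must match the model.
#' @return A list with \code{caseStratum} (length n), \code{controlStratum}
#'   (n x m), \code{caseGenotypes} (n x (L+1)) and \code{controlGenotypes}
#'   (n x (L+1) x m array).
#' @export
drawMatchedSets <- function(model, config) {
    stopifnot(is(model, "StratumModel"), is(config, "ScenarioConfig"))
    nMk <- nrow(model@alleleFreqs)
    if (nMk != config@L + 1L)
        stop("model has ", nMk - 1L, " null markers but config requests ",
             config@L)
    n <- config@nCases
    m <- config@m
    S <- length(model@weights)
    psi <- config@effectSize

    ## case stratum distribution: weights x risk x marginal odds tilt at the
    ## candidate, Pr(s | case) propto w_s r_s (1 - p_s + psi p_s)^2
    pCand <- model@alleleFreqs[1L, ]
    caseDist <- model@weights * model@diseaseRisk * (1 - pCand + psi * pCand)^2
    caseDist <- caseDist / sum(caseDist)
    caseStratum <- sample.int(S, n, replace = TRUE, prob = caseDist)

    ## controls: perfect match w.p. 1 - delta, population draw w.p. delta
    controlStratum <- matrix(caseStratum, nrow = n, ncol = m)
    mismatch <- matrix(runif(n * m) < config@delta, nrow = n)
    nMis <- sum(mismatch)
    if (nMis > 0L)
        controlStratum[mismatch] <- sample.int(S, nMis, replace = TRUE,
                                               prob = model@weights)

    ## genotypes: per-individual p matrix (n x (L+1)) indexed by stratum
    freqByInd <- function(strata) t(model@alleleFreqs)[strata, , drop = FALSE]
    pCase <- freqByInd(caseStratum)
    pCase[, 1L] <- .tiltFreq(pCase[, 1L], psi)
    caseGenotypes <- matrix(rbinom(n * nMk, 2L, pCase), nrow = n)

    controlGenotypes <- array(0L, dim = c(n, nMk, m))
    for (k in seq_len(m)) {
        pCtl <- freqByInd(controlStratum[, k])
        controlGenotypes[, , k] <- matrix(rbinom(n * nMk, 2L, pCtl), nrow = n)
    }
    list(caseStratum = caseStratum, controlStratum = controlStratum,
         caseGenotypes = caseGenotypes, controlGenotypes = controlGenotypes)
}

#' Randomly allocate matched sets to pooling sets
#'
#' Each matched set (a case with its m controls) is assigned independently
#' and uniformly to one of the J pooling sets.  If any pooling set ends up
#' empty the allocation is redrawn (with a message), so every pool is
#' non-empty.
#'
#' @param nSets number of matched sets (must be >= J).
#' @param J number of pooling sets.
#' @param seed optional seed.
#' @return Integer vector of length nSets with values in 1..J.
#' @export
allocateToPools <- function(nSets, J, seed = NULL) {
    stopifnot(nSets >= J, J >= 1L)
    if (!is.null(seed)) set.seed(seed)
    repeat {
        pool <- sample.int(J, nSets, replace = TRUE)
        if (length(unique(pool)) == J) return(pool)
        message("a pooling set received no matched sets; reallocating")
    }
}

#' True allele fraction of a DNA pool
#'
#' @param genotypes integer vector of allele copy numbers (0/1/2) of the
#'   pool's members.
#' @return Total allele copies / (2 x pool size), in [0, 1].
#' @export
truePoolFrequency <- function(genotypes) {
    if (length(genotypes) == 0L)
        stop("cannot compute the allele fraction of an empty pool")
    sum(genotypes) / (2 * length(genotypes))
}

#' Quantitative-PCR measurement of a pooled allele frequency
#'
#' Two-step measurement model.  Unequal allelic amplification first distorts
#' the true pool frequency p to \eqn{p' = \kappa p / (\kappa p + 1 - p)},
#' where kappa is the per-marker amplification coefficient (one assay per
#' marker measures all pools, so kappa is shared by every pool of a marker).
#' Measurement noise is then logit-normal around p':
#' \eqn{\mathrm{logit}(p_{obs}) \sim N(\mathrm{logit}(p'), \tau^2)} with
#' \eqn{\tau = \sigma / (p'(1 - p'))}, the delta-method calibration that makes
#' the standard deviation of the measured frequency approximately sigma on
#' the allele-frequency scale.  With sigma = 0 the distorted value p' is
#' returned exactly.  Monomorphic pools (p of exactly 0 or 1) are returned
#' unchanged -- with a warning when sigma > 0, since the logit-normal noise
#' step is undefined at the boundary (the amplification map itself is exact
#' there: 0 maps to 0 and 1 to 1).
#'
#' @param p true pool allele frequencies (vectorised).
#' @param kappa amplification coefficient(s) >= 1, recycled along p.
#' @param sigma measurement error on the frequency scale (scalar).
#' @param seed optional seed.
#' @return Measured frequencies, same length as p.
#' @examples
#' measurePool(0.5, kappa = 2, sigma = 0)  # 2/3 exactly
#' @export
measurePool <- function(p, kappa, sigma, seed = NULL) {
    stopifnot(all(p >= 0 & p <= 1), all(kappa >= 1), sigma >= 0)
    if (!is.null(seed)) set.seed(seed)
    out <- p
    inner <- p > 0 & p < 1
    # at the boundaries the amplification map is exact (0 -> 0, 1 -> 1);
    # only the logit-normal noise step is undefined there
    if (any(!inner) && sigma > 0)
        warning("monomorphic pool frequency (0 or 1) returned unchanged; ",
                "the logit-normal measurement model is undefined there")
    if (any(inner)) {
        kp <- rep_len(kappa, length(p))[inner]
        pd <- .tiltFreq(p[inner], kp)       # same form as allelic tilt
        if (sigma == 0) {
            out[inner] <- pd
        } else {
            tau <- sigma / (pd * (1 - pd))
            out[inner] <- plogis(rnorm(sum(inner), qlogis(pd), tau))
        }
    }
    out
}

#' Simulate a full oligoset DNA pooling dataset
#'
#' End-to-end composition of the data-generating model: matched sets are
#' drawn from the hidden-stratum population (\code{\link{drawMatchedSets}}),
#' allocated uniformly to J pooling sets (\code{\link{allocateToPools}}),
#' each pool's true allele fraction is computed
#' (\code{\link{truePoolFrequency}}), one amplification coefficient kappa is
#' drawn per marker from \code{kappaRange}, and every pool of every marker is
#' measured through \code{\link{measurePool}}.  The returned table carries
#' \eqn{p_{1ij}}, the measured case-pool frequency, and \eqn{p_{0ij}}, the
#' arithmetic mean of the m measured control-pool frequencies.
#'
#' When \code{config@seed} is set the result is fully reproducible from
#' (model, config); otherwise the current RNG stream is used.
#'
#' @param model a \linkS4class{StratumModel}.
#' @param config a \linkS4class{ScenarioConfig}.
#' @return A \linkS4class{PoolFrequencySet}.
#' @examples
#' cfg <- scenarioConfig(nCases = 120, J = 4, L = 5, seed = 42)
#' set.seed(42); mod <- defaultStratumModel(L = 5)
#' simulateDataset(mod, cfg)
#' @export
simulateDataset <- function(model, config) {
    if (!is.na(config@seed)) set.seed(config@seed)
    mats <- .simulateFreqMatrices(model, config)
    PoolFrequencySet(mats$p1, mats$p0)
}

## matrix core of simulateDataset, shared with the grid drivers (which skip
## the cost of building a validated S4 container per replicate)
.simulateFreqMatrices <- function(model, config) {
    sets <- drawMatchedSets(model, config)
    J <- config@J
    m <- config@m
    nMk <- config@L + 1L
    pool <- allocateToPools(config@nCases, J)
    poolSizes <- tabulate(pool, nbins = J)

    ## per-pool true frequencies: rowsum over matched-set allocation
    poolFreq <- function(geno) {
        sums <- rowsum(geno, pool)              # J x (L+1) allele-copy totals
        sweep(t(sums), 2L, 2 * poolSizes, `/`)  # (L+1) x J
    }
    trueP1 <- poolFreq(sets$caseGenotypes)

    kappa <- runif(nMk, config@kappaRange[1], config@kappaRange[2])
    measure <- function(tp)                      # tp is (L+1) x J
        matrix(measurePool(as.vector(tp), rep(kappa, times = J),
                           config@sigma),
               nrow = nMk)
    p1 <- measure(trueP1)
    p0 <- matrix(0, nrow = nMk, ncol = J)
    for (k in seq_len(m))
        p0 <- p0 + measure(poolFreq(sets$controlGenotypes[, , k]))
    p0 <- p0 / m

    rownames(p1) <- rownames(p0) <-
        c("candidate", paste0("null", seq_len(config@L)))
    list(p1 = p1, p0 = p0)
}
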