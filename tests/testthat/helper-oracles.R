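# Independent scalar-loop oracles against which the vectorised
# implementation is checked.  Deliberately naive: explicit loops, no shared
# code with the package internals.

oracleChi2 <- function(D) {
    out <- numeric(nrow(D))
    for (i in seq_len(nrow(D))) {
        s <- 0
        q <- 0
        for (j in seq_len(ncol(D))) {
            s <- s + D[i, j]
            q <- q + D[i, j]^2
        }
        out[i] <- if (q == 0) 0 else s^2 / q
    }
    out
}

oracleT <- function(D) {
    chi2 <- oracleChi2(D)
    chi2[1] / mean(chi2[-1])
}

# T under one sign pattern, by explicit column flipping and full
# recomputation
oracleTSigned <- function(D, signs) {
    Ds <- D
    for (j in seq_len(ncol(D))) Ds[, j] <- D[, j] * signs[j]
    oracleT(Ds)
}

# exact p-value by hand enumeration of all 2^J patterns (recursive, no bit
# tricks shared with the implementation)
oracleExhaustiveP <- function(D, strict = FALSE) {
    J <- ncol(D)
    tObs <- oracleT(D)
    patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), J)))
    tAll <- apply(patterns, 1L, function(s) oracleTSigned(D, s))
    if (strict) mean(tAll > tObs) else mean(tAll >= tObs)
}

randomD <- function(L, J, sd = 0.05) {
    matrix(rnorm((L + 1) * J, sd = sd), nrow = L + 1)
}

smallConfig <- function(...) {
    args <- list(...)
    defaults <- list(nCases = 120, m = 1, J = 4, L = 3, delta = 0,
                     sigma = 0, kappaRange = c(1, 1), effectSize = 1)
    do.call(scenarioConfig, utils::modifyList(defaults, args))
}

flatModel <- function(L, nStrata = 5, freq = 0.3) {
    stratumModel(weights = rep(1 / nStrata, nStrata),
                 alleleFreqs = matrix(freq, nrow = L + 1, ncol = nStrata),
                 diseaseRisk = rep(0.05, nStrata))
}
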