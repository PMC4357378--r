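test_that("matching limits: delta = 0 copies the case stratum, delta = 1 draws from the population", {
    set.seed(21)
    mod <- defaultStratumModel(3)
    s0 <- drawMatchedSets(mod, scenarioConfig(nCases = 400, m = 2, J = 4,
                                              L = 3, delta = 0))
    expect_true(all(s0$controlStratum == s0$caseStratum))

    s1 <- drawMatchedSets(mod, scenarioConfig(nCases = 4000, m = 1, J = 4,
                                              L = 3, delta = 1))
    # with random matching the control strata follow the population weights
    # (equal fifths), not the risk-tilted case distribution
    freq <- tabulate(s1$controlStratum, 5) / 4000
    se <- sqrt(0.2 * 0.8 / 4000)
    expect_true(all(abs(freq - 0.2) < 4 * se))
    # while cases over-represent the high-risk strata
    expect_gt(mean(s1$caseStratum), mean(s1$controlStratum))
})

test_that("null effect with perfect matching gives no systematic case-control difference", {
    set.seed(22)
    mod <- flatModel(2, freq = 0.3)
    cfg <- smallConfig(nCases = 2000, L = 2, delta = 0)
    s <- drawMatchedSets(mod, cfg)
    d <- mean(s$caseGenotypes[, 1]) / 2 - mean(s$controlGenotypes[, 1, 1]) / 2
    se <- sqrt(2 * 0.3 * 0.7 / (2 * 2000))
    expect_lt(abs(d), 3 * se)
})

test_that("the candidate effect tilts case allele frequencies as a per-allele odds model", {
    set.seed(23)
    psi <- 2
    mod <- flatModel(1, freq = 0.3)
    cfg <- smallConfig(nCases = 5000, L = 1, effectSize = psi)
    s <- drawMatchedSets(mod, cfg)
    pCase <- mean(s$caseGenotypes[, 1]) / 2
    expected <- 0.3 * psi / (0.3 * psi + 0.7)
    expect_lt(abs(pCase - expected),
              3 * sqrt(expected * (1 - expected) / (2 * 5000)))
    # null markers are untouched by the effect
    pNull <- mean(s$caseGenotypes[, 2]) / 2
    expect_lt(abs(pNull - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 5000)))
})

test_that("pool allocation is uniform, non-empty and reproducible", {
    pool <- allocateToPools(900, 10, seed = 3)
    expect_identical(pool, allocateToPools(900, 10, seed = 3))
    expect_identical(sort(unique(pool)), 1:10)
    sizes <- tabulate(pool, 10)
    expect_lt(max(abs(sizes - 90)), 4 * sqrt(900 * 0.1 * 0.9))
    expect_identical(allocateToPools(7, 1), rep(1L, 7))
    expect_error(allocateToPools(3, 5), "nSets >= J")
})

test_that("true pool frequency is the allele-copy fraction", {
    expect_equal(truePoolFrequency(c(0L, 0L, 0L)), 0)
    expect_equal(truePoolFrequency(c(2L, 2L)), 1)
    expect_equal(truePoolFrequency(c(0L, 1L, 2L)), 0.5)
    expect_error(truePoolFrequency(integer(0)), "empty pool")
})

test_that("measurement model: distortion is exact and monotone, noise is calibrated", {
    expect_equal(measurePool(0.5, kappa = 1, sigma = 0), 0.5)
    expect_equal(measurePool(0.5, kappa = 2, sigma = 0), 2 / 3)
    # strictly increasing in p for fixed kappa, and in kappa for fixed p
    p <- seq(0.05, 0.95, by = 0.05)
    expect_true(all(diff(measurePool(p, 1.5, 0)) > 0))
    expect_true(all(diff(sapply(c(1, 1.3, 1.7, 2),
                                function(k) measurePool(0.4, k, 0))) > 0))
    # delta-method calibration: SD of the measured frequency ~ sigma
    obs <- measurePool(rep(0.5, 20000), kappa = 1, sigma = 0.05, seed = 9)
    expect_gt(sd(obs), 0.044)
    expect_lt(sd(obs), 0.056)
    expect_warning(measurePool(c(0, 0.5, 1), 1.5, 0.01, seed = 1),
                   "monomorphic")
})

test_that("simulated datasets are reproducible and structurally sound", {
    set.seed(31); mod <- defaultStratumModel(4)
    cfg <- scenarioConfig(nCases = 200, m = 2, J = 5, L = 4, seed = 77)
    t1 <- simulateDataset(mod, cfg)
    t2 <- simulateDataset(mod, cfg)
    expect_identical(p1freq(t1), p1freq(t2))
    expect_identical(p0freq(t1), p0freq(t2))
    expect_identical(dim(t1), c(5L, 5L))
    expect_s4_class(t1, "PoolFrequencySet")
})

test_that("the noiseless limit reproduces the true pool frequencies exactly", {
    set.seed(41); mod <- flatModel(3, freq = 0.4)
    cfg <- smallConfig(nCases = 60, J = 3, L = 3, seed = 123)
    tab <- simulateDataset(mod, cfg)

    # mirror the generative composition step by step with the exported
    # operations on the same stream
    set.seed(123)
    sets <- drawMatchedSets(mod, cfg)
    pool <- allocateToPools(60, 3)
    for (i in 1:4) for (j in 1:3) {
        expect_equal(unname(p1freq(tab)[i, j]),
                     truePoolFrequency(sets$caseGenotypes[pool == j, i]))
        expect_equal(unname(p0freq(tab)[i, j]),
                     truePoolFrequency(sets$controlGenotypes[pool == j, i, 1]))
    }
})

test_that("averaging over control pools: m = 2 blends two measured pools", {
    set.seed(43); mod <- flatModel(2, freq = 0.4)
    cfg <- smallConfig(nCases = 60, m = 2, J = 3, L = 2, seed = 5)
    tab <- simulateDataset(mod, cfg)
    set.seed(5)
    sets <- drawMatchedSets(mod, cfg)
    pool <- allocateToPools(60, 3)
    for (j in 1:3) {
        f1 <- truePoolFrequency(sets$controlGenotypes[pool == j, 1, 1])
        f2 <- truePoolFrequency(sets$controlGenotypes[pool == j, 1, 2])
        expect_equal(unname(p0freq(tab)[1, j]), (f1 + f2) / 2)
    }
})

test_that("candidate differences are centred and sign-balanced under the exchangeable null", {
    set.seed(51)
    mod <- flatModel(1, freq = 0.3)
    cfg <- smallConfig(nCases = 50, J = 2, L = 1)
    d <- replicate(500, {
        m <- poolGC:::.simulateFreqMatrices(mod, cfg)
        (m$p1 - m$p0)[1, 1]
    })
    expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(500))
    nz <- d[d != 0]
    expect_lt(abs(mean(nz > 0) - 0.5), 3 * sqrt(0.25 / length(nz)))
})

test_that("unmatched confounding inflates the naive single-marker test", {
    # delta = 1 (random controls) with opposed frequency/risk gradients:
    # the candidate chi-square alone, referred to chi-square(1), rejects far
    # above the nominal level -- the bias genomic control is there to fix
    set.seed(61)
    rej <- replicate(200, {
        mod <- defaultStratumModel(1)
        m <- poolGC:::.simulateFreqMatrices(
            mod, scenarioConfig(nCases = 300, J = 6, L = 1, delta = 1,
                                sigma = 0.01))
        chi0 <- chiSquarePerMarker(m$p1 - m$p0)[1]
        pchisq(chi0, 1, lower.tail = FALSE) <= 0.05
    })
    expect_gt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("at J = 25 the simulated null T distribution matches the sign-flip distribution", {
    set.seed(71)
    mod <- flatModel(5, freq = 0.3)
    cfg <- smallConfig(nCases = 150, J = 25, L = 5)
    tSim <- replicate(400, {
        m <- poolGC:::.simulateFreqMatrices(mod, cfg)
        tStatistic(chiSquarePerMarker(m$p1 - m$p0))
    })
    m <- poolGC:::.simulateFreqMatrices(mod, cfg)
    D <- m$p1 - m$p0
    tPerm <- poolGC:::.tUnderSigns(
        D, matrix(sample(c(-1, 1), 25 * 3000, replace = TRUE), nrow = 25))
    ks <- suppressWarnings(ks.test(tSim, tPerm))$statistic
    expect_lt(unname(ks), 0.12)
})

test_that("scenario validation catches out-of-range knobs", {
    expect_error(scenarioConfig(delta = 1.5), "delta")
    expect_error(scenarioConfig(sigma = -0.1), "sigma")
    expect_error(scenarioConfig(kappaRange = c(0.5, 2)), "kappaRange")
    expect_error(scenarioConfig(effectSize = 0), "effectSize")
    expect_error(scenarioConfig(nCases = 5, J = 10), "nCases >= J")
    expect_error(stratumModel(c(0.5, 0.5),
                              matrix(c(0.3, 1.2, 0.3, 0.4), 2), c(0.05, 0.05)),
                 "strictly inside")
})
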