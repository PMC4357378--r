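test_that("difference matrix is the elementwise case-minus-control subtraction", {
    p1 <- rbind(c(0.55, 0.52), c(0.31, 0.29))
    p0 <- rbind(c(0.50, 0.50), c(0.30, 0.30))
    pfs <- PoolFrequencySet(p1, p0)
    expect_equal(unname(differenceMatrix(pfs)[1, ]), c(0.05, 0.02))

    # identical assays give the zero matrix
    same <- PoolFrequencySet(p1, p1)
    expect_true(all(differenceMatrix(same) == 0))

    # random table vs cell-by-cell scalar loop
    set.seed(101)
    a <- matrix(runif(12), nrow = 3)
    b <- matrix(runif(12), nrow = 3)
    D <- differenceMatrix(PoolFrequencySet(a, b))
    for (i in 1:3) for (j in 1:4)
        expect_equal(unname(D[i, j]), a[i, j] - b[i, j])
})

test_that("container validation rejects malformed frequency tables", {
    p <- matrix(0.5, 2, 3)
    expect_error(PoolFrequencySet(p, matrix(0.5, 2, 2)), "dimensions")
    bad <- p; bad[2, 3] <- 1.2
    expect_error(PoolFrequencySet(bad, p), "outside \\[0, 1\\]")
    expect_error(PoolFrequencySet(bad, p), "row 2, pool set 3")
    nas <- p; nas[1, 1] <- NA
    expect_error(PoolFrequencySet(nas, p), "missing")
    expect_error(PoolFrequencySet(matrix(0.5, 2, 1), matrix(0.5, 2, 1)),
                 "J = 2")
    expect_error(PoolFrequencySet(p, p, candidate = "nope"),
                 "unknown candidate")
})

test_that("candidate marker is reordered to row 1", {
    p1 <- rbind(a = c(0.5, 0.5), b = c(0.6, 0.6), c = c(0.7, 0.7))
    pfs <- PoolFrequencySet(p1, p1, candidate = "b")
    expect_identical(rownames(pfs)[1], "b")
    expect_true(SummarizedExperiment::rowData(pfs)$candidate[1])
    expect_equal(unname(p1freq(pfs)[1, 1]), 0.6)
})

test_that("per-marker chi-square matches the printed formula", {
    # constant nonzero row attains the Cauchy-Schwarz bound J
    expect_equal(unname(chiSquarePerMarker(rbind(rep(0.02, 10),
                                                 rep(0.01, 10)))[1]), 10)
    # sum-zero row gives 0
    D <- rbind(c(0.05, -0.05, 0.03, -0.03), c(0.01, 0.01, 0.01, 0.02))
    expect_equal(unname(chiSquarePerMarker(D)[1]), 0)
    # hand arithmetic: (0.03 - 0.01 + 0.02)^2 / (9+1+4)e-4
    D2 <- rbind(c(0.03, -0.01, 0.02), c(0.01, 0.01, 0.01))
    expect_equal(unname(chiSquarePerMarker(D2)[1]), 0.0016 / 0.0014,
                 tolerance = 1e-12)
    # all-zero row is defined as 0, not an error
    D3 <- rbind(c(0, 0, 0), c(0.01, 0.02, 0.01))
    expect_equal(unname(chiSquarePerMarker(D3)[1]), 0)
})

test_that("chi-square agrees with the scalar-loop oracle and obeys its bounds", {
    set.seed(77)
    for (rep in 1:25) {
        L <- sample(1:6, 1)
        J <- sample(2:12, 1)
        D <- randomD(L, J)
        chi2 <- chiSquarePerMarker(D)
        expect_equal(unname(chi2), oracleChi2(D), tolerance = 1e-12)
        expect_true(all(chi2 >= 0 & chi2 <= J + 1e-12))
        # scale and sign invariance per row
        c0 <- runif(1, 0.1, 5)
        expect_equal(chiSquarePerMarker(D * c0), chi2, tolerance = 1e-12)
        expect_equal(chiSquarePerMarker(-D), chi2, tolerance = 1e-12)
    }
})

test_that("T is the candidate chi-square over the null mean", {
    expect_equal(tStatistic(c(4, 2, 2, 2)), 2)
    expect_equal(tStatistic(c(0, 1, 2, 3)), 0)
    expect_equal(tStatistic(c(3.0, 1.0, 2.0, 3.0)), 1.5)
    expect_error(tStatistic(c(1, 0, 0)), "degenerate null")
    expect_error(tStatistic(2), "at least one null")
})

test_that("large-sample references give textbook tail probabilities", {
    expect_equal(largeSamplePValue(0), 1)
    expect_equal(largeSamplePValue(3.841459), 0.05, tolerance = 1e-6)
    expect_equal(largeSamplePValue(6.634897), 0.01, tolerance = 1e-6)
    # finite-L reference is the F(1, L) upper tail, heavier than chi2(1)
    expect_equal(largeSamplePValue(qf(0.95, 1, 10), 10), 0.05,
                 tolerance = 1e-10)
    expect_gt(largeSamplePValue(3.841459, 10), 0.05)
    # and approaches the chi-square convention as L grows
    expect_equal(largeSamplePValue(3.841459, 1e6), 0.05, tolerance = 1e-4)
})

test_that("typing cost ratio counts pools against individuals", {
    expect_equal(typingCostRatio(10, 1, 9000, 9000), 1 / 900)
    expect_equal(typingCostRatio(25, 2, 900, 1800), 1 / 36)
    # no-pooling limit: one pair per set
    expect_equal(typingCostRatio(900, 1, 900, 900), 1)
})
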