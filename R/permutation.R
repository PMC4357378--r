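#' Apply a sign pattern to a difference matrix
#'
#' Exchanging case and control labels within pooling set j leaves the genetic
#' data unchanged but negates every entry of column j of the difference
#' matrix: one sign per pooling set, applied identically to the candidate and
#' all null markers.  The per-row sum of squares is invariant under any
#' pattern, so only the row sums (and hence the chi-squares) change.
#'
#' @param D numeric (L+1) x J difference matrix.
#' @param signs numeric/integer vector of length J with entries +1 or -1.
#' @return The column-flipped matrix.
#' @export
applySigns <- function(D, signs) {
    D <- .asDMatrix(D)
    if (length(signs) != ncol(D))
        stop("'signs' must have one entry per pooling set (", ncol(D),
             "), got ", length(signs))
    if (!all(signs %in% c(-1, 1)))
        stop("'signs' entries must be +1 or -1")
    sweep(D, 2L, signs, `*`)
}

## T statistic under each column of a J x B sign-pattern matrix.
## Exploits the invariance of the per-row sum of squares: only the row sums
## are recomputed, as D %*% S.  Columns where the null-mean chi-square
## degenerates to 0 give T = Inf when the candidate chi-square is positive,
## and T = 0 when it is also zero.
.tUnderSigns <- function(D, S) {
    den <- rowSums(D^2)
    if (all(den[-1] == 0))
        stop("degenerate null: every null-marker row is identically zero; ",
             "the genomic-control denominator cannot be calibrated")
    chi2 <- (D %*% S)^2 / den
    if (any(den == 0))
        chi2[den == 0, ] <- 0
    nullMean <- colMeans(chi2[-1, , drop = FALSE])
    tv <- chi2[1, ] / nullMean
    tv[is.nan(tv)] <- 0          # 0/0: candidate and nulls all vanish
    tv
}

.observedT <- function(D) {
    tStatistic(chiSquarePerMarker(D))
}

.resolveD <- function(x) {
    if (is(x, "PoolFrequencySet")) differenceMatrix(x) else .asDMatrix(x)
}

#' Sign-flip permutation test for the disequilibrium statistic T
#'
#' Approximates the null sampling distribution of T by randomly shuffling the
#' disease status within each pooling set: each permutation multiplies every
#' column of the difference matrix independently by +1 (status unchanged) or
#' -1 (status exchanged), each with probability 1/2, and recomputes T (the
#' candidate and all null-marker chi-squares are recomputed under the same
#' pattern).  The p-value is the proportion of permutation T statistics at
#' least as large as the observed one.
#'
#' Two tie rules are available.  The default,
#' \code{"greater-or-equal-plus-one"}, returns
#' \eqn{(1 + \#\{T^{(b)} \ge T_{obs}\}) / (1 + B)}, which is guaranteed valid
#' (p-value never 0, type-I error at most the nominal level).  The literal
#' rule \code{"greater"} returns \eqn{\#\{T^{(b)} > T_{obs}\} / B} and can be
#' anti-conservative in the extreme tail.
#'
#' @param x a \linkS4class{PoolFrequencySet} or a difference matrix with the
#'   candidate marker as row 1.
#' @param nPermutations number of random sign patterns (default 10000).
#' @param seed optional integer seed; recorded in the result.
#' @param tieRule \code{"greater-or-equal-plus-one"} (default) or
#'   \code{"greater"}.
#' @param comparator logical; also compute the large-sample comparator
#'   p-value for the observed T (F(1, L) reference, see
#'   \code{\link{largeSamplePValue}}).
#' @return A \linkS4class{PoolTestResult}.
#' @examples
#' set.seed(1)
#' D <- matrix(rnorm(44, sd = 0.02), nrow = 11)
#' permutationTest(D, nPermutations = 1000, seed = 7)
#' @seealso \code{\link{exhaustiveTest}} for exact enumeration at small J.
#' @export
permutationTest <- function(x, nPermutations = 10000L, seed = NULL,
                            tieRule = c("greater-or-equal-plus-one",
                                        "greater"),
                            comparator = FALSE) {
    tieRule <- match.arg(tieRule)
    D <- .resolveD(x)
    nPermutations <- as.integer(nPermutations)
    stopifnot(nPermutations >= 1L)
    if (!is.null(seed)) set.seed(seed)
    J <- ncol(D)
    tObs <- .observedT(D)
    S <- matrix(sample(c(-1, 1), J * nPermutations, replace = TRUE),
                nrow = J)
    tPerm <- .tUnderSigns(D, S)
    p <- if (tieRule == "greater")
        sum(tPerm > tObs) / nPermutations
    else
        (1 + sum(tPerm >= tObs)) / (1 + nPermutations)
    new("PoolTestResult",
        tObserved = tObs, pValue = p, nPermutations = nPermutations,
        exhaustive = FALSE, tieRule = tieRule,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        largeSamplePValue = if (comparator)
                                largeSamplePValue(tObs, nrow(D) - 1L)
                            else NA_real_)
}

.allSignPatterns <- function(J) {
    if (J > 20L)
        stop("exhaustive enumeration of 2^", J, " sign patterns refused; ",
             "use permutationTest() for J > 20")
    k <- 0:(2^J - 1)
    S <- matrix(1, nrow = J, ncol = length(k))
    for (b in seq_len(J))
        S[b, ] <- ifelse(bitwAnd(k, bitwShiftL(1L, b - 1L)) > 0L, -1, 1)
    S
}

#' Exact sign-flip test by exhaustive enumeration
#'
#' Enumerates all \eqn{2^J} sign patterns and computes T under each, giving
#' the exact permutation distribution for small J (at most 20).  The identity
#' pattern always reproduces the observed T, so the exact p-value is at least
#' \eqn{2^{-J}}.  Used as the ground-truth oracle for the Monte-Carlo test.
#'
#' @inheritParams permutationTest
#' @return A \linkS4class{PoolTestResult} with \code{exhaustive = TRUE}; the
#'   p-value is \eqn{\#\{T^{(b)} \ge T_{obs}\}/2^J} (or the strict-inequality
#'   count under \code{tieRule = "greater"}).
#' @export
exhaustiveTest <- function(x, tieRule = c("greater-or-equal-plus-one",
                                          "greater"),
                           comparator = FALSE) {
    tieRule <- match.arg(tieRule)
    D <- .resolveD(x)
    J <- ncol(D)
    tObs <- .observedT(D)
    tAll <- .tUnderSigns(D, .allSignPatterns(J))
    p <- if (tieRule == "greater") mean(tAll > tObs) else mean(tAll >= tObs)
    new("PoolTestResult",
        tObserved = tObs, pValue = p, nPermutations = NA_integer_,
        exhaustive = TRUE, tieRule = tieRule, seed = NA_integer_,
        largeSamplePValue = if (comparator)
                                largeSamplePValue(tObs, nrow(D) - 1L)
                            else NA_real_)
}
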