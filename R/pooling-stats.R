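#' Case-minus-control pooled frequency difference matrix
#'
#' For every marker i and pooling set j, computes
#' \eqn{D_{ij} = p_{1ij} - p_{0ij}}, the measured case-pool allele frequency
#' minus the averaged control-pool frequency.  All downstream statistics are
#' functions of this matrix; its first row is the candidate marker.
#'
#' @param x a \linkS4class{PoolFrequencySet}.
#' @return A numeric (L+1) x J matrix with the candidate marker as row 1.
#' @seealso \code{\link{chiSquarePerMarker}}, \code{\link{permutationTest}}
#' @export
setGeneric("differenceMatrix", function(x) standardGeneric("differenceMatrix"))

#' @rdname differenceMatrix
#' @export
setMethod("differenceMatrix", "PoolFrequencySet", function(x) {
    p1freq(x) - p0freq(x)
})

.asDMatrix <- function(D) {
    D <- as.matrix(D)
    if (!is.numeric(D) || anyNA(D))
        stop("the difference matrix must be numeric with no missing values")
    if (ncol(D) < 2L)
        stop("at least J = 2 pooling sets (columns) are required")
    if (nrow(D) < 2L)
        stop("at least one null marker row is required below the candidate")
    D
}

#' Per-marker pooling-set chi-square statistic
#'
#' For each marker row of the difference matrix, computes
#' \deqn{\chi^2_i = \left(\sum_{j=1}^{J} D_{ij}\right)^2 / \sum_{j=1}^{J} D_{ij}^2.}
#' By the Cauchy-Schwarz inequality \eqn{0 \le \chi^2_i \le J}, with the upper
#' bound attained exactly when all J differences in the row are equal and
#' nonzero.  An all-zero row (0/0) is defined to give \eqn{\chi^2 = 0}: no
#' frequency difference in any pooling set is no evidence of association, and
#' this convention keeps the ratio statistic T well defined.
#'
#' @param D a numeric (L+1) x J difference matrix (candidate row first), or a
#'   \linkS4class{PoolFrequencySet} from which it is derived.
#' @return Numeric vector of length L+1 of nonnegative chi-square values.
#' @examples
#' chiSquarePerMarker(rbind(rep(0.02, 10), rep(0.01, 10)))  # both equal J = 10
#' @export
chiSquarePerMarker <- function(D) {
    if (is(D, "PoolFrequencySet")) D <- differenceMatrix(D)
    D <- .asDMatrix(D)
    den <- rowSums(D^2)
    chi2 <- numeric(nrow(D))
    ok <- den > 0
    chi2[ok] <- rowSums(D)[ok]^2 / den[ok]
    names(chi2) <- rownames(D)
    chi2
}

#' Genomic-control ratio statistic T
#'
#' The disequilibrium test statistic for the candidate marker:
#' \deqn{T = \chi^2_0 / \mathrm{mean}\{\chi^2_1, \ldots, \chi^2_L\},}
#' the candidate's chi-square divided by the mean chi-square of the L null
#' markers.  Dividing by the empirical null mean calibrates away residual
#' population stratification shared by all markers (genomic control).
#'
#' @param chi2 numeric vector of per-marker chi-squares, candidate first
#'   (as returned by \code{\link{chiSquarePerMarker}}).
#' @return The nonnegative scalar T.
#' @examples
#' tStatistic(c(4, 2, 2, 2))  # 2
#' @export
tStatistic <- function(chi2) {
    if (length(chi2) < 2L)
        stop("need the candidate chi-square plus at least one null marker")
    nullMean <- mean(chi2[-1])
    if (nullMean == 0)
        stop("degenerate null: every null-marker row is identically zero; ",
             "the genomic-control denominator cannot be calibrated")
    chi2[[1]] / nullMean
}

#' Large-sample comparator p-value
#'
#' Refers the observed T statistic to its large-sample (many-pooling-set)
#' null distribution and returns the upper-tail probability.  As the number
#' of pooling sets J grows, the candidate chi-square converges to a 1-df
#' chi-square and the mean of the L null-marker chi-squares to an independent
#' \eqn{\chi^2_L / L}, so \eqn{T \Rightarrow F(1, L)}.  With
#' \code{nullMarkers = Inf} (the default) the denominator is treated as
#' degenerate at 1 and T is referred to \eqn{\chi^2_1} -- the classical
#' genomic-control convention.  Supplying the actual (finite) number of null
#' markers gives the F(1, L) reference, which keeps the denominator's
#' sampling variability and is the comparator used by the experiment drivers.
#'
#' Either way this is a large-J approximation: at oligoset J (< 30) the
#' per-marker chi-squares are lighter-tailed than their limits (they are
#' capped at J), which makes the F(1, L) referral conservative there.  The
#' permutation p-value is the recommended primary analysis for J < 30.
#'
#' @param tObserved nonnegative numeric vector of observed T values.
#' @param nullMarkers number of null markers L behind the genomic-control
#'   denominator, or \code{Inf} (default) for the chi-square(1 df) convention.
#' @return Upper-tail probabilities in [0, 1].
#' @examples
#' largeSamplePValue(3.841459)       # ~0.05, chi-square(1) convention
#' largeSamplePValue(3.841459, 10)   # F(1, 10) reference, larger p
#' @export
largeSamplePValue <- function(tObserved, nullMarkers = Inf) {
    stopifnot(all(tObserved >= 0), length(nullMarkers) == 1L,
              nullMarkers >= 1)
    if (is.infinite(nullMarkers))
        pchisq(tObserved, df = 1, lower.tail = FALSE)
    else
        stats::pf(tObserved, df1 = 1, df2 = nullMarkers, lower.tail = FALSE)
}

#' Genotyping cost of pooling relative to individual typing
#'
#' Per marker, a pooling design types J*(1+m) pools where individual
#' genotyping would type every one of the nCases + nControls subjects.
#'
#' @param J number of pooling sets.
#' @param m matching ratio (control pools per set).
#' @param nCases,nControls study sizes.
#' @return The ratio J*(1+m) / (nCases + nControls).
#' @examples
#' typingCostRatio(10, 1, 9000, 9000)  # 1/900
#' @export
typingCostRatio <- function(J, m, nCases, nControls) {
    stopifnot(J >= 1, m >= 1, nCases >= 1, nControls >= 1)
    J * (1 + m) / (nCases + nControls)
}
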