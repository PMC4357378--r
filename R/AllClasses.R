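#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pchisq plogis qlogis rbinom rnorm runif sd
#' @importFrom utils read.delim write.table modifyList
NULL

#' PoolFrequencySet: measured allele frequencies of a multiple-DNA-pooling study
#'
#' An S4 container for the measured allele frequencies of a stratum-matched
#' case-control DNA pooling study.  Rows are markers (the candidate marker of
#' interest first, then \eqn{L \ge 1} unlinked null markers used for genomic
#' control); columns are the \eqn{J \ge 2} pooling sets.  Two assays are
#' carried: \code{"p1"}, the measured case-pool allele frequency
#' \eqn{p_{1ij}}, and \code{"p0"}, the average of the \eqn{m} measured
#' control-pool frequencies \eqn{p_{0ij}}.  The class extends
#' \linkS4class{SummarizedExperiment}, so the usual \code{assay()},
#' \code{rowData()} and subsetting machinery applies; \code{rowData()$candidate}
#' flags the candidate marker, which is always stored as row 1.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#'
#' @seealso \code{\link{PoolFrequencySet}} (constructor),
#'   \code{\link{differenceMatrix}}, \code{\link{permutationTest}}
#' @export
setClass("PoolFrequencySet", contains = "SummarizedExperiment")

.validPoolFrequencySet <- function(object) {
    msg <- NULL
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("p1", "p0") %in% a))
        msg <- c(msg, "assays 'p1' and 'p0' are both required")
    else {
        p1 <- SummarizedExperiment::assay(object, "p1")
        p0 <- SummarizedExperiment::assay(object, "p0")
        if (anyNA(p1) || anyNA(p0))
            msg <- c(msg, "missing values are not allowed in 'p1'/'p0'")
        else if (any(p1 < 0 | p1 > 1) || any(p0 < 0 | p0 > 1))
            msg <- c(msg, "all measured allele frequencies must lie in [0, 1]")
        if (ncol(object) < 2L)
            msg <- c(msg, "at least J = 2 pooling sets are required (the statistic is degenerate at J = 1)")
        if (nrow(object) < 2L)
            msg <- c(msg, "at least one null marker is required (L >= 1)")
        cand <- SummarizedExperiment::rowData(object)$candidate
        if (is.null(cand) || sum(cand) != 1L)
            msg <- c(msg, "rowData()$candidate must flag exactly one marker")
        else if (which(cand) != 1L)
            msg <- c(msg, "the candidate marker must be stored as row 1")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("PoolFrequencySet", .validPoolFrequencySet)

#' PoolTestResult: outcome of a disequilibrium test on pooled data
#'
#' Holds the observed genomic-control ratio statistic \eqn{T}, the permutation
#' (or exhaustive-enumeration) p-value, and the provenance needed to reproduce
#' it: replicate count or exhaustive flag, tie rule, and RNG seed.
#'
#' @slot tObserved numeric(1), the observed statistic \eqn{T \ge 0}.
#' @slot pValue numeric(1) in [0, 1].
#' @slot nPermutations integer(1), Monte-Carlo replicates (\code{NA} when
#'   exhaustive).
#' @slot exhaustive logical(1), \code{TRUE} when all \eqn{2^J} sign patterns
#'   were enumerated.
#' @slot tieRule character(1), \code{"greater-or-equal-plus-one"} or
#'   \code{"greater"}.
#' @slot seed integer(1) or \code{NA}.
#' @slot largeSamplePValue numeric(1), upper-tail chi-square(1 df) p-value for
#'   \code{tObserved}, or \code{NA} if not requested.
#'
#' @seealso \code{\link{permutationTest}}, \code{\link{exhaustiveTest}}
#' @export
setClass("PoolTestResult",
    representation(
        tObserved = "numeric",
        pValue = "numeric",
        nPermutations = "integer",
        exhaustive = "logical",
        tieRule = "character",
        seed = "integer",
        largeSamplePValue = "numeric"
    ),
    prototype(
        tObserved = NA_real_, pValue = NA_real_,
        nPermutations = NA_integer_, exhaustive = FALSE,
        tieRule = "greater-or-equal-plus-one", seed = NA_integer_,
        largeSamplePValue = NA_real_
    )
)

setValidity("PoolTestResult", function(object) {
    msg <- NULL
    if (length(object@tObserved) != 1L || (!is.na(object@tObserved) && object@tObserved < 0))
        msg <- c(msg, "tObserved must be a single nonnegative number")
    if (length(object@pValue) != 1L ||
        (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1)))
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (!object@tieRule %in% c("greater-or-equal-plus-one", "greater"))
        msg <- c(msg, "tieRule must be 'greater-or-equal-plus-one' or 'greater'")
    if (is.null(msg)) TRUE else msg
})

#' StratumModel: hidden-stratum structure of the source population
#'
#' Describes a source population composed of hidden strata that differ in
#' marker allele frequencies and baseline disease risk -- the configuration
#' under which stratification bias arises and which stratum matching plus
#' genomic control are meant to neutralise.
#'
#' @slot weights numeric, stratum population proportions (sums to 1).
#' @slot alleleFreqs numeric matrix, (L+1) markers x strata, true allele
#'   frequencies strictly inside (0, 1); row 1 is the candidate marker.
#' @slot diseaseRisk numeric, per-stratum baseline disease probability.
#'
#' @seealso \code{\link{stratumModel}}, \code{\link{defaultStratumModel}}
#' @export
setClass("StratumModel",
    representation(
        weights = "numeric",
        alleleFreqs = "matrix",
        diseaseRisk = "numeric"
    )
)

setValidity("StratumModel", function(object) {
    msg <- NULL
    S <- length(object@weights)
    if (S < 1L) msg <- c(msg, "at least one stratum is required")
    if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights < 0))
        msg <- c(msg, "stratum weights must be nonnegative and sum to 1")
    if (ncol(object@alleleFreqs) != S)
        msg <- c(msg, "alleleFreqs must have one column per stratum")
    if (nrow(object@alleleFreqs) < 2L)
        msg <- c(msg, "alleleFreqs needs the candidate row plus at least one null marker")
    if (any(object@alleleFreqs <= 0 | object@alleleFreqs >= 1))
        msg <- c(msg, "all true allele frequencies must lie strictly inside (0, 1)")
    if (length(object@diseaseRisk) != S)
        msg <- c(msg, "diseaseRisk must have one entry per stratum")
    if (any(object@diseaseRisk <= 0 | object@diseaseRisk >= 1))
        msg <- c(msg, "diseaseRisk entries must lie in (0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' ScenarioConfig: all knobs of one simulation scenario
#'
#' @slot nCases integer, number of cases n (default 900).
#' @slot m integer, matching ratio (controls per case; 1 or 2 in the study
#'   designs emulated here).
#' @slot J integer, number of pooling sets (each contributes 1 case pool and
#'   m control pools, J*(1+m) pools in total).
#' @slot L integer, number of null markers used for genomic control.
#' @slot delta numeric in [0, 1], stratum mismatch index: a matched control is
#'   a random draw from the population with probability delta, and a perfect
#'   stratum match with probability 1 - delta.
#' @slot sigma numeric >= 0, measurement error of the pooled-frequency assay on
#'   the allele-frequency scale.
#' @slot kappaRange numeric(2), range of the per-marker unequal-amplification
#'   coefficient kappa (drawn uniformly, one kappa per marker).
#' @slot effectSize numeric > 0, per-allele odds ratio at the candidate marker
#'   (1 = null).
#' @slot seed integer or NA; when set, \code{simulateDataset} is fully
#'   reproducible from (model, config).
#'
#' @seealso \code{\link{scenarioConfig}}, \code{\link{simulateDataset}}
#' @export
setClass("ScenarioConfig",
    representation(
        nCases = "integer", m = "integer", J = "integer", L = "integer",
        delta = "numeric", sigma = "numeric", kappaRange = "numeric",
        effectSize = "numeric", seed = "integer"
    )
)

setValidity("ScenarioConfig", function(object) {
    msg <- NULL
    if (object@nCases < 1L) msg <- c(msg, "nCases must be positive")
    if (object@m < 1L) msg <- c(msg, "matching ratio m must be >= 1")
    if (object@J < 2L) msg <- c(msg, "at least J = 2 pooling sets are required")
    if (object@L < 1L) msg <- c(msg, "at least L = 1 null marker is required")
    if (object@nCases < object@J)
        msg <- c(msg, "need at least one matched set per pooling set (nCases >= J)")
    if (object@delta < 0 || object@delta > 1)
        msg <- c(msg, "delta must lie in [0, 1]")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    if (length(object@kappaRange) != 2L || object@kappaRange[1] < 1 ||
        object@kappaRange[2] < object@kappaRange[1])
        msg <- c(msg, "kappaRange must be an increasing interval within [1, Inf)")
    if (object@effectSize <= 0) msg <- c(msg, "effectSize must be > 0")
    if (is.null(msg)) TRUE else msg
})
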