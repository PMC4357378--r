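#' Construct a PoolFrequencySet
#'
#' Builds the central data container from two (L+1) x J matrices of measured
#' allele frequencies.  The candidate marker must be one of the rows; it is
#' moved to row 1 (the convention used throughout the package) and flagged in
#' \code{rowData()$candidate}.
#'
#' @param p1 numeric matrix, measured case-pool allele frequencies, one row
#'   per marker and one column per pooling set; entries in [0, 1].
#' @param p0 numeric matrix of the same shape: the average of the m measured
#'   control-pool frequencies.
#' @param markerIds character vector of marker identifiers (defaults to the
#'   rownames of \code{p1}, or \code{"candidate", "null1", ...}).
#' @param candidate identifier or row index of the candidate marker
#'   (default: the first row).
#'
#' @return A \linkS4class{PoolFrequencySet}.
#'
#' @examples
#' p1 <- rbind(candidate = c(0.55, 0.52), null1 = c(0.31, 0.29))
#' p0 <- rbind(candidate = c(0.50, 0.50), null1 = c(0.30, 0.30))
#' pfs <- PoolFrequencySet(p1, p0)
#' differenceMatrix(pfs)
#'
#' @export
PoolFrequencySet <- function(p1, p0, markerIds = NULL, candidate = 1L) {
    p1 <- as.matrix(p1)
    p0 <- as.matrix(p0)
    if (!identical(dim(p1), dim(p0)))
        stop("'p1' and 'p0' must have identical dimensions, got ",
             paste(dim(p1), collapse = "x"), " vs ",
             paste(dim(p0), collapse = "x"))
    .checkFreqRange(p1, "p1")
    .checkFreqRange(p0, "p0")
    if (is.null(markerIds))
        markerIds <- if (!is.null(rownames(p1))) rownames(p1)
                     else c("candidate", paste0("null", seq_len(nrow(p1) - 1L)))
    if (length(markerIds) != nrow(p1))
        stop("'markerIds' must name every marker row")
    ci <- if (is.character(candidate)) match(candidate, markerIds)
          else as.integer(candidate)
    if (is.na(ci) || ci < 1L || ci > nrow(p1))
        stop("unknown candidate marker: ", candidate)
    ord <- c(ci, setdiff(seq_len(nrow(p1)), ci))
    p1 <- p1[ord, , drop = FALSE]
    p0 <- p0[ord, , drop = FALSE]
    markerIds <- markerIds[ord]
    dimnames(p1) <- dimnames(p0) <-
        list(markerIds, paste0("set", seq_len(ncol(p1))))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(p1 = p1, p0 = p0),
        rowData = S4Vectors::DataFrame(
            candidate = seq_along(markerIds) == 1L, row.names = markerIds)
    )
    new("PoolFrequencySet", se)
}

.checkFreqRange <- function(x, what) {
    if (anyNA(x))
        stop("'", what, "' contains missing values")
    bad <- which(x < 0 | x > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop("'", what, "' entry at marker row ", bad[1, 1], ", pool set ",
             bad[1, 2], " is ", format(x[bad[1, , drop = FALSE]]),
             ", outside [0, 1]")
    invisible(TRUE)
}

#' @describeIn PoolFrequencySet measured case-pool frequencies \eqn{p_{1ij}}.
#' @param x a \code{PoolFrequencySet}.
#' @export
p1freq <- function(x) SummarizedExperiment::assay(x, "p1")

#' @describeIn PoolFrequencySet averaged control-pool frequencies \eqn{p_{0ij}}.
#' @export
p0freq <- function(x) SummarizedExperiment::assay(x, "p0")

#' @describeIn PoolFrequencySet the number of pooling sets J.
#' @export
numPoolSets <- function(x) ncol(x)

#' @describeIn PoolFrequencySet the number of null markers L.
#' @export
numNullMarkers <- function(x) nrow(x) - 1L

setMethod("show", "PoolFrequencySet", function(object) {
    cat("PoolFrequencySet:", numNullMarkers(object),
        "null marker(s) +1 candidate x", numPoolSets(object),
        "pooling set(s)\n")
    cat("  candidate marker:", rownames(object)[1], "\n")
    D <- p1freq(object) - p0freq(object)
    cat("  candidate p1 - p0 range: [",
        format(min(D[1, ]), digits = 4), ", ",
        format(max(D[1, ]), digits = 4), "]\n", sep = "")
})

setMethod("show", "PoolTestResult", function(object) {
    cat("Disequilibrium test for oligoset DNA pooling\n")
    cat("  T observed        :", format(object@tObserved, digits = 6), "\n")
    if (object@exhaustive) {
        cat("  p-value (exact)   :", format(object@pValue, digits = 6),
            " [all sign patterns enumerated]\n")
    } else {
        cat("  p-value (permut.) :", format(object@pValue, digits = 6),
            sprintf(" [%d permutations, tie rule '%s']\n",
                    object@nPermutations, object@tieRule))
    }
    if (!is.na(object@seed))
        cat("  seed              :", object@seed, "\n")
    if (!is.na(object@largeSamplePValue))
        cat("  large-sample p    :",
            format(object@largeSamplePValue, digits = 6),
            " [F(1, L) comparator]\n")
})

#' @describeIn PoolTestResult the permutation (or exact) p-value.
#' @param x a \code{PoolTestResult}.
#' @export
pValue <- function(x) x@pValue

#' @describeIn PoolTestResult the observed statistic T.
#' @export
tObserved <- function(x) x@tObserved

setMethod("show", "StratumModel", function(object) {
    cat("StratumModel:", length(object@weights), "hidden strata,",
        nrow(object@alleleFreqs) - 1L, "null marker(s) + 1 candidate\n")
    cat("  weights     :", paste(format(object@weights, digits = 3),
                                 collapse = " "), "\n")
    cat("  disease risk:", paste(format(object@diseaseRisk, digits = 3),
                                 collapse = " "), "\n")
    cat("  candidate allele freq:",
        paste(format(object@alleleFreqs[1, ], digits = 3), collapse = " "),
        "\n")
})

setMethod("show", "ScenarioConfig", function(object) {
    cat("ScenarioConfig:\n")
    df <- as.data.frame(object)
    for (nm in names(df))
        cat(sprintf("  %-10s: %s\n", nm, format(df[[nm]])))
})

#' @describeIn scenarioConfig flatten a config to a one-row data.frame
#'   (kappaRange is shown as "lo-hi").
#' @param x a \code{ScenarioConfig}.
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.ScenarioConfig <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    data.frame(
        nCases = x@nCases, m = x@m, J = x@J, L = x@L,
        delta = x@delta, sigma = x@sigma,
        kappaRange = paste(x@kappaRange, collapse = "-"),
        effectSize = x@effectSize,
        seed = x@seed
    )
}
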