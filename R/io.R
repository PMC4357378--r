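#' Read a pool frequency table from TSV
#'
#' Expects a tab-separated file with a header row and columns
#' \code{marker_id}, \code{pool_set} (1-based integer), \code{p1}, \code{p0};
#' one row per (marker, pool set), the full (L+1) x J grid present with no
#' duplicates.  The candidate marker is identified by \code{candidate}
#' (default: the marker named "candidate").
#'
#' @param path file path.
#' @param candidate marker identifier of the candidate (default
#'   \code{"candidate"}).
#' @return A \linkS4class{PoolFrequencySet}, candidate row first.
#' @seealso \code{\link{writePoolTable}}
#' @export
readPoolTable <- function(path, candidate = "candidate") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("marker_id", "pool_set", "p1", "p0")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L)
        stop("pool table is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df[c("marker_id", "pool_set")]))
        stop("duplicate (marker_id, pool_set) pair in ", path)
    markers <- unique(df$marker_id)
    sets <- sort(unique(df$pool_set))
    if (!identical(sets, seq_along(sets)))
        stop("pool_set must be the consecutive integers 1..J, got: ",
             paste(sets, collapse = ", "))
    if (nrow(df) != length(markers) * length(sets))
        stop("ragged pool table: expected the full ", length(markers), " x ",
             length(sets), " grid, got ", nrow(df), " rows")
    toMat <- function(col) {
        m <- matrix(NA_real_, nrow = length(markers), ncol = length(sets),
                    dimnames = list(markers, NULL))
        m[cbind(match(df$marker_id, markers), df$pool_set)] <- df[[col]]
        if (anyNA(m)) stop("missing (marker, pool_set) cell for '", col, "'")
        m
    }
    PoolFrequencySet(toMat("p1"), toMat("p0"), candidate = candidate)
}

#' Write a pool frequency table as TSV
#'
#' Inverse of \code{\link{readPoolTable}}; full precision, one row per
#' (marker, pool set).
#'
#' @param x a \linkS4class{PoolFrequencySet}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePoolTable <- function(x, path) {
    stopifnot(is(x, "PoolFrequencySet"))
    J <- numPoolSets(x)
    df <- data.frame(
        marker_id = rep(rownames(x), times = J),
        pool_set = rep(seq_len(J), each = nrow(x)),
        p1 = sprintf("%.17g", as.vector(p1freq(x))),   # round-trip exact
        p0 = sprintf("%.17g", as.vector(p0freq(x))))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a precomputed difference matrix from TSV
#'
#' First column \code{marker_id}, remaining J columns the \eqn{D_{ij}}
#' values; the first data row is the candidate marker.
#'
#' @param path file path.
#' @return A numeric (L+1) x J matrix with marker rownames.
#' @export
readDMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("a difference matrix file needs marker_id plus at least 2 ",
             "pool-set columns")
    D <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(D) || anyNA(D) || any(!is.finite(D)))
        stop("non-numeric or non-finite cell in difference matrix ", path)
    rownames(D) <- df[[1L]]
    D
}

#' Write a difference matrix as TSV
#'
#' @param D numeric matrix, candidate row first.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeDMatrix <- function(D, path) {
    D <- .asDMatrix(D)
    ids <- if (!is.null(rownames(D))) rownames(D)
           else c("candidate", paste0("null", seq_len(nrow(D) - 1L)))
    df <- data.frame(marker_id = ids,
                     matrix(sprintf("%.17g", D), nrow = nrow(D)),
                     check.names = FALSE)
    colnames(df) <- c("marker_id", paste0("set", seq_len(ncol(D))))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' Recognised keys mirror \code{\link{scenarioConfig}} arguments
#' (\code{nCases}, \code{m}, \code{J}, \code{L}, \code{delta}, \code{sigma},
#' \code{kappaRange}, \code{effectSize}, \code{seed}); omitted keys take the
#' defaults.  Unknown keys raise an error naming the field.
#'
#' @param path YAML file path.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
readScenarioConfig <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    vals <- yaml::read_yaml(path)
    .configFromList(vals)
}

.configFromList <- function(vals) {
    known <- names(formals(scenarioConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad) > 0L)
        stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
    do.call(scenarioConfig, vals)
}

#' Read an experiment grid from a YAML file
#'
#' The file holds a \code{scenario} block (base knobs, schema of
#' \code{\link{readScenarioConfig}}) and an optional \code{vary} block whose
#' entries are lists of values for individual knobs; the grid is the full
#' cross of the varied knobs over the base scenario.  An optional
#' \code{alpha} key lists nominal levels.
#'
#' @param path YAML file path.
#' @return A list with \code{scenarios} (list of
#'   \linkS4class{ScenarioConfig}) and \code{alpha} (numeric).
#' @export
readGridConfig <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    vals <- yaml::read_yaml(path)
    if (is.null(vals) || is.null(vals$scenario))
        stop("no scenarios: the grid file must contain a 'scenario' block")
    base <- vals$scenario
    vary <- vals$vary
    if (is.null(vary) || length(vary) == 0L) {
        scenarios <- list(.configFromList(base))
    } else {
        grid <- expand.grid(vary, stringsAsFactors = FALSE)
        scenarios <- lapply(seq_len(nrow(grid)), function(i) {
            v <- as.list(grid[i, , drop = FALSE])
            .configFromList(utils::modifyList(base, v))
        })
    }
    alpha <- if (is.null(vals$alpha)) c(0.05, 0.005) else as.numeric(vals$alpha)
    list(scenarios = scenarios, alpha = alpha)
}
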