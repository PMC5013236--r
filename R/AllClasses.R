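#' @import methods
NULL

#' An undirected interaction network
#'
#' The central container of the package: a named, undirected graph over
#' string-labelled nodes. Edges are stored as a two-column character matrix
#' in input order, so a freshly read network may still carry self-loops and
#' duplicate edges; cleaning is a separate, explicit step
#' (\code{\link{cleanNetwork}}). Per-edge annotation (free-text relation
#' labels, references, curator notes) travels alongside the edge matrix but
#' is ignored by all topology computations.
#'
#' Node identity is the exact label after trimming leading/trailing
#' whitespace; no case folding is applied, because biological labels such as
#' \code{"F-actin"} and \code{"[Ca2+]i"} mix cases meaningfully and silent
#' case-merging could fuse distinct molecules.
#'
#' @slot name Single string naming the network.
#' @slot nodes Character vector of unique node labels.
#' @slot edges Character matrix with two columns; one row per edge as given.
#' @slot edgeData A \code{data.frame} of per-edge annotation with one row per
#'   row of \code{edges} (possibly zero columns).
#'
#' @seealso \code{\link{Network}} (constructor), \code{\link{cleanNetwork}},
#'   \code{\link{topologyReport}}
#' @export
setClass("InteractionNetwork",
    representation(
        name = "character",
        nodes = "character",
        edges = "matrix",
        edgeData = "data.frame"
    ),
    prototype(
        name = "network",
        nodes = character(),
        edges = matrix(character(), ncol = 2L),
        edgeData = data.frame()
    )
)

setValidity("InteractionNetwork", function(object) {
    msg <- character()
    if (length(object@name) != 1L || is.na(object@name))
        msg <- c(msg, "'name' must be a single string")
    if (anyNA(object@nodes) || any(!nzchar(object@nodes)))
        msg <- c(msg, "node labels must be non-empty strings")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node labels must be unique")
    if (ncol(object@edges) != 2L)
        msg <- c(msg, "'edges' must have exactly two columns")
    if (nrow(object@edges) > 0L) {
        ep <- as.vector(object@edges)
        if (anyNA(ep) || any(!nzchar(ep)))
            msg <- c(msg, "edge endpoints must be non-empty strings")
        else if (!all(ep %in% object@nodes))
            msg <- c(msg, "every edge endpoint must be a member of 'nodes'")
    }
    if (nrow(object@edgeData) != nrow(object@edges))
        msg <- c(msg, "'edgeData' must have one row per edge")
    if (length(msg)) msg else TRUE
})

#' Shortest-path statistics of a network
#'
#' Ordered-pair accounting of all finite shortest paths: pairs (n, m) with
#' n != m are counted in both directions, so the count for a connected
#' component of c nodes is c * (c - 1) and the denominator of the
#' reachable-pair percentage is N * (N - 1).
#'
#' @slot finitePairCount Number of ordered node pairs at finite distance.
#' @slot percentOfAllPairs Fraction (in [0, 1]) of all N(N-1) ordered pairs
#'   that are connected by a finite path.
#' @slot characteristicPathLength Mean shortest-path length over finite
#'   ordered pairs.
#' @slot diameter Longest finite shortest path (NA if no finite pair).
#' @slot histogram Named integer vector mapping each distance k >= 1 to the
#'   number of ordered pairs at that distance.
#' @export
setClass("DistanceSummary",
    representation(
        finitePairCount = "numeric",
        percentOfAllPairs = "numeric",
        characteristicPathLength = "numeric",
        diameter = "integer",
        histogram = "integer"
    )
)

setValidity("DistanceSummary", function(object) {
    msg <- character()
    if (length(object@histogram) &&
        sum(object@histogram) != object@finitePairCount)
        msg <- c(msg, "histogram must sum to finitePairCount")
    if (!is.na(object@percentOfAllPairs) &&
        (object@percentOfAllPairs < 0 || object@percentOfAllPairs > 1))
        msg <- c(msg, "percentOfAllPairs must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' One-network topological summary
#'
#' The full set of whole-network topological parameters: connected
#' components, node and edge counts, mean clustering coefficient, diameter,
#' shortest-path statistics, characteristic path length and mean number of
#' neighbors. Values are kept at full precision; rounding to three decimals
#' happens only at serialization (\code{as.data.frame}).
#'
#' @slot networkName Name of the summarised network.
#' @slot nComponents Number of connected components.
#' @slot nNodes,nEdges Node and (distinct) edge counts.
#' @slot meanClustering Mean node clustering coefficient over nodes of
#'   degree >= 2.
#' @slot diameter Longest finite shortest path.
#' @slot distances A \code{\linkS4class{DistanceSummary}}.
#' @slot characteristicPathLength Mean finite shortest-path length.
#' @slot avgNeighbors Mean degree, 2E/N.
#' @export
setClass("TopologyReport",
    representation(
        networkName = "character",
        nComponents = "integer",
        nNodes = "integer",
        nEdges = "integer",
        meanClustering = "numeric",
        diameter = "integer",
        distances = "DistanceSummary",
        characteristicPathLength = "numeric",
        avgNeighbors = "numeric"
    )
)

#' Least-squares power-law fit on logarithmized data
#'
#' Result of fitting y = a * x^gamma by ordinary least squares of log10(y)
#' on log10(x). Two distinct agreement statistics are reported, mirroring
#' the convention of Cytoscape's NetworkAnalyzer: \code{rSquared} is the
#' coefficient of determination of the linear fit on the logarithmized data,
#' while \code{r} is the Pearson correlation between the observed values and
#' the fitted power-law values on the original scale. The two generally
#' differ on noisy data.
#'
#' @slot gamma Fitted exponent (slope on log-log axes).
#' @slot amplitude Back-transformed intercept, a = 10^intercept (> 0).
#' @slot r Pearson correlation of observed vs fitted values, original scale.
#' @slot rSquared Coefficient of determination of the log-log regression.
#' @slot nPoints Number of points used in the fit.
#' @slot nExcluded Number of points excluded upstream (zero counts or zero
#'   clustering classes, whose logarithm is undefined).
#' @slot what Short label of what was fitted.
#' @export
setClass("PowerLawFit",
    representation(
        gamma = "numeric",
        amplitude = "numeric",
        r = "numeric",
        rSquared = "numeric",
        nPoints = "integer",
        nExcluded = "integer",
        what = "character"
    )
)

setValidity("PowerLawFit", function(object) {
    msg <- character()
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (!is.na(object@amplitude) && object@amplitude <= 0)
        msg <- c(msg, "amplitude must be positive")
    if (object@nPoints < 2L)
        msg <- c(msg, "a fit needs at least two points")
    if (length(msg)) msg else TRUE
})

#' Hub set of a network
#'
#' Hubs are the nodes whose degree is at least one standard deviation above
#' the network mean degree. The population (divide-by-N) standard deviation
#' is the default: the node set is the whole population, not a sample.
#'
#' @slot networkName Name of the network.
#' @slot meanDegree Mean node degree.
#' @slot sdDegree Standard deviation of the degrees.
#' @slot threshold meanDegree + sdDegree; nodes with degree >= threshold are
#'   hubs.
#' @slot hubs \code{data.frame} with columns \code{node}, \code{degree},
#'   sorted by decreasing degree then label.
#' @slot degenerate TRUE when all degrees are equal (SD = 0), in which case
#'   every node meets the threshold and "hub" is uninformative.
#' @export
setClass("HubSet",
    representation(
        networkName = "character",
        meanDegree = "numeric",
        sdDegree = "numeric",
        threshold = "numeric",
        hubs = "data.frame",
        degenerate = "logical"
    )
)

#' Topology classification of a network
#'
#' Label is one of \code{"hierarchical"} (high mean clustering whose
#' per-degree means correlate with degree), \code{"scale_free_BA"}
#' (negative power-law degree exponent with a good log-log fit and low
#' clustering) or \code{"indeterminate"}. The label is a pure function of
#' the evidence vector; see \code{\link{classifyEvidence}}.
#'
#' @slot label Classification label.
#' @slot smallWorld Small-world annotation (short characteristic path length
#'   at high reachability).
#' @slot evidence Named numeric vector of the quantities the rule inspects.
#' @slot reason Free-text explanation, mainly for indeterminate results.
#' @export
setClass("TopologyClass",
    representation(
        label = "character",
        smallWorld = "logical",
        evidence = "numeric",
        reason = "character"
    )
)

#' Multi-network comparison report
#'
#' Per-network topological summaries, degree and degree-vs-clustering fits,
#' hub sets and topology classes, together with node- and hub-label overlap
#' partitions (Venn regions) across up to five networks.
#'
#' @slot perNetwork Named list; one entry per network holding its
#'   \code{report}, \code{degreeFit}, \code{clusteringFit}, \code{hubs} and
#'   \code{class} (fit slots may be NULL when a fit legitimately fails).
#' @slot topologyTable,degreeFitTable,clusteringFitTable Assembled
#'   data.frame views of the per-network results.
#' @slot nodeOverlap,hubOverlap Venn-region partitions (lists mapping region
#'   name to member labels), or empty lists when not computed.
#' @export
setClass("ComparisonReport",
    representation(
        perNetwork = "list",
        topologyTable = "data.frame",
        degreeFitTable = "data.frame",
        clusteringFitTable = "data.frame",
        nodeOverlap = "list",
        hubOverlap = "list"
    )
)
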