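#' Node degree
#'
#' Number of distinct neighbors of a node; on a clean network this equals
#' the number of incident edges.
#'
#' @param x An \code{InteractionNetwork}.
#' @param node Node label.
#' @return Integer degree.
#' @export
nodeDegree <- function(x, node) {
    node <- .trim(node)
    if (!node %in% x@nodes) stop("unknown node: ", node)
    unname(nodeDegrees(x)[node])
}

#' Degrees of all nodes
#'
#' @param x An \code{InteractionNetwork}.
#' @return Named integer vector, one entry per node.
#' @export
nodeDegrees <- function(x) {
    adj <- .adjacency(x)
    d <- vapply(adj, length, integer(1L))
    names(d) <- x@nodes
    d
}

#' Node clustering coefficient
#'
#' C_I = 2 n_I / (k_I (k_I - 1)), where k_I is the degree of node I and n_I
#' the number of links connecting its k_I neighbors to each other. For
#' nodes of degree < 2 the coefficient is undefined (the denominator
#' vanishes) and NA is returned.
#'
#' @param x A clean \code{InteractionNetwork}.
#' @param node Node label.
#' @return Numeric in [0, 1], or NA for degree < 2.
#' @export
nodeClustering <- function(x, node) {
    node <- .trim(node)
    i <- match(node, x@nodes)
    if (is.na(i)) stop("unknown node: ", node)
    unname(nodeClusterings(x)[i])
}

#' Clustering coefficients of all nodes
#'
#' @param x A clean \code{InteractionNetwork}.
#' @return Named numeric vector (NA where degree < 2).
#' @export
nodeClusterings <- function(x) {
    .checkClean(x, "nodeClusterings")
    adj <- .adjacency(x)
    n <- length(adj)
    cc <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        nb <- adj[[i]]
        k <- length(nb)
        if (k < 2L) next
        # count edges among neighbors: for each neighbor, how many of its
        # own neighbors are also neighbors of i (each link counted twice)
        links2 <- 0L
        for (j in nb) links2 <- links2 + sum(adj[[j]] %in% nb)
        cc[i] <- links2 / (k * (k - 1))
    }
    names(cc) <- x@nodes
    cc
}

#' Mean clustering coefficient
#'
#' Arithmetic mean of the node clustering coefficients. By default only
#' nodes of degree >= 2 enter the average (the coefficient is undefined
#' below that); \code{countLowDegreeAsZero = TRUE} switches to the
#' alternative convention in which degree < 2 nodes contribute 0 and the
#' mean runs over all nodes.
#'
#' @param x A clean, non-empty \code{InteractionNetwork}.
#' @param countLowDegreeAsZero Convention flag, see above.
#' @return Numeric in [0, 1]; 0 when no node has degree >= 2.
#' @export
meanClustering <- function(x, countLowDegreeAsZero = FALSE) {
    if (length(x@nodes) == 0L)
        stop("meanClustering() needs a non-empty network")
    cc <- nodeClusterings(x)
    if (countLowDegreeAsZero) {
        cc[is.na(cc)] <- 0
        return(mean(cc))
    }
    cc <- cc[!is.na(cc)]
    if (length(cc) == 0L) return(0)
    mean(cc)
}

# BFS distances from one source; Inf where unreachable
.bfsDistances <- function(adj, s) {
    n <- length(adj)
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
        d <- d + 1
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[is.infinite(dist[nxt])]
        dist[nxt] <- d
        frontier <- nxt
    }
    dist
}

#' All-pairs shortest-path summary
#'
#' Breadth-first search from every node; distances are counted over ordered
#' pairs (n, m), n != m, so a connected component of c nodes contributes
#' c(c-1) finite pairs and the reachable percentage has denominator N(N-1).
#'
#' @param x A clean \code{InteractionNetwork} with at least two nodes.
#' @return A \code{\linkS4class{DistanceSummary}}.
#' @export
allPairsDistances <- function(x) {
    .checkClean(x, "allPairsDistances")
    n <- length(x@nodes)
    if (n < 2L) stop("allPairsDistances() needs at least two nodes")
    adj <- .adjacency(x)
    counts <- integer()
    for (s in seq_len(n)) {
        d <- .bfsDistances(adj, s)
        d <- d[is.finite(d) & d > 0]
        if (length(d)) {
            tab <- tabulate(d)
            if (length(tab) > length(counts))
                counts <- c(counts, integer(length(tab) - length(counts)))
            counts[seq_along(tab)] <- counts[seq_along(tab)] + tab
        }
    }
    finite <- sum(counts)
    hist <- counts
    names(hist) <- as.character(seq_along(hist))
    hist <- hist[hist > 0]
    cpl <- if (finite > 0)
        sum(as.integer(names(hist)) * hist) / finite else NA_real_
    diam <- if (finite > 0) max(as.integer(names(hist))) else NA_integer_
    new("DistanceSummary",
        finitePairCount = finite,
        percentOfAllPairs = finite / (n * (n - 1)),
        characteristicPathLength = cpl,
        diameter = as.integer(diam),
        histogram = hist)
}

#' Network diameter
#'
#' The longest of all finite shortest paths. NA when the network has no
#' connected pair at all.
#'
#' @param x A clean \code{InteractionNetwork} with at least two nodes.
#' @return Integer distance, or NA.
#' @export
networkDiameter <- function(x) {
    allPairsDistances(x)@diameter
}

#' Mean number of neighbors
#'
#' The mean degree, 2E/N for a clean network.
#'
#' @param x A clean, non-empty \code{InteractionNetwork}.
#' @return Numeric mean degree.
#' @export
avgNeighbors <- function(x) {
    .checkClean(x, "avgNeighbors")
    if (length(x@nodes) == 0L)
        stop("avgNeighbors() needs a non-empty network")
    2 * nrow(x@edges) / length(x@nodes)
}

#' Degree distribution
#'
#' Counts of nodes per degree value k >= 1; zero-degree nodes are tallied
#' separately because log(k) is undefined for them downstream in the
#' log-log power-law fit.
#'
#' @param x A clean \code{InteractionNetwork}.
#' @return A \code{data.frame} with columns \code{k} and \code{count},
#'   plus an attribute \code{nZeroDegree}.
#' @export
degreeDistribution <- function(x) {
    .checkClean(x, "degreeDistribution")
    d <- nodeDegrees(x)
    nz <- sum(d == 0L)
    d <- d[d > 0L]
    if (length(d)) {
        tab <- table(d)
        out <- data.frame(k = as.integer(names(tab)),
                          count = as.integer(tab))
    } else {
        out <- data.frame(k = integer(), count = integer())
    }
    attr(out, "nZeroDegree") <- as.integer(nz)
    out
}

#' Full topological summary of one network
#'
#' Assembles the standard whole-network parameter set (components, nodes,
#' edges, mean clustering, diameter, shortest-path statistics,
#' characteristic path length, mean neighbors) into a
#' \code{\linkS4class{TopologyReport}}.
#'
#' @param x A clean \code{InteractionNetwork} with at least two nodes.
#' @return A \code{TopologyReport}.
#' @examples
#' net <- cleanNetwork(Network("tri",
#'     edges = cbind(c("A", "B", "C"), c("B", "C", "A"))))
#' topologyReport(net)
#' @export
setMethod("topologyReport", "InteractionNetwork", function(x) {
    .checkClean(x, "topologyReport")
    ds <- allPairsDistances(x)
    new("TopologyReport",
        networkName = x@name,
        nComponents = length(connectedComponents(x)),
        nNodes = length(x@nodes),
        nEdges = nrow(x@edges),
        meanClustering = meanClustering(x),
        diameter = ds@diameter,
        distances = ds,
        characteristicPathLength = ds@characteristicPathLength,
        avgNeighbors = avgNeighbors(x))
})

setMethod("show", "DistanceSummary", function(object) {
    cat("DistanceSummary: ", object@finitePairCount, " finite ordered ",
        "pairs (", sprintf("%.0f%%", 100 * object@percentOfAllPairs),
        "), CPL ", sprintf("%.3f", object@characteristicPathLength),
        ", diameter ", object@diameter, "\n", sep = "")
    invisible(NULL)
})

setMethod("show", "TopologyReport", function(object) {
    cat("TopologyReport for \"", object@networkName, "\"\n", sep = "")
    df <- as.data.frame(object)
    for (nm in colnames(df))
        cat(sprintf("  %-28s %s\n", nm, as.character(df[[nm]])))
    invisible(NULL)
})

#' @describeIn topologyReport Serialize to a one-row data.frame with the
#'   conventional column names; numeric values rounded to three decimals.
#' @param row.names,optional,... Ignored; present for generic consistency.
#' @export
as.data.frame.TopologyReport <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    ds <- x@distances
    data.frame(
        network = x@networkName,
        connected_components = x@nComponents,
        n_nodes = x@nNodes,
        n_edges = x@nEdges,
        clustering_coefficient = round(x@meanClustering, 3L),
        network_diameter = ds@diameter,
        shortest_paths = ds@finitePairCount,
        shortest_paths_percent = round(100 * ds@percentOfAllPairs, 0L),
        characteristic_path_length =
            round(x@characteristicPathLength, 3L),
        avg_neighbors = round(x@avgNeighbors, 3L),
        stringsAsFactors = FALSE)
}
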