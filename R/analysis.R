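#' Identify network hubs
#'
#' Hubs are the nodes whose degree is at least one standard deviation above
#' the network's mean degree. The population (divide-by-N) standard
#' deviation is used by default, the node set being the entire population
#' rather than a sample; \code{sampleSD = TRUE} switches to the N-1
#' estimator. When every degree is equal the standard deviation is zero and
#' every node formally meets the threshold; the result is flagged and a
#' warning raised because "hub" is then uninformative.
#'
#' @param x A clean \code{InteractionNetwork} with at least two nodes.
#' @param sampleSD Use the sample (N-1) standard deviation instead of the
#'   population one.
#' @return A \code{\linkS4class{HubSet}}.
#' @examples
#' star <- cleanNetwork(Network("star",
#'     edges = cbind("hub", paste0("leaf", 1:10))))
#' identifyHubs(star)
#' @export
setMethod("identifyHubs", "InteractionNetwork",
          function(x, sampleSD = FALSE) {
    .checkClean(x, "identifyHubs")
    if (length(x@nodes) < 2L)
        stop("identifyHubs() needs at least two nodes")
    d <- nodeDegrees(x)
    m <- mean(d)
    s <- if (sampleSD) stats::sd(d)
         else sqrt(mean((d - m)^2))
    thr <- m + s
    degenerate <- s == 0
    if (degenerate)
        warning("all node degrees are equal (SD = 0): every node meets ",
                "the hub threshold; the hub set is uninformative")
    sel <- d >= thr
    hubs <- data.frame(node = names(d)[sel],
                       degree = unname(d[sel]),
                       stringsAsFactors = FALSE)
    hubs <- hubs[order(-hubs$degree, hubs$node), , drop = FALSE]
    rownames(hubs) <- NULL
    new("HubSet", networkName = x@name, meanDegree = m, sdDegree = s,
        threshold = thr, hubs = hubs, degenerate = degenerate)
})

setMethod("show", "HubSet", function(object) {
    cat("HubSet for \"", object@networkName, "\": mean degree ",
        sprintf("%.3f", object@meanDegree), ", SD ",
        sprintf("%.3f", object@sdDegree), ", threshold ",
        sprintf("%.3f", object@threshold),
        if (object@degenerate) " (degenerate: all degrees equal)" else "",
        "\n", sep = "")
    if (nrow(object@hubs)) {
        cat("  ", nrow(object@hubs), " hub(s): ",
            paste(sprintf("%s (%d)", object@hubs$node,
                          object@hubs$degree), collapse = ", "),
            "\n", sep = "")
    } else cat("  no hubs\n")
    invisible(NULL)
})

#' Hub labels of a hub set
#'
#' @param hubSet A \code{\linkS4class{HubSet}}.
#' @return Character vector of hub node labels.
#' @export
hubLabels <- function(hubSet) hubSet@hubs$node

#' Classify a topology-evidence vector
#'
#' The pure decision rule behind \code{\link{classifyTopology}}: the label
#' depends on the evidence values only. A network is
#' \code{"hierarchical"} when its mean clustering coefficient is at least
#' \code{clusteringMin} and the degree-vs-clustering correlation satisfies
#' |r| >= \code{corMin} (high clustering that decays with degree);
#' \code{"scale_free_BA"} when the degree-distribution exponent is
#' negative, the log-log fit has R^2 >= \code{r2Min} and mean clustering is
#' below \code{clusteringMin} (power-law degrees with the near-zero
#' clustering of preferential-attachment growth); anything else is
#' \code{"indeterminate"}. Mean clustering is the primary separator; the
#' correlation alone cannot discriminate, since sparse scale-free networks
#' can show sizable degree-clustering correlations.
#'
#' @param evidence Named numeric vector with (at least) entries
#'   \code{gamma}, \code{r_squared} (degree fit), \code{mean_clustering}
#'   and \code{degree_cc_r}; NA entries mark failed fits.
#' @param clusteringMin,corMin,r2Min Decision thresholds (defaults 0.3,
#'   0.5, 0.5).
#' @return Character label.
#' @export
classifyEvidence <- function(evidence, clusteringMin = 0.3, corMin = 0.5,
                             r2Min = 0.5) {
    g <- evidence[["gamma"]]
    r2 <- evidence[["r_squared"]]
    cc <- evidence[["mean_clustering"]]
    r <- evidence[["degree_cc_r"]]
    if (!is.na(cc) && cc >= clusteringMin && !is.na(r) &&
        abs(r) >= corMin)
        return("hierarchical")
    if (!is.na(g) && g < 0 && !is.na(r2) && r2 >= r2Min &&
        !is.na(cc) && cc < clusteringMin)
        return("scale_free_BA")
    "indeterminate"
}

#' Classify a network's topology
#'
#' Computes the evidence vector -- degree-distribution power-law fit
#' (gamma, R^2), mean clustering coefficient, degree-vs-clustering
#' correlation r, characteristic path length, mean neighbors and
#' reachable-pair fraction -- and applies \code{\link{classifyEvidence}}.
#' Failed fits (e.g. on networks too small or too regular to fit) yield an
#' indeterminate label with the failure recorded in \code{reason}.
#'
#' The small-world annotation is a documented heuristic, not a formal test:
#' a network is flagged small-world when its characteristic path length is
#' at most \code{smallWorldFactor * ln(N) / ln(<k>)} (the random-graph
#' path-length scale) and at least \code{minReachability} of all ordered
#' pairs are connected.
#'
#' @param x A clean \code{InteractionNetwork}.
#' @param clusteringMin,corMin,r2Min Thresholds passed to
#'   \code{\link{classifyEvidence}}.
#' @param smallWorldFactor,minReachability Small-world heuristic
#'   parameters.
#' @return A \code{\linkS4class{TopologyClass}}.
#' @export
setMethod("classifyTopology", "InteractionNetwork",
          function(x, clusteringMin = 0.3, corMin = 0.5, r2Min = 0.5,
                   smallWorldFactor = 1.5, minReachability = 0.9) {
    .checkClean(x, "classifyTopology")
    n <- length(x@nodes)
    reason <- character()
    if (n < 2L) {
        return(new("TopologyClass", label = "indeterminate",
                   smallWorld = FALSE, evidence = numeric(),
                   reason = "fewer than two nodes"))
    }
    degFit <- tryCatch(fitDegreeDistribution(x), error = function(e) {
        reason <<- c(reason, paste("degree fit:", conditionMessage(e)))
        NULL
    })
    ccFit <- tryCatch(fitDegreeVsClustering(x), error = function(e) {
        reason <<- c(reason,
                     paste("degree-clustering fit:", conditionMessage(e)))
        NULL
    })
    ds <- allPairsDistances(x)
    avgN <- avgNeighbors(x)
    evidence <- c(
        gamma = if (is.null(degFit)) NA_real_ else degFit@gamma,
        r_squared = if (is.null(degFit)) NA_real_ else degFit@rSquared,
        mean_clustering = meanClustering(x),
        degree_cc_r = if (is.null(ccFit)) NA_real_ else ccFit@r,
        cpl = ds@characteristicPathLength,
        avg_neighbors = avgN,
        reachability = ds@percentOfAllPairs,
        n_nodes = n)
    label <- classifyEvidence(evidence, clusteringMin = clusteringMin,
                              corMin = corMin, r2Min = r2Min)
    sw <- !is.na(ds@characteristicPathLength) && avgN > 1 &&
        ds@characteristicPathLength <=
            smallWorldFactor * log(n) / log(avgN) &&
        ds@percentOfAllPairs >= minReachability
    new("TopologyClass", label = label, smallWorld = sw,
        evidence = evidence,
        reason = if (length(reason)) paste(reason, collapse = "; ")
                 else NA_character_)
})

setMethod("show", "TopologyClass", function(object) {
    cat("TopologyClass: ", object@label,
        if (isTRUE(object@smallWorld)) " (small-world)" else "",
        "\n", sep = "")
    if (length(object@evidence)) {
        ev <- object@evidence
        cat("  evidence: ",
            paste(sprintf("%s=%.3f", names(ev), ev), collapse = ", "),
            "\n", sep = "")
    }
    if (!is.na(object@reason))
        cat("  note: ", object@reason, "\n", sep = "")
    invisible(NULL)
})
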