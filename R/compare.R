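#' Venn-region partition of up to five label sets
#'
#' Partitions the union of the given sets into the 2^k - 1 exclusive Venn
#' regions (every element lands in exactly one region, the one named by
#' the sets that contain it). Comparison is case-insensitive by default --
#' "ACTIN" and "Actin" are the same label, with the first-seen casing
#' preserved in the output -- which matches how hub labels from different
#' curation tools must be merged. More than five sets are rejected (the
#' practical limit of the classical Venn layout).
#'
#' @param sets Named list of 1 to 5 character vectors. Unnamed lists get
#'   names \code{set1}, \code{set2}, ...
#' @param caseInsensitive Fold case when comparing labels (default TRUE).
#' @return Named list mapping each region (set names joined by \code{"&"})
#'   to the sorted member labels; empty regions are present with
#'   zero-length members.
#' @examples
#' vennRegions(list(A = c("actin", "PKA"), B = c("ACTIN", "RHOA")))
#' @export
vennRegions <- function(sets, caseInsensitive = TRUE) {
    if (!is.list(sets) || length(sets) < 1L)
        stop("'sets' must be a non-empty list")
    if (length(sets) > 5L)
        stop("at most five sets are supported")
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("set", seq_along(sets))
    if (anyDuplicated(names(sets)))
        stop("set names must be unique")
    sets <- lapply(sets, function(s) unique(.trim(as.character(s))))
    norm <- if (caseInsensitive) tolower else identity
    allLabs <- unlist(sets, use.names = FALSE)
    allNorm <- norm(allLabs)
    display <- allLabs[!duplicated(allNorm)]
    names(display) <- allNorm[!duplicated(allNorm)]
    universe <- names(display)
    member <- vapply(sets, function(s) universe %in% norm(s),
                     logical(length(universe)))
    if (length(universe) == 1L)
        member <- matrix(member, nrow = 1L,
                         dimnames = list(NULL, names(sets)))
    k <- length(sets)
    regions <- list()
    for (mask in seq_len(2^k - 1L)) {
        inSet <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
        regionName <- paste(names(sets)[inSet], collapse = "&")
        if (length(universe)) {
            hit <- apply(member, 1L, function(rw) all(rw == inSet))
            regions[[regionName]] <- sort(unname(display[hit]))
        } else {
            regions[[regionName]] <- character()
        }
    }
    regions
}

#' Compare several networks
#'
#' Runs the full per-network pipeline -- topological summary, degree
#' power-law fit, degree-vs-clustering fit, hub identification and
#' topology classification -- over a list of clean networks, assembles the
#' tabular views, and (for two to five networks) the exclusive Venn
#' partitions of node labels and of hub labels. Individual fit failures
#' (networks too small or too regular to fit) are recorded per network
#' rather than aborting the comparison.
#'
#' @param nets List of clean \code{InteractionNetwork} objects with
#'   distinct names.
#' @param mainComponents If TRUE, an \code{MC_<name>} main-component
#'   variant is appended for every network with more than one component.
#' @param stoplist Optional character vector of node labels stripped from
#'   every network (with \code{\link{removeNodes}}) before analysis.
#' @param clusteringMin,corMin,r2Min Classification thresholds, see
#'   \code{\link{classifyEvidence}}.
#' @return A \code{\linkS4class{ComparisonReport}}.
#' @export
runComparison <- function(nets, mainComponents = FALSE, stoplist = NULL,
                          clusteringMin = 0.3, corMin = 0.5,
                          r2Min = 0.5) {
    if (!is.list(nets) || length(nets) < 1L)
        stop("'nets' must be a non-empty list of networks")
    nms <- vapply(nets, networkName, character(1L))
    if (anyDuplicated(nms))
        stop("duplicate network names: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    if (!is.null(stoplist))
        nets <- lapply(nets, removeNodes, stoplist = stoplist)
    if (mainComponents) {
        extra <- list()
        for (net in nets) {
            if (length(connectedComponents(net)) > 1L)
                extra[[length(extra) + 1L]] <- mainComponent(net)
        }
        nets <- c(nets, extra)
        nms <- vapply(nets, networkName, character(1L))
    }
    names(nets) <- nms
    per <- vector("list", length(nets))
    names(per) <- nms
    for (nm in nms) {
        net <- nets[[nm]]
        degFit <- tryCatch(fitDegreeDistribution(net),
                           error = function(e) conditionMessage(e))
        ccFit <- tryCatch(fitDegreeVsClustering(net),
                          error = function(e) conditionMessage(e))
        per[[nm]] <- list(
            report = topologyReport(net),
            degreeFit = if (is(degFit, "PowerLawFit")) degFit else NULL,
            degreeFitError = if (is.character(degFit)) degFit
                             else NA_character_,
            clusteringFit = if (is(ccFit, "PowerLawFit")) ccFit
                            else NULL,
            clusteringFitError = if (is.character(ccFit)) ccFit
                                 else NA_character_,
            hubs = suppressWarnings(identifyHubs(net)),
            class = classifyTopology(net, clusteringMin = clusteringMin,
                                     corMin = corMin, r2Min = r2Min))
    }
    topoTab <- do.call(rbind, lapply(per, function(p)
        as.data.frame(p$report)))
    rownames(topoTab) <- NULL
    fitRow <- function(fit, nm) {
        if (is.null(fit))
            return(data.frame(network = nm, gamma = NA_real_,
                              r = NA_real_, r_squared = NA_real_,
                              n_points = NA_integer_,
                              stringsAsFactors = FALSE))
        cbind(data.frame(network = nm, stringsAsFactors = FALSE),
              as.data.frame(fit)[, c("gamma", "r", "r_squared",
                                     "n_points")])
    }
    degTab <- do.call(rbind, lapply(nms, function(nm)
        fitRow(per[[nm]]$degreeFit, nm)))
    ccTab <- do.call(rbind, lapply(nms, function(nm)
        fitRow(per[[nm]]$clusteringFit, nm)))
    rownames(degTab) <- rownames(ccTab) <- NULL
    nodeOv <- list(); hubOv <- list()
    if (length(nets) <= 5L) {
        nodeOv <- vennRegions(lapply(nets, nodes))
        hubOv <- vennRegions(lapply(per, function(p) hubLabels(p$hubs)))
    } else if (length(nets) > 5L) {
        .log("runComparison: overlap partitions skipped (more than five ",
             "networks)")
    }
    new("ComparisonReport", perNetwork = per, topologyTable = topoTab,
        degreeFitTable = degTab, clusteringFitTable = ccTab,
        nodeOverlap = nodeOv, hubOverlap = hubOv)
}

setMethod("show", "ComparisonReport", function(object) {
    cat("ComparisonReport over", length(object@perNetwork),
        "network(s)\n")
    print(object@topologyTable)
    cat("\nDegree-distribution fits:\n")
    print(object@degreeFitTable)
    cat("\nDegree-vs-clustering fits:\n")
    print(object@clusteringFitTable)
    cat("\nTopology classes:\n")
    for (nm in names(object@perNetwork))
        cat(sprintf("  %-24s %s\n", nm,
                    object@perNetwork[[nm]]$class@label))
    invisible(NULL)
})

#' Export a comparison report
#'
#' Writes the three tabular views as CSV files and the full report
#' (tables, hub sets, topology classes, overlap partitions) as one JSON
#' bundle, into a directory.
#'
#' @param report A \code{\linkS4class{ComparisonReport}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
exportComparison <- function(report, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
        topology = file.path(dir, "topology.csv"),
        degree_fits = file.path(dir, "degree_fits.csv"),
        clustering_fits = file.path(dir, "clustering_fits.csv"),
        bundle = file.path(dir, "comparison.json"))
    utils::write.csv(report@topologyTable, paths[["topology"]],
                     row.names = FALSE)
    utils::write.csv(report@degreeFitTable, paths[["degree_fits"]],
                     row.names = FALSE)
    utils::write.csv(report@clusteringFitTable,
                     paths[["clustering_fits"]], row.names = FALSE)
    bundle <- list(
        topology = report@topologyTable,
        degree_fits = report@degreeFitTable,
        clustering_fits = report@clusteringFitTable,
        hubs = lapply(report@perNetwork, function(p) p$hubs@hubs),
        classes = lapply(report@perNetwork, function(p)
            list(label = p$class@label,
                 small_world = p$class@smallWorld,
                 evidence = as.list(p$class@evidence))),
        node_overlap = report@nodeOverlap,
        hub_overlap = report@hubOverlap)
    jsonlite::write_json(bundle, paths[["bundle"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}
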