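#' Construct an interaction network
#'
#' Builds an \code{\linkS4class{InteractionNetwork}} from node labels and an
#' edge table. Labels are trimmed of leading/trailing whitespace; endpoints
#' that do not appear in \code{nodes} are added automatically, so the node
#' set is always the union of declared nodes and edge endpoints. Edges are
#' stored exactly as given -- self-loops and duplicates included -- because
#' cleaning is an explicit pipeline step.
#'
#' @param name Single string naming the network.
#' @param nodes Character vector of node labels (may be empty; isolated
#'   nodes are declared here).
#' @param edges Two-column character matrix or data.frame of endpoints, or
#'   NULL for an edgeless network.
#' @param edgeData Optional \code{data.frame} of per-edge annotation, one
#'   row per edge.
#' @return An \code{InteractionNetwork}.
#' @examples
#' net <- Network("toy", edges = cbind(c("A", "B"), c("B", "C")))
#' numNodes(net)
#' @export
Network <- function(name, nodes = character(), edges = NULL,
                    edgeData = NULL) {
    nodes <- .trim(as.character(nodes))
    if (is.null(edges)) {
        em <- matrix(character(), ncol = 2L)
    } else {
        if (is.data.frame(edges)) edges <- as.matrix(edges)
        if (length(edges) == 0L) {
            em <- matrix(character(), ncol = 2L)
        } else {
            if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L,
                                                     byrow = TRUE)
            em <- matrix(.trim(as.character(edges)), ncol = 2L,
                         dimnames = NULL)
        }
    }
    allNodes <- unique(c(nodes, as.vector(em)))
    allNodes <- allNodes[nzchar(allNodes)]
    if (is.null(edgeData)) {
        edgeData <- data.frame(matrix(nrow = nrow(em), ncol = 0L))
    } else {
        edgeData <- as.data.frame(edgeData, stringsAsFactors = FALSE)
        rownames(edgeData) <- NULL
    }
    new("InteractionNetwork", name = as.character(name)[1L],
        nodes = allNodes, edges = em, edgeData = edgeData)
}

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkName", "InteractionNetwork", function(x) x@name)

#' @rdname InteractionNetwork-class
#' @export
setReplaceMethod("networkName", "InteractionNetwork", function(x, value) {
    x@name <- as.character(value)[1L]
    validObject(x)
    x
})

#' @rdname InteractionNetwork-class
#' @export
setMethod("nodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname InteractionNetwork-class
#' @export
setMethod("edges", "InteractionNetwork", function(x) x@edges)

#' @rdname InteractionNetwork-class
#' @export
setMethod("edgeData", "InteractionNetwork", function(x) x@edgeData)

#' @rdname InteractionNetwork-class
#' @export
setMethod("numNodes", "InteractionNetwork", function(x) length(x@nodes))

#' @rdname InteractionNetwork-class
#' @export
setMethod("numEdges", "InteractionNetwork", function(x) nrow(x@edges))

#' Is a network clean?
#'
#' A network is clean when it has no self-loops and each unordered node pair
#' appears at most once.
#'
#' @param x An \code{InteractionNetwork}.
#' @return Logical scalar.
#' @export
setMethod("isClean", "InteractionNetwork", function(x) {
    if (nrow(x@edges) == 0L) return(TRUE)
    if (any(x@edges[, 1L] == x@edges[, 2L])) return(FALSE)
    !anyDuplicated(.pairKeys(x@edges))
})

# canonical "a||b" keys for unordered pairs
.pairKeys <- function(em) {
    a <- pmin(em[, 1L], em[, 2L])
    b <- pmax(em[, 1L], em[, 2L])
    paste(a, b, sep = "\r")
}

#' Canonical edge matrix
#'
#' Endpoints sorted within each edge and rows sorted lexicographically;
#' duplicates are NOT collapsed (use \code{\link{cleanNetwork}} for that).
#' Useful for order-independent comparison and diff-stable output.
#'
#' @param x An \code{InteractionNetwork}.
#' @return Two-column character matrix.
#' @export
canonicalEdges <- function(x) {
    em <- x@edges
    if (nrow(em) == 0L) return(em)
    a <- pmin(em[, 1L], em[, 2L])
    b <- pmax(em[, 1L], em[, 2L])
    o <- order(a, b)
    cbind(a, b, deparse.level = 0L)[o, , drop = FALSE]
}

#' Topological equality of two networks
#'
#' TRUE when the two networks have the same node set and the same set of
#' distinct unordered edges (names and annotations are ignored).
#'
#' @param a,b \code{InteractionNetwork} objects.
#' @return Logical scalar.
#' @export
sameTopology <- function(a, b) {
    setequal(nodes(a), nodes(b)) &&
        setequal(unique(.pairKeys2(a)), unique(.pairKeys2(b)))
}

.pairKeys2 <- function(net) {
    em <- net@edges
    if (nrow(em) == 0L) return(character())
    keep <- em[, 1L] != em[, 2L]
    if (!any(keep)) return(character())
    .pairKeys(em[keep, , drop = FALSE])
}

# integer adjacency list for a clean network: index -> sorted neighbor indices
.adjacency <- function(net) {
    n <- length(net@nodes)
    adj <- vector("list", n)
    for (i in seq_len(n)) adj[[i]] <- integer()
    if (nrow(net@edges)) {
        ia <- match(net@edges[, 1L], net@nodes)
        ib <- match(net@edges[, 2L], net@nodes)
        for (k in seq_along(ia)) {
            if (ia[k] != ib[k]) {
                adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
                adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
            }
        }
        adj <- lapply(adj, function(v) sort(unique(v)))
    }
    adj
}

setMethod("show", "InteractionNetwork", function(object) {
    cat("InteractionNetwork \"", object@name, "\"\n", sep = "")
    cat("  nodes: ", length(object@nodes), "   edges: ",
        nrow(object@edges),
        if (isClean(object)) "  (clean)" else "  (not clean)", "\n",
        sep = "")
    if (length(object@nodes)) {
        shown <- utils::head(sort(object@nodes), 6L)
        cat("  labels: ", paste(shown, collapse = ", "),
            if (length(object@nodes) > 6L) ", ..." else "", "\n", sep = "")
    }
    if (ncol(object@edgeData))
        cat("  edge annotation: ",
            paste(colnames(object@edgeData), collapse = ", "), "\n",
            sep = "")
    invisible(NULL)
})
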