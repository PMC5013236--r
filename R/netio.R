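#' Read a tab-separated edge list
#'
#' One edge per line, \code{node_a<delimiter>node_b}; extra fields are
#' ignored. Lines starting with \code{#} are comments; a single-field line
#' declares an isolated node. Duplicate lines and self-loops are preserved
#' as given -- cleaning is a separate explicit step.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default tab).
#' @param name Network name; defaults to the file name without extension.
#' @return An \code{\linkS4class{InteractionNetwork}}.
#' @seealso \code{\link{writeEdgeList}}, \code{\link{cleanNetwork}}
#' @export
readEdgeList <- function(path, delimiter = "\t", name = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    nodes <- character()
    from <- character(); to <- character()
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (ln == "" || grepl("^\\s*#", ln)) next
        fields <- .trim(strsplit(ln, delimiter, fixed = TRUE)[[1L]])
        fields <- fields[nzchar(fields)]
        if (length(fields) == 0L)
            stop("parse error at line ", i, ": no fields")
        if (length(fields) == 1L) {
            nodes <- c(nodes, fields)
        } else {
            from <- c(from, fields[1L])
            to <- c(to, fields[2L])
        }
    }
    Network(name, nodes = nodes, edges = cbind(from, to))
}

#' Read a Cytoscape SIF file
#'
#' Each line is either a single node label (an isolated node) or
#' \code{node relation node [node ...]}, whitespace- or tab-delimited; one
#' edge is created between the first node and each trailing node. The
#' relation label is kept as per-edge annotation but plays no role in
#' topology (all networks are undirected).
#'
#' @inheritParams readEdgeList
#' @return An \code{\linkS4class{InteractionNetwork}} with a
#'   \code{relation} annotation column.
#' @export
readSIF <- function(path, name = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    nodes <- character()
    from <- character(); to <- character(); rel <- character()
    for (i in seq_along(lines)) {
        ln <- .trim(lines[i])
        if (ln == "" || startsWith(ln, "#")) next
        tok <- strsplit(ln, "[ \t]+")[[1L]]
        if (length(tok) == 1L) {
            nodes <- c(nodes, tok)
        } else if (length(tok) == 2L) {
            stop("parse error at line ", i,
                 ": relation without a target node")
        } else {
            targets <- tok[-(1:2)]
            from <- c(from, rep(tok[1L], length(targets)))
            to <- c(to, targets)
            rel <- c(rel, rep(tok[2L], length(targets)))
        }
    }
    ed <- if (length(rel)) data.frame(relation = rel,
                                      stringsAsFactors = FALSE) else NULL
    Network(name, nodes = nodes, edges = cbind(from, to), edgeData = ed)
}

#' Read a curated interaction table
#'
#' Imports a curated interaction database: a delimited table (TSV or CSV,
#' chosen from the file extension unless \code{sep} is given) whose header
#' names at least the columns \emph{Source molecule}, \emph{Interaction}
#' and \emph{Target molecule} (matched case-insensitively, ignoring
#' punctuation). One undirected edge is created per record; the
#' Interaction, Alias, Role, Reference and Notes columns, where present,
#' are retained as per-edge annotation and never create direction.
#'
#' @inheritParams readEdgeList
#' @param sep Field separator; default \code{","} for \code{.csv}, tab
#'   otherwise.
#' @return An \code{\linkS4class{InteractionNetwork}}.
#' @export
readInteractionTable <- function(path, sep = NULL, name = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "", colClasses = "character")
    norm <- function(x) gsub(" +", " ",
                             .trim(gsub("[^a-z0-9]+", " ", tolower(x))))
    hdr <- norm(colnames(tab))
    need <- c("source molecule", "interaction", "target molecule")
    miss <- setdiff(need, hdr)
    if (length(miss))
        stop("schema error: missing column(s): ",
             paste(miss, collapse = ", "))
    col <- function(key) tab[[which(hdr == key)[1L]]]
    src <- .trim(col("source molecule"))
    tgt <- .trim(col("target molecule"))
    bad <- which(!nzchar(src) | !nzchar(tgt))
    if (length(bad))
        stop("parse error: empty source or target molecule at row ",
             bad[1L])
    optional <- c(interaction = "interaction", alias = "alias",
                  role = "role", reference = "reference", notes = "notes")
    ed <- data.frame(row.names = seq_along(src))
    for (nm in names(optional)) {
        if (optional[[nm]] %in% hdr) ed[[nm]] <- col(optional[[nm]])
    }
    Network(name, edges = cbind(src, tgt), edgeData = ed)
}

#' Read a node stoplist
#'
#' Plain text, one node label per line, \code{#} comments allowed. Used to
#' strip nonspecific nodes (e.g. "spermatozoa", "membrane", "in vitro")
#' that literature-mining tools introduce into interaction networks.
#'
#' @param path Path to the stoplist file.
#' @return Character vector of trimmed labels.
#' @export
readStoplist <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- .trim(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    unique(lines)
}

#' Remove self-loops and duplicate edges
#'
#' Drops every self-loop and collapses each unordered node pair to a single
#' edge. The node set is unchanged: nodes isolated by loop removal remain
#' (they still count towards the network's node total). Annotation values
#' of collapsed duplicates are merged per column, distinct non-empty values
#' joined by \code{"; "}. Idempotent.
#'
#' @param x An \code{InteractionNetwork}.
#' @return A clean \code{InteractionNetwork} with the same name and nodes.
#' @export
setMethod("cleanNetwork", "InteractionNetwork", function(x) {
    em <- x@edges
    if (nrow(em) == 0L) return(x)
    keep <- em[, 1L] != em[, 2L]
    nLoops <- sum(!keep)
    em <- em[keep, , drop = FALSE]
    ed <- x@edgeData[keep, , drop = FALSE]
    if (nrow(em)) {
        keys <- .pairKeys(em)
        first <- !duplicated(keys)
        nDup <- sum(!first)
        if (nDup > 0L && ncol(ed) > 0L) {
            agg <- function(v) {
                u <- unique(v[nzchar(.trim(v))])
                paste(u, collapse = "; ")
            }
            byKey <- split(seq_along(keys), keys)
            ukeys <- keys[first]
            ed <- as.data.frame(
                lapply(ed, function(colv)
                    vapply(byKey[ukeys],
                           function(ix) agg(colv[ix]), character(1L),
                           USE.NAMES = FALSE)),
                stringsAsFactors = FALSE)
            rownames(ed) <- NULL
        } else {
            ed <- ed[first, , drop = FALSE]
            rownames(ed) <- NULL
        }
        em <- em[first, , drop = FALSE]
        if (nLoops || nDup)
            .log("cleanNetwork(", x@name, "): removed ", nLoops,
                 " self-loop(s), ", nDup, " duplicate edge(s)")
    } else if (nLoops) {
        ed <- ed[integer(), , drop = FALSE]
        .log("cleanNetwork(", x@name, "): removed ", nLoops,
             " self-loop(s)")
    }
    initialize(x, edges = em, edgeData = ed)
})

#' Merge several networks into one
#'
#' Node set is the union of the node sets; edge set is the union of the
#' cleaned edge sets. The result is clean, and the operation is
#' order-independent and idempotent.
#'
#' @param nets List of \code{InteractionNetwork} objects (at least one).
#' @param name Name for the merged network; defaults to the input names
#'   joined by \code{"+"}.
#' @return A clean \code{InteractionNetwork}.
#' @export
mergeNetworks <- function(nets, name = NULL) {
    if (!is.list(nets) || length(nets) == 0L)
        stop("'nets' must be a non-empty list of networks")
    nets <- lapply(nets, cleanNetwork)
    if (is.null(name))
        name <- paste(vapply(nets, networkName, character(1L)),
                      collapse = "+")
    allNodes <- unique(unlist(lapply(nets, nodes)))
    em <- do.call(rbind, lapply(nets, edges))
    cols <- unique(unlist(lapply(nets, function(n) colnames(edgeData(n)))))
    ed <- NULL
    if (length(cols)) {
        ed <- do.call(rbind, lapply(nets, function(n) {
            d <- edgeData(n)
            for (cc in setdiff(cols, colnames(d))) d[[cc]] <- ""
            d[, cols, drop = FALSE]
        }))
    }
    cleanNetwork(Network(name, nodes = allNodes, edges = em, edgeData = ed))
}

#' Remove stoplisted nodes
#'
#' Removes every node whose label matches a stoplist term exactly (after
#' whitespace trimming; matching is never substring-based, so filtering
#' "membrane" does not remove "membrane receptor"), together with all
#' incident edges. Terms absent from the network are ignored and logged.
#'
#' @param x A clean \code{InteractionNetwork}.
#' @param stoplist Character vector of labels to remove (e.g. from
#'   \code{\link{readStoplist}}).
#' @param dropIsolated If TRUE, nodes left with no edges after filtering
#'   are dropped as well; by default they are kept and still count in node
#'   totals.
#' @return The filtered \code{InteractionNetwork}.
#' @export
removeNodes <- function(x, stoplist, dropIsolated = FALSE) {
    .checkClean(x, "removeNodes")
    terms <- unique(.trim(as.character(stoplist)))
    hit <- terms[terms %in% x@nodes]
    absent <- setdiff(terms, hit)
    if (length(absent))
        .log("removeNodes(", x@name, "): ", length(absent),
             " stoplist term(s) not present in the network")
    .log("removeNodes(", x@name, "): removing ", length(hit), " node(s)")
    keepNodes <- setdiff(x@nodes, hit)
    em <- x@edges
    keepE <- !(em[, 1L] %in% hit) & !(em[, 2L] %in% hit)
    em <- em[keepE, , drop = FALSE]
    ed <- x@edgeData[keepE, , drop = FALSE]
    rownames(ed) <- NULL
    if (dropIsolated) {
        connected <- unique(as.vector(em))
        dropped <- setdiff(keepNodes, connected)
        if (length(dropped))
            .log("removeNodes(", x@name, "): dropping ", length(dropped),
                 " isolated node(s)")
        keepNodes <- intersect(keepNodes, connected)
    }
    initialize(x, nodes = keepNodes, edges = em, edgeData = ed)
}

#' Connected components of a network
#'
#' Partitions the node set into maximal connected subgraphs, returned as a
#' list of networks sorted by node count (largest first), with ties broken
#' by the lexicographically smallest member label so output order is
#' deterministic.
#'
#' @param x A clean \code{InteractionNetwork}.
#' @return List of \code{InteractionNetwork} components (empty for an
#'   empty network).
#' @export
setMethod("connectedComponents", "InteractionNetwork", function(x) {
    .checkClean(x, "connectedComponents")
    n <- length(x@nodes)
    if (n == 0L) return(list())
    adj <- .adjacency(x)
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (comp[s] != 0L) next
        cur <- cur + 1L
        frontier <- s
        comp[s] <- cur
        while (length(frontier)) {
            nxt <- unique(unlist(adj[frontier]))
            nxt <- nxt[comp[nxt] == 0L]
            comp[nxt] <- cur
            frontier <- nxt
        }
    }
    groups <- split(seq_len(n), comp)
    sizes <- lengths(groups)
    minLab <- vapply(groups, function(ix) min(x@nodes[ix]), character(1L))
    ord <- order(-sizes, minLab)
    groups <- groups[ord]
    out <- vector("list", length(groups))
    for (i in seq_along(groups)) {
        members <- x@nodes[groups[[i]]]
        keepE <- x@edges[, 1L] %in% members
        ed <- x@edgeData[keepE, , drop = FALSE]
        rownames(ed) <- NULL
        out[[i]] <- initialize(x,
            name = sprintf("%s_c%d", x@name, i),
            nodes = members,
            edges = x@edges[keepE, , drop = FALSE],
            edgeData = ed)
    }
    out
})

#' Main connected component
#'
#' Returns the component with the most nodes (ties broken by smallest
#' member label), renamed \code{MC_<name>} following the usual convention
#' for main-component networks.
#'
#' @param x A non-empty clean \code{InteractionNetwork}.
#' @return An \code{InteractionNetwork}.
#' @export
setMethod("mainComponent", "InteractionNetwork", function(x) {
    if (length(x@nodes) == 0L)
        stop("mainComponent() needs a non-empty network")
    comp <- connectedComponents(x)[[1L]]
    comp@name <- paste0("MC_", x@name)
    comp
})

#' Write a network as an edge list / SIF file
#'
#' Output is deterministic: edges are written with endpoints sorted within
#' each pair and rows sorted lexicographically, followed by isolated nodes
#' as single-field lines, so files are diff-stable and write-then-read is
#' the identity. \code{writeSIF} uses the stored \code{relation} annotation
#' where available and \code{"pp"} otherwise.
#'
#' @param x A clean \code{InteractionNetwork}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writeEdgeList <- function(x, path) {
    .checkClean(x, "writeEdgeList")
    em <- canonicalEdges(x)
    lines <- if (nrow(em)) paste(em[, 1L], em[, 2L], sep = "\t")
             else character()
    isolated <- sort(setdiff(x@nodes, as.vector(em)))
    writeLines(c(lines, isolated), path)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeSIF <- function(x, path) {
    .checkClean(x, "writeSIF")
    em <- x@edges
    rel <- rep("pp", nrow(em))
    if ("relation" %in% colnames(x@edgeData)) {
        r <- x@edgeData$relation
        # relation labels are single SIF tokens: no internal whitespace
        r <- gsub("[ \t]+", "_", .trim(r))
        rel[nzchar(r)] <- r[nzchar(r)]
    }
    a <- pmin(em[, 1L], em[, 2L])
    b <- pmax(em[, 1L], em[, 2L])
    o <- order(a, b)
    lines <- if (nrow(em)) paste(a[o], rel[o], b[o], sep = "\t")
             else character()
    isolated <- sort(setdiff(x@nodes, as.vector(em)))
    writeLines(c(lines, isolated), path)
    invisible(path)
}
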