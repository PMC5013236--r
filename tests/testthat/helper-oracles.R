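# Independent brute-force oracles and fixture builders for the test suite.
# These deliberately avoid the package's own metric code paths.

# random clean undirected graph built by direct pair sampling
randomNetwork <- function(n, p = 0.15, name = "rand") {
    labels <- sprintf("r%02d", seq_len(n))
    pairs <- t(combn(n, 2L))
    pick <- runif(nrow(pairs)) < p
    Network(name, nodes = labels,
            edges = cbind(labels[pairs[pick, 1L]],
                          labels[pairs[pick, 2L]]))
}

# raw multigraph with planted self-loops and duplicate edges
randomMultigraph <- function(n, nEdges = 2L * n, name = "multi") {
    labels <- sprintf("m%02d", seq_len(n))
    a <- sample(labels, nEdges, replace = TRUE)
    b <- sample(labels, nEdges, replace = TRUE)
    Network(name, nodes = labels, edges = cbind(a, b))
}

# deterministic clean graph with exactly n nodes and e edges
fixedSizeNetwork <- function(n, e, name = sprintf("g_%d_%d", n, e)) {
    stopifnot(e <= choose(n, 2L))
    labels <- sprintf("f%03d", seq_len(n))
    pairs <- t(combn(n, 2L))[seq_len(e), , drop = FALSE]
    Network(name, nodes = labels,
            edges = cbind(labels[pairs[, 1L]], labels[pairs[, 2L]]))
}

# exhaustive count of distinct non-loop unordered pairs in a raw edge matrix
bruteDistinctPairs <- function(net) {
    em <- edges(net)
    if (nrow(em) == 0L) return(0L)
    keep <- em[, 1L] != em[, 2L]
    em <- em[keep, , drop = FALSE]
    length(unique(paste(pmin(em[, 1L], em[, 2L]),
                        pmax(em[, 1L], em[, 2L]))))
}

# clustering by exhaustive enumeration of neighbor pairs
bruteClustering <- function(net, node) {
    em <- edges(net)
    nb <- unique(c(em[em[, 1L] == node, 2L], em[em[, 2L] == node, 1L]))
    nb <- setdiff(nb, node)
    k <- length(nb)
    if (k < 2L) return(NA_real_)
    links <- 0L
    prs <- combn(sort(nb), 2L)
    for (j in seq_len(ncol(prs))) {
        u <- prs[1L, j]; v <- prs[2L, j]
        if (any((em[, 1L] == u & em[, 2L] == v) |
                (em[, 1L] == v & em[, 2L] == u)))
            links <- links + 1L
    }
    2 * links / (k * (k - 1))
}

# Floyd-Warshall all-pairs distance matrix (Inf = unreachable)
floydWarshall <- function(net) {
    labs <- nodes(net)
    n <- length(labs)
    d <- matrix(Inf, n, n, dimnames = list(labs, labs))
    diag(d) <- 0
    em <- edges(net)
    for (i in seq_len(nrow(em))) {
        d[em[i, 1L], em[i, 2L]] <- 1
        d[em[i, 2L], em[i, 1L]] <- 1
    }
    for (k in seq_len(n))
        d <- pmin(d, outer(d[, k], d[k, ], `+`))
    d
}

# component sizes by label propagation over the edge set
bruteComponentSizes <- function(net) {
    labs <- nodes(net)
    comp <- seq_along(labs)
    names(comp) <- labs
    em <- edges(net)
    repeat {
        changed <- FALSE
        for (i in seq_len(nrow(em))) {
            a <- em[i, 1L]; b <- em[i, 2L]
            m <- min(comp[a], comp[b])
            if (comp[a] != m || comp[b] != m) {
                comp[comp == comp[a] | comp == comp[b]] <- m
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    sort(as.integer(table(comp)), decreasing = TRUE)
}
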