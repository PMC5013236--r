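#' Barabasi-Albert preferential-attachment network
#'
#' Growth with preferential attachment: the seed graph is the complete
#' graph on m + 1 nodes, and each subsequent node attaches to m DISTINCT
#' existing nodes drawn without replacement with probability proportional
#' to their current degree. The result is connected, every non-seed node
#' has degree >= m, and the edge count is C(m+1, 2) + (n - m - 1) * m
#' exactly. Identical seed and parameters give an identical network.
#'
#' @param n Number of nodes (> m).
#' @param m Edges added per new node (>= 1).
#' @param seed Integer random seed (required: generation is stochastic).
#' @param name Network name.
#' @return A clean, connected \code{InteractionNetwork}.
#' @examples
#' ba <- baNetwork(128, 2, seed = 1)
#' numEdges(ba)  # 3 + 125 * 2 = 253
#' @export
baNetwork <- function(n, m = 2L, seed, name = "BA") {
    n <- as.integer(n); m <- as.integer(m)
    if (m < 1L) stop("config error: 'm' must be >= 1")
    if (n <= m) stop("config error: 'n' must exceed 'm'")
    if (missing(seed) || is.null(seed))
        stop("config error: 'seed' is required for the stochastic model")
    labels <- sprintf("v%0*d", nchar(n), seq_len(n))
    nSeed <- m + 1L
    seedEdges <- t(utils::combn(nSeed, 2L))
    extra <- (n - nSeed) * m
    from <- integer(nrow(seedEdges) + extra)
    to <- integer(length(from))
    from[seq_len(nrow(seedEdges))] <- seedEdges[, 1L]
    to[seq_len(nrow(seedEdges))] <- seedEdges[, 2L]
    deg <- integer(n)
    deg[seq_len(nSeed)] <- m
    .withSeed(seed, {
        pos <- nrow(seedEdges)
        for (t in seq.int(nSeed + 1L, length.out = n - nSeed)) {
            targets <- sample.int(t - 1L, m, replace = FALSE,
                                  prob = deg[seq_len(t - 1L)])
            from[pos + seq_len(m)] <- t
            to[pos + seq_len(m)] <- targets
            pos <- pos + m
            deg[targets] <- deg[targets] + 1L
            deg[t] <- m
        }
    })
    Network(name, nodes = labels,
            edges = cbind(labels[from], labels[to]))
}

#' Erdos-Renyi random network
#'
#' G(n, p): each of the C(n, 2) node pairs is an edge independently with
#' probability p. Deterministic given the seed.
#'
#' @param n Number of nodes (>= 1).
#' @param p Edge probability in [0, 1].
#' @param seed Integer random seed (required when 0 < p < 1).
#' @param name Network name.
#' @return A clean \code{InteractionNetwork}.
#' @export
erNetwork <- function(n, p, seed = NULL, name = "ER") {
    n <- as.integer(n)
    if (n < 1L) stop("config error: 'n' must be >= 1")
    if (p < 0 || p > 1) stop("config error: 'p' must lie in [0, 1]")
    labels <- sprintf("v%0*d", nchar(n), seq_len(n))
    if (n < 2L || p == 0)
        return(Network(name, nodes = labels))
    pairs <- t(utils::combn(n, 2L))
    if (p == 1) {
        pick <- rep(TRUE, nrow(pairs))
    } else {
        if (is.null(seed))
            stop("config error: 'seed' is required for the stochastic ",
                 "model")
        pick <- .withSeed(seed, stats::runif(nrow(pairs)) < p)
    }
    Network(name, nodes = labels,
            edges = cbind(labels[pairs[pick, 1L]],
                          labels[pairs[pick, 2L]]))
}

#' Ravasz-style hierarchical network
#'
#' Deterministic hierarchical construction producing a scale-free network
#' with high, degree-dependent clustering: the unit is a complete 5-node
#' module; at each replication level four copies of the current graph are
#' attached and all peripheral nodes (those never central at any level)
#' are wired to the root hub. With \code{levels} replication levels the
#' network has 5^levels nodes, mean clustering well above 0.5, and a C(k)
#' profile that decreases with degree -- the hierarchical signature.
#' Optionally a small seeded perturbation rewires a fraction
#' \code{rewireRate} of the edges (one endpoint redrawn uniformly;
#' self-loops and duplicates discarded by cleaning).
#'
#' @param levels Replication depth, 1 to 4 (5 to 625 nodes).
#' @param seed Integer seed for the optional rewiring; NULL for the pure
#'   deterministic construction.
#' @param rewireRate Fraction of edges to rewire when a seed is given.
#' @param name Network name.
#' @return A clean \code{InteractionNetwork}.
#' @export
hierarchicalNetwork <- function(levels, seed = NULL,
                                rewireRate = if (is.null(seed)) 0
                                             else 0.02,
                                name = "HIER") {
    levels <- as.integer(levels)
    if (levels < 1L) stop("config error: 'levels' must be >= 1")
    if (levels > 4L)
        stop("config error: 'levels' > 4 rejected (network would exceed ",
             "3000 nodes)")
    n <- 5L^levels
    digits <- as.matrix(expand.grid(rep(list(0:4), levels))[, levels:1,
                                                            drop = FALSE])
    labels <- apply(digits, 1L, paste, collapse = "")
    labels <- paste0("h", labels)
    from <- character(); to <- character()
    # bottom-level complete 5-modules (vary the last digit)
    pairIdx <- t(utils::combn(5L, 2L))
    prefixKey <- if (levels > 1L)
        apply(digits[, -levels, drop = FALSE], 1L, paste, collapse = "")
        else rep("", n)
    for (pref in unique(prefixKey)) {
        members <- which(prefixKey == pref)
        members <- members[order(digits[members, levels])]
        from <- c(from, labels[members[pairIdx[, 1L]]])
        to <- c(to, labels[members[pairIdx[, 2L]]])
    }
    # level-l wiring: peripheral nodes of each level-l module to its root
    if (levels > 1L) {
        for (l in 2:levels) {
            low <- (levels - l + 1L):levels
            high <- seq_len(levels - l)
            modKey <- if (length(high))
                apply(digits[, high, drop = FALSE], 1L, paste,
                      collapse = "") else rep("", n)
            for (mod in unique(modKey)) {
                members <- which(modKey == mod)
                rootIdx <- members[rowSums(
                    digits[members, low, drop = FALSE] != 0L) == 0L]
                periph <- members[rowSums(
                    digits[members, low, drop = FALSE] == 0L) == 0L]
                from <- c(from, rep(labels[rootIdx], length(periph)))
                to <- c(to, labels[periph])
            }
        }
    }
    net <- cleanNetwork(Network(name, nodes = labels,
                                edges = cbind(from, to)))
    if (!is.null(seed) && rewireRate > 0) {
        em <- net@edges
        nRewire <- round(rewireRate * nrow(em))
        if (nRewire > 0) {
            .withSeed(seed, {
                which_e <- sample.int(nrow(em), nRewire)
                newEnd <- sample(labels, nRewire, replace = TRUE)
                side <- sample(1:2, nRewire, replace = TRUE)
                for (i in seq_len(nRewire))
                    em[which_e[i], side[i]] <- newEnd[i]
            })
            net <- cleanNetwork(Network(name, nodes = labels,
                                        edges = em))
        }
    }
    net
}

#' Generate a synthetic network from a model configuration
#'
#' Single entry point over the package's generators. Supported models:
#' \code{barabasi_albert} (n, m, seed), \code{erdos_renyi} (n, p, seed),
#' \code{hierarchical} (levels, seed), \code{star} (n = total nodes),
#' \code{ring} (n), \code{complete} (n) and \code{two_component} (a
#' 125-node preferential-attachment main component plus a disjoint
#' 3-node triangle, seeded). Identical configuration and seed give an
#' identical network.
#'
#' @param model Model name, see above.
#' @param n,m,p,levels Model parameters (each validated for the chosen
#'   model).
#' @param seed Integer seed, required for the stochastic models.
#' @param name Network name (defaults to the model name).
#' @return A clean \code{InteractionNetwork}.
#' @export
generateNetwork <- function(model = c("barabasi_albert", "erdos_renyi",
                                      "hierarchical", "star", "ring",
                                      "complete", "two_component"),
                            n = NULL, m = 2L, p = NULL, levels = NULL,
                            seed = NULL, name = NULL) {
    model <- match.arg(model)
    if (is.null(name)) name <- model
    switch(model,
        barabasi_albert = {
            if (is.null(n)) stop("config error: 'n' is required")
            baNetwork(n, m, seed = seed, name = name)
        },
        erdos_renyi = {
            if (is.null(n)) stop("config error: 'n' is required")
            if (is.null(p)) stop("config error: 'p' is required")
            erNetwork(n, p, seed = seed, name = name)
        },
        hierarchical = {
            if (is.null(levels))
                stop("config error: 'levels' is required")
            hierarchicalNetwork(levels, seed = seed, name = name)
        },
        star = {
            if (is.null(n) || n < 2L)
                stop("config error: 'n' must be >= 2")
            Network(name, edges = cbind("center",
                                        sprintf("leaf%02d",
                                                seq_len(n - 1L))))
        },
        ring = {
            if (is.null(n) || n < 3L)
                stop("config error: 'n' must be >= 3")
            lab <- sprintf("v%0*d", nchar(n), seq_len(n))
            Network(name, edges = cbind(lab, lab[c(2:n, 1L)]))
        },
        complete = {
            if (is.null(n) || n < 2L)
                stop("config error: 'n' must be >= 2")
            lab <- sprintf("v%0*d", nchar(n), seq_len(n))
            pr <- t(utils::combn(n, 2L))
            Network(name, edges = cbind(lab[pr[, 1L]], lab[pr[, 2L]]))
        },
        two_component = {
            if (is.null(seed))
                stop("config error: 'seed' is required")
            main <- baNetwork(125L, 2L, seed = seed, name = name)
            tri <- Network(name, edges = cbind(c("x1", "x2", "x3"),
                                               c("x2", "x3", "x1")))
            cleanNetwork(Network(name,
                nodes = c(nodes(main), nodes(tri)),
                edges = rbind(edges(main), edges(tri))))
        })
}

#' Deterministic fixture networks
#'
#' A named list of small, fully deterministic networks exercising the
#' pipeline's edge cases: a triangle, an 11-node path (diameter 10), an
#' 11-node star, a 10-node ring, the complete graph K5, two disjoint
#' triangles, and a 128-node two-component network whose parts have 125
#' and 3 nodes (a main component of 125 nodes plus a detached triangle,
#' the shape a 128-node preferential-attachment run can decompose into).
#' Stable across calls and sessions.
#'
#' @return Named list of clean \code{InteractionNetwork} objects.
#' @export
fixtureSuite <- function() {
    path11 <- sprintf("p%02d", 1:11)
    list(
        triangle = Network("triangle",
            edges = cbind(c("A", "B", "C"), c("B", "C", "A"))),
        path_11 = Network("path_11",
            edges = cbind(path11[-11], path11[-1])),
        star_11 = generateNetwork("star", n = 11L, name = "star_11"),
        ring_10 = generateNetwork("ring", n = 10L, name = "ring_10"),
        k5 = generateNetwork("complete", n = 5L, name = "k5"),
        two_triangles = Network("two_triangles",
            edges = cbind(c("A", "B", "C", "D", "E", "F"),
                          c("B", "C", "A", "E", "F", "D"))),
        two_component_125_3 = generateNetwork("two_component",
            seed = 42L, name = "two_component_125_3"))
}
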