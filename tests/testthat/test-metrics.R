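test_that("degrees satisfy the handshake identity", {
    tri <- fixtureSuite()$triangle
    expect_equal(nodeDegree(tri, "A"), 2L)
    star <- fixtureSuite()$star_11
    expect_equal(nodeDegree(star, "center"), 10L)
    expect_error(nodeDegree(tri, "Z"), "unknown node")

    set.seed(101)
    for (i in 1:30) {
        net <- cleanNetwork(randomNetwork(sample(5:25, 1), 0.2))
        expect_equal(sum(nodeDegrees(net)), 2L * numEdges(net))
    }
})

test_that("node clustering matches exhaustive triangle counting", {
    tri <- fixtureSuite()$triangle
    expect_equal(nodeClustering(tri, "A"), 1.0)
    path <- Network("p", edges = cbind(c("A", "B"), c("B", "C")))
    expect_equal(nodeClustering(path, "B"), 0.0)
    expect_true(is.na(nodeClustering(path, "A")))  # degree 1: undefined

    set.seed(111)
    for (i in 1:40) {
        net <- cleanNetwork(randomNetwork(sample(5:20, 1), 0.3))
        cc <- nodeClusterings(net)
        for (nd in nodes(net))
            expect_equal(unname(cc[nd]), bruteClustering(net, nd))
        expect_true(all(cc >= 0 & cc <= 1, na.rm = TRUE))
    }
})

test_that("mean clustering follows the degree >= 2 convention", {
    expect_equal(meanClustering(fixtureSuite()$k5), 1.0)
    tree <- Network("t", edges = cbind(c("A", "A", "B", "B"),
                                       c("B", "C", "D", "E")))
    expect_equal(meanClustering(tree), 0.0)
    # alternative convention: degree < 2 nodes count as zero
    pendant <- cleanNetwork(Network("pt",
        edges = cbind(c("A", "B", "C", "C"), c("B", "C", "A", "D"))))
    expect_gt(meanClustering(pendant),
              meanClustering(pendant, countLowDegreeAsZero = TRUE))
    expect_error(meanClustering(Network("empty")), "non-empty")
})

test_that("hierarchical construction reaches the high-clustering regime", {
    h <- hierarchicalNetwork(3)
    expect_gte(meanClustering(h), 0.5)
})

test_that("all-pairs distances use ordered-pair accounting", {
    # two disjoint triangles: 2 * 3 * 2 = 12 finite ordered pairs of 30
    ds <- allPairsDistances(fixtureSuite()$two_triangles)
    expect_equal(ds@finitePairCount, 12)
    expect_equal(ds@percentOfAllPairs, 0.4)

    # any connected 128-node graph: 128 * 127 ordered pairs, 100%
    ba <- baNetwork(128, 2, seed = 9)
    ds <- allPairsDistances(ba)
    expect_equal(ds@finitePairCount, 16256)
    expect_equal(ds@percentOfAllPairs, 1.0)

    expect_error(allPairsDistances(Network("one", nodes = "A")),
                 "two nodes")
})

test_that("distance summaries agree with Floyd-Warshall exactly", {
    set.seed(121)
    for (i in 1:40) {
        net <- cleanNetwork(randomNetwork(sample(5:30, 1), 0.12))
        ds <- allPairsDistances(net)
        fw <- floydWarshall(net)
        off <- fw[row(fw) != col(fw)]
        finite <- off[is.finite(off)]
        expect_equal(ds@finitePairCount, length(finite))
        if (length(finite)) {
            expect_equal(ds@diameter, as.integer(max(finite)))
            expect_equal(ds@characteristicPathLength, mean(finite))
            expect_equal(ds@histogram,
                         table(finite)[names(ds@histogram)],
                         ignore_attr = TRUE)
        }
        # invariants: even ordered counts, component identity, CPL bound
        expect_true(all(ds@histogram %% 2 == 0))
        sizes <- sapply(connectedComponents(net), numNodes)
        expect_equal(ds@finitePairCount, sum(sizes * (sizes - 1)))
        if (ds@finitePairCount > 0)
            expect_lte(ds@characteristicPathLength, ds@diameter)
    }
})

test_that("diameter and mean neighbors on canonical shapes", {
    expect_equal(networkDiameter(fixtureSuite()$path_11), 10L)
    expect_equal(networkDiameter(fixtureSuite()$k5), 1L)
    expect_equal(avgNeighbors(generateNetwork("ring", n = 17)), 2.0)
    expect_equal(avgNeighbors(generateNetwork("ring", n = 3)), 2.0)
})

test_that("degree distribution tallies per degree class", {
    star10 <- cleanNetwork(Network("s",
        edges = cbind("hub", paste0("l", 1:9))))
    dd <- degreeDistribution(star10)
    expect_equal(dd$k, c(1L, 9L))
    expect_equal(dd$count, c(9L, 1L))

    k4 <- generateNetwork("complete", n = 4)
    dd <- degreeDistribution(k4)
    expect_equal(dd$k, 3L)
    expect_equal(dd$count, 4L)

    set.seed(131)
    for (i in 1:30) {
        net <- cleanNetwork(randomNetwork(sample(5:25, 1), 0.2))
        dd <- degreeDistribution(net)
        expect_equal(sum(dd$k * dd$count), 2L * numEdges(net))
        expect_equal(sum(dd$count) + attr(dd, "nZeroDegree"),
                     numNodes(net))
    }
})

test_that("topology report assembles all fields correctly", {
    tri <- fixtureSuite()$triangle
    rep <- topologyReport(tri)
    expect_equal(rep@nComponents, 1L)
    expect_equal(rep@nNodes, 3L)
    expect_equal(rep@nEdges, 3L)
    expect_equal(rep@meanClustering, 1.0)
    expect_equal(rep@diameter, 1L)
    expect_equal(rep@characteristicPathLength, 1.0)
    expect_equal(rep@avgNeighbors, 2.0)

    # a connected 66-node network has 66 * 65 = 4290 ordered pairs
    net66 <- baNetwork(66, 2, seed = 13)
    expect_equal(topologyReport(net66)@distances@finitePairCount, 4290)

    # field-by-field against independently recomputed values
    set.seed(141)
    net <- cleanNetwork(randomNetwork(30, 0.1))
    rep <- topologyReport(net)
    expect_equal(rep@nComponents, length(bruteComponentSizes(net)))
    ccs <- sapply(nodes(net), function(nd) bruteClustering(net, nd))
    expect_equal(rep@meanClustering, mean(ccs[!is.na(ccs)]))
    fw <- floydWarshall(net)
    off <- fw[row(fw) != col(fw)]
    expect_equal(rep@diameter, as.integer(max(off[is.finite(off)])))
    expect_equal(rep@avgNeighbors, 2 * numEdges(net) / numNodes(net))
    df <- as.data.frame(rep)
    expect_equal(df$n_nodes, 30L)
    expect_equal(df$clustering_coefficient,
                 round(rep@meanClustering, 3))
})

test_that("metrics refuse unclean networks", {
    raw <- Network("raw", edges = cbind(c("A", "A"), c("A", "B")))
    expect_error(topologyReport(raw), "clean")
    expect_error(nodeClusterings(raw), "clean")
})
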