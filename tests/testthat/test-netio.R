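test_that("edge-list reading preserves raw input and declares isolates", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c("# comment", "A\tB", "B\tC"), f)
    net <- readEdgeList(f)
    expect_equal(sort(nodes(net)), c("A", "B", "C"))
    expect_equal(numEdges(net), 2L)

    writeLines(c("A\tA", "A\tB", "A\tB"), f)
    raw <- readEdgeList(f)
    expect_equal(sort(nodes(raw)), c("A", "B"))
    expect_equal(numEdges(raw), 3L)          # raw multiset kept for audit
    expect_equal(bruteDistinctPairs(raw), 1L)

    writeLines(c("A\tB", "C", "  D  "), f)
    iso <- readEdgeList(f)
    expect_equal(sort(nodes(iso)), c("A", "B", "C", "D"))

    writeLines(c("A\tB", "\t\t"), f)
    expect_error(readEdgeList(f), "line 2")
    expect_error(readEdgeList(file.path(tempdir(), "nope.txt")),
                 "not found")
})

test_that("SIF reading follows one-source-many-targets semantics", {
    f <- withr::local_tempfile(fileext = ".sif")
    writeLines("A pp B C", f)
    net <- readSIF(f)
    expect_equal(sort(nodes(net)), c("A", "B", "C"))
    expect_true(sameTopology(net,
        Network("x", edges = cbind(c("A", "A"), c("B", "C")))))
    expect_equal(edgeData(net)$relation, c("pp", "pp"))

    writeLines("A", f)
    expect_equal(numNodes(readSIF(f)), 1L)
    expect_equal(numEdges(readSIF(f)), 0L)

    writeLines("A pp", f)
    expect_error(readSIF(f), "line 1")
})

test_that("SIF and edge-list renderings of one network read back equal", {
    net <- cleanNetwork(baNetwork(40, 2, seed = 7))
    fe <- withr::local_tempfile(fileext = ".txt")
    fs <- withr::local_tempfile(fileext = ".sif")
    writeEdgeList(net, fe)
    writeSIF(net, fs)
    expect_true(sameTopology(readEdgeList(fe), readSIF(fs)))
})

test_that("interaction tables map records to undirected annotated edges", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        "Source molecule\tInteraction\tTarget molecule\tReference",
        "EGFR\tactivates\tPLC\tref1",
        "PLC\tcleaves\tPIP2\tref2"), f)
    net <- readInteractionTable(f)
    expect_equal(sort(nodes(net)), c("EGFR", "PIP2", "PLC"))
    expect_equal(numEdges(net), 2L)
    expect_equal(edgeData(net)$interaction, c("activates", "cleaves"))

    # duplicated pair with different references collapses, keeping both
    writeLines(c(
        "Source molecule\tInteraction\tTarget molecule\tReference",
        "EGFR\tactivates\tPLC\tref1",
        "PLC\tbinds\tEGFR\tref2"), f)
    dup <- cleanNetwork(readInteractionTable(f))
    expect_equal(numEdges(dup), 1L)
    expect_match(edgeData(dup)$reference, "ref1")
    expect_match(edgeData(dup)$reference, "ref2")

    writeLines(c("Source molecule\tTarget molecule", "A\tB"), f)
    expect_error(readInteractionTable(f), "interaction")
    writeLines(c(
        "Source molecule\tInteraction\tTarget molecule",
        "A\tx\tB", "\tx\tC"), f)
    expect_error(readInteractionTable(f), "row 2")
})

test_that("interaction-table node set equals the distinct source/target union", {
    f <- withr::local_tempfile(fileext = ".csv")
    set.seed(11)
    pool <- c("EGFR", "PLC", "PIP2", "PKA", "PKC", "RHOA", "CDC42",
              "RAC1", "cofilin", "Arp2/3")
    src <- sample(pool, 26, replace = TRUE)
    tgt <- sample(pool, 26, replace = TRUE)
    ok <- src != tgt
    src <- src[ok]; tgt <- tgt[ok]
    writeLines(c("Source molecule,Interaction,Target molecule",
                 paste(src, "acts_on", tgt, sep = ",")), f)
    net <- readInteractionTable(f)
    expect_setequal(nodes(net), unique(c(src, tgt)))
})

test_that("cleanNetwork removes loops and duplicates, keeps nodes, idempotent", {
    raw <- Network("raw", edges = cbind(c("A", "A", "B"),
                                        c("A", "B", "A")))
    cl <- cleanNetwork(raw)
    expect_equal(sort(nodes(cl)), c("A", "B"))
    expect_equal(unname(canonicalEdges(cl)), cbind("A", "B"))
    expect_identical(edges(cleanNetwork(cl)), edges(cl))

    set.seed(21)
    for (i in 1:25) {
        mg <- randomMultigraph(sample(4:12, 1))
        cl <- cleanNetwork(mg)
        expect_true(isClean(cl))
        expect_equal(numEdges(cl), bruteDistinctPairs(mg))
        expect_setequal(nodes(cl), nodes(mg))
        expect_identical(edges(cleanNetwork(cl)), edges(cl))
    }
})

test_that("mergeNetworks unions nodes and cleaned edges order-independently", {
    a <- Network("a", edges = cbind("A", "B"))
    b <- Network("b", edges = cbind("B", "C"))
    m <- mergeNetworks(list(a, b))
    expect_setequal(nodes(m), c("A", "B", "C"))
    expect_equal(numEdges(m), 2L)
    expect_true(sameTopology(mergeNetworks(list(a, a)), cleanNetwork(a)))
    expect_error(mergeNetworks(list()), "non-empty")

    set.seed(31)
    nets <- replicate(5, randomNetwork(10, 0.2), simplify = FALSE)
    merged <- mergeNetworks(nets, name = "m")
    allKeys <- unique(unlist(lapply(nets, function(nn) {
        em <- edges(nn)
        paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
    })))
    expect_equal(numEdges(merged), length(allKeys))
    expect_setequal(nodes(merged), unique(unlist(lapply(nets, nodes))))
    shuffled <- mergeNetworks(rev(nets), name = "m")
    expect_true(sameTopology(merged, shuffled))
})

test_that("stoplist filtering is exact-label and keeps survivors intact", {
    star <- cleanNetwork(Network("s",
        edges = cbind("spermatozoa", c("a", "b", "c", "d"))))
    filt <- removeNodes(star, "spermatozoa")
    expect_equal(numEdges(filt), 0L)
    expect_equal(sort(nodes(filt)), c("a", "b", "c", "d"))
    expect_equal(numNodes(removeNodes(star, "spermatozoa",
                                      dropIsolated = TRUE)), 0L)

    # exact match: "membrane" must not remove "membrane receptor"
    net <- cleanNetwork(Network("n",
        edges = cbind(c("membrane", "membrane receptor"),
                      c("PKA", "PKA"))))
    filt <- removeNodes(net, "membrane")
    expect_true("membrane receptor" %in% nodes(filt))
    expect_equal(numEdges(filt), 1L)

    untouched <- removeNodes(star, c("absent", "also absent"))
    expect_true(sameTopology(untouched, star))

    set.seed(41)
    for (i in 1:20) {
        net <- randomNetwork(12, 0.25)
        stop <- sample(nodes(net), 3)
        filt <- removeNodes(net, stop)
        em <- edges(net)
        keep <- !(em[, 1] %in% stop) & !(em[, 2] %in% stop)
        expect_equal(numEdges(filt), sum(keep))
        expect_setequal(nodes(filt), setdiff(nodes(net), stop))
    }
})

test_that("components partition the node set deterministically", {
    twoTri <- fixtureSuite()$two_triangles
    comps <- connectedComponents(twoTri)
    expect_length(comps, 2L)
    expect_equal(sapply(comps, numNodes), c(3L, 3L))
    # tie broken by smallest member label
    expect_true("A" %in% nodes(comps[[1]]))

    expect_length(connectedComponents(baNetwork(60, 2, seed = 3)), 1L)
    expect_length(connectedComponents(Network("empty")), 0L)

    set.seed(51)
    for (i in 1:20) {
        net <- randomNetwork(14, 0.08)
        comps <- connectedComponents(net)
        expect_equal(sum(sapply(comps, numNodes)), numNodes(net))
        expect_equal(sum(sapply(comps, numEdges)), numEdges(net))
        expect_equal(sapply(comps, numNodes), bruteComponentSizes(net))
    }
})

test_that("main component is the largest part, renamed MC_", {
    twoComp <- fixtureSuite()$two_component_125_3
    expect_equal(sapply(connectedComponents(twoComp), numNodes),
                 c(125L, 3L))
    mc <- mainComponent(twoComp)
    expect_equal(numNodes(mc), 125L)
    expect_equal(networkName(mc), "MC_two_component_125_3")

    ba <- baNetwork(30, 2, seed = 5)
    expect_true(sameTopology(mainComponent(ba), ba))
    expect_error(mainComponent(Network("empty")), "non-empty")

    set.seed(61)
    for (i in 1:20) {
        net <- randomNetwork(15, 0.07)
        expect_equal(numNodes(mainComponent(net)),
                     max(bruteComponentSizes(net)))
    }
})

test_that("write-then-read is the identity and output is byte-stable", {
    set.seed(71)
    for (i in 1:20) {
        net <- cleanNetwork(randomNetwork(sample(5:15, 1), 0.2))
        fe <- tempfile(fileext = ".txt")
        writeEdgeList(net, fe)
        expect_true(sameTopology(readEdgeList(fe), net))
        fs <- tempfile(fileext = ".sif")
        writeSIF(net, fs)
        expect_true(sameTopology(readSIF(fs), net))
        file.remove(fe, fs)
    }
    net <- cleanNetwork(Network("x", nodes = "C",
                                edges = cbind("A", "B")))
    f <- withr::local_tempfile(fileext = ".txt")
    writeEdgeList(net, f)
    expect_equal(readLines(f), c("A\tB", "C"))
    f2 <- withr::local_tempfile(fileext = ".txt")
    writeEdgeList(net, f2)
    expect_identical(readLines(f), readLines(f2))
})
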