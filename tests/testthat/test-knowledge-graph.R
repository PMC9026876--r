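test_that("edge-list reader deduplicates, drops self-loops, reports loads", {
  kg <- readEdgeList(writeTempEdges(character(0)))
  expect_equal(nodeCount(kg), 0)
  expect_equal(edgeCount(kg), 0)

  kg <- readEdgeList(writeTempEdges(c("A\tB", "B\tC", "A\tB")))
  expect_equal(edgeCount(kg), 2)
  expect_equal(nodeCount(kg), 3)
  rep <- loadReport(kg)
  expect_equal(rep$lines, 3)
  expect_equal(rep$unique_edges, 2)
  expect_equal(rep$duplicates_dropped, 1)

  kg <- readEdgeList(writeTempEdges("A\tA"))
  expect_equal(edgeCount(kg), 0)
  expect_equal(loadReport(kg)$self_loops_dropped, 1)

  # reversed duplicates collapse onto one unordered pair
  kg <- readEdgeList(writeTempEdges(c("B\tA", "A\tB")))
  expect_equal(edgeCount(kg), 1)

  # comments skipped, SIF format, accession normalization
  kg <- readEdgeList(writeTempEdges(c("# header", "p07996-2 pp Q92743")),
                     format = "sif")
  expect_setequal(nodeIds(kg), c("P07996", "Q92743"))
})

test_that("malformed and empty-identifier lines are rejected by line number", {
  expect_error(readEdgeList(writeTempEdges(c("A\tB", "Conly"))), "line 2")
  expect_error(readEdgeList(writeTempEdges("\tB")), "empty identifier")
  expect_error(readEdgeList(writeTempEdges("A B", ".sif")), "line 1")
})

test_that("merging layers unions nodes and collapses topology", {
  g1 <- KnowledgeGraph(data.frame(source = "A", target = "B",
                                  layer = "physical", provenance = ""))
  g2 <- KnowledgeGraph(data.frame(source = "A", target = "B",
                                  layer = "signaling", provenance = ""))
  m <- mergeGraphs(list(g1, g2))
  expect_equal(edgeCount(m), 1)          # one topological edge
  expect_equal(nrow(layerTable(m)), 2)   # two layer records

  expect_equal(edgeCount(mergeGraphs(list())), 0)
  expect_equal(edgeCount(mergeGraphs(list(g1))), edgeCount(g1))

  # idempotent: merging a graph with itself leaves topology unchanged
  kg <- randomGraph(10, 0.3, seed = 7)
  m2 <- mergeGraphs(list(kg, kg))
  expect_equal(edgeCount(m2), edgeCount(kg))
  expect_setequal(nodeIds(m2), nodeIds(kg))
})

test_that("hop distances match hand counts and the sentinel contract", {
  kg <- pathGraph(3)
  expect_equal(shortestPathLength(kg, "A", "A"), 0)
  expect_equal(shortestPathLength(kg, "A", "C"), 2)
  two <- KnowledgeGraph(data.frame(source = c("A", "C"),
                                   target = c("B", "D")))
  expect_equal(shortestPathLength(two, "A", "D"), Inf)
  expect_error(shortestPathLength(kg, "A", "ZZZ"), "ZZZ")
})

test_that("shortest paths agree with a Floyd-Warshall oracle on small graphs", {
  for (seed in 1:5) {
    kg <- randomGraph(sample(4:12, 1), 0.25, seed = seed)
    D <- fwOracle(kg)
    ids <- nodeIds(kg)
    pairs <- t(utils::combn(ids, 2))
    for (i in sample(nrow(pairs), min(15, nrow(pairs)))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      expect_equal(shortestPathLength(kg, a, b), D[a, b])
      expect_equal(shortestPathLength(kg, b, a),
                   shortestPathLength(kg, a, b))  # symmetry
    }
  }
})

test_that("restart walk matches a direct linear solve and normalizes", {
  # two nodes A-B, seeds {A}, restart 0.5: exact solution 2/3, 1/3
  kg <- KnowledgeGraph(data.frame(source = "A", target = "B"))
  p <- rwrProximity(kg, "A", restart = 0.5)
  expect_equal(unname(p[c("A", "B")]), c(2 / 3, 1 / 3), tolerance = 1e-9)

  # single node: all mass on the seed
  solo <- KnowledgeGraph(nodes = "A")
  expect_equal(unname(rwrProximity(solo, "A", restart = 0.3)), 1)

  # isolated seed in a larger graph: mass stays on the seed
  iso <- KnowledgeGraph(data.frame(source = "A", target = "B"), nodes = "Z")
  pz <- rwrProximity(iso, "Z", restart = 0.3)
  expect_equal(unname(pz["Z"]), 1)
  expect_equal(sum(pz), 1, tolerance = 1e-8)

  for (seed in 1:4) {
    kg <- randomGraph(sample(10:50, 1), 0.1, seed = seed + 20)
    seeds <- sample(nodeIds(kg), 3)
    p <- rwrProximity(kg, seeds, restart = 0.4, tol = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-8)
    expect_equal(p, rwrOracle(kg, seeds, 0.4)[names(p)], tolerance = 1e-8)
  }
  expect_error(rwrProximity(pathGraph(3), "NOPE"), "NOPE")
})

test_that("degree sequence reports collapsed simple-graph degrees", {
  expect_length(degreeSequence(KnowledgeGraph()), 0)
  expect_equal(degreeSequence(pathGraph(3)), c(A = 1L, B = 2L, C = 1L))
  star <- KnowledgeGraph(data.frame(source = "HUB",
                                    target = c("A", "B", "C", "D")))
  expect_equal(unname(degreeSequence(star)["HUB"]), 4L)
})
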