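test_that("motif census matches hand counts on canonical graphs", {
  k3 <- asSignedNet(igraph::make_full_graph(3))
  expect_identical(motifCensus(k3, 3), c(path = 0L, triangle = 1L))
  k4 <- asSignedNet(igraph::make_full_graph(4))
  expect_identical(motifCensus(k4, 3), c(path = 0L, triangle = 4L))
  expect_identical(motifCensus(k4, 4)[["clique"]], 1L)
  claw <- asSignedNet(igraph::make_star(4, mode = "undirected"))
  expect_identical(motifCensus(claw, 3), c(path = 3L, triangle = 0L))
  expect_identical(motifCensus(claw, 4)[["star"]], 1L)
  expect_error(motifCensus(k4, 5), "3 or 4")
})

test_that("motif census equals brute-force enumeration on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    m <- sample(seq_len(n * (n - 1) / 2), 1)
    net <- randomSignedNet(n, m, seed = seed)
    g <- asIgraph(net)
    for (k in c(3L, 4L)) {
      expect_identical(motifCensus(net, k),
                       bruteMotifCensus(g, k)[names(motifCensus(net, k))],
                       label = sprintf("n=%d m=%d k=%d", n, m, k))
    }
  }
})

test_that("cluster scores recompute exactly from member sets", {
  # module with 16 nodes and 110 internal edges scores 6.875
  set.seed(1)
  g16 <- igraph::sample_gnm(16, 110)
  net16 <- asSignedNet(g16)
  cl <- clusterResult(net16, nodeTable(net16)$name)
  expect_identical(clusterScore(cl), 110 / 16)
  expect_identical(clusterScore(cl), 6.875)
  # K4 module: 6/4 = 1.5
  expect_identical(clusterScore(clusterResult(asSignedNet(
    igraph::make_full_graph(4)), paste0("n", 1:4))), 1.5)
  expect_error(clusterResult(net16, c("n1", "nope")), "network nodes")
})

test_that("MCODE recovers a planted clique and is deterministic", {
  path <- igraph::make_ring(6, circular = FALSE)
  igraph::V(path)$name <- paste0("bg", 1:6)
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("cl", 1:5)
  g <- igraph::disjoint_union(path, k5)
  g <- igraph::add_edges(g, match(c("bg1", "cl1"), igraph::V(g)$name))
  net <- asSignedNet(g)
  cl <- mcodeClusters(net)
  expect_true(length(cl) >= 1)
  expect_setequal(clusterMembers(cl[[1]]), paste0("cl", 1:5))
  expect_identical(clusterScore(cl[[1]]), 2)
  expect_identical(cl[[1]]@rank, 1L)
  # deterministic: identical output on repeat
  expect_identical(lapply(mcodeClusters(net), clusterMembers),
                   lapply(cl, clusterMembers))
  # ranks sorted by descending score, scores consistent with members
  big <- randomSignedNet(40, 180, seed = 8, nNeg = 20)
  cls <- mcodeClusters(big)
  sc <- vapply(cls, clusterScore, numeric(1))
  expect_true(all(diff(sc) <= 1e-12))
  for (x in cls) {
    re <- clusterResult(big, clusterMembers(x))
    expect_equal(clusterScore(x), clusterScore(re))
  }
  expect_identical(mcodeClusters(asSignedNet(
    igraph::make_empty_graph(0, directed = FALSE))), list())
})

test_that("negative links inside a cluster are inventoried exactly", {
  # hub negatively tied to every other member of a dense module
  k <- igraph::make_full_graph(8)
  igraph::V(k)$name <- c("hub", paste0("m", 1:7))
  el <- igraph::as_edgelist(k, names = TRUE)
  r <- ifelse(el[, 1] == "hub" | el[, 2] == "hub", -0.8, 0.8)
  net <- asSignedNet(k, r = r)
  cl <- clusterResult(net, igraph::V(k)$name)
  neg <- negativeLinksInCluster(net, cl)
  expect_identical(nrow(neg), 7L)
  expect_true(all(neg$node_a == "hub" | neg$node_b == "hub"))
  # all-positive cluster -> empty inventory
  allPos <- asSignedNet(igraph::make_full_graph(4))
  expect_identical(nrow(negativeLinksInCluster(
    allPos, clusterResult(allPos, paste0("n", 1:4)))), 0L)
  # a single planted negative edge is returned as exactly that pair
  r2 <- rep(0.9, 6); r2[1] <- -0.5
  one <- asSignedNet(igraph::make_full_graph(4), r = r2)
  nl <- negativeLinksInCluster(one, paste0("n", 1:4))
  expect_identical(nrow(nl), 1L)
  expect_equal(nl$r, -0.5)
})
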