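test_that("pearsonWithP matches the closed forms and flags constants", {
  expect_equal(pearsonWithP(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearsonWithP(1:5, -(1:5))$r, -1, tolerance = 1e-12)

  # independent high-precision evaluation of r and its t-transform p
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  rManual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tManual <- rManual * sqrt((4 - 2) / (1 - rManual^2))
  pManual <- 2 * (1 - pt(abs(tManual), df = 2))
  res <- pearsonWithP(x, y)
  expect_equal(res$r, rManual, tolerance = 1e-12)
  expect_equal(res$p, pManual, tolerance = 1e-12)

  expect_true(is.na(pearsonWithP(rep(2, 5), 1:5)$r))
  expect_error(pearsonWithP(1:2, 1:2), "at least 3")
})

test_that("same-table networks keep all nodes and honor alpha", {
  set.seed(7)
  m <- matrix(rnorm(5 * 30, 10), nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:30)))
  m <- abs(m)
  ft <- FeatureTable(m, "otu")
  # alpha = 1: every unordered pair of non-constant features is an edge
  full <- buildNetwork(ft, alpha = 1)
  expect_identical(nEdges(full), 10)
  expect_identical(sort(nodeTable(full)$name), paste0("f", 1:5))

  # constant feature participates in no edge but remains a node
  m2 <- rbind(m, const = 3)
  netc <- buildNetwork(FeatureTable(m2, "otu"), alpha = 1)
  expect_identical(nEdges(netc), 10)
  expect_true("const" %in% nodeTable(netc)$name)
  expect_identical(nodeTable(netc)$degree[nodeTable(netc)$name == "const"], 0)

  # edge set is monotone in alpha and every kept edge satisfies p <= alpha
  for (a in c(0.01, 0.05, 0.5)) {
    net <- buildNetwork(ft, alpha = a)
    expect_true(all(edgeTable(net)$p <= a))
    expect_true(nEdges(net) <= nEdges(full))
  }
  e1 <- nEdges(buildNetwork(ft, alpha = 0.01))
  e5 <- nEdges(buildNetwork(ft, alpha = 0.05))
  expect_true(e1 <= e5)
})

test_that("cross-table mode is symmetric and drops isolated features", {
  set.seed(11)
  a <- matrix(abs(rnorm(4 * 40, 10)), nrow = 4,
              dimnames = list(paste0("a", 1:4), paste0("s", 1:40)))
  b <- matrix(abs(rnorm(3 * 40, 10)), nrow = 3,
              dimnames = list(paste0("b", 1:3), paste0("s", 1:40)))
  b[1, ] <- a[1, ] + rnorm(40, sd = 0.1)       # strong cross edge
  ab <- buildNetwork(FeatureTable(a, "otu"), FeatureTable(b, "metabolite"))
  ba <- buildNetwork(FeatureTable(b, "metabolite"), FeatureTable(a, "otu"))
  eab <- edgeTable(ab); eba <- edgeTable(ba)
  canon <- function(e) {
    key <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b))
    e <- e[order(key), ]
    rownames(e) <- NULL
    e[, c("r", "p", "sign")]
  }
  expect_equal(canon(eab), canon(eba), tolerance = 1e-12)
  # only connected nodes are retained in cross mode
  nt <- nodeTable(ab)
  expect_true(all(nt$degree >= 1))
  expect_true(all(c("a1", "b1") %in% nt$name))
  # within-table pairs are never tested in cross mode
  expect_false(any(startsWith(eab$node_a, "a") & startsWith(eab$node_b, "a")))
})

test_that("planted latent factors are recovered with the right sign", {
  sim <- generateOtuTable(100, 20,
                          planted = data.frame(sign = c("pos", "neg"),
                                               r = 0.85),
                          dominance = 1, seed = 99)
  net <- buildNetwork(sim$table)
  et <- edgeTable(net)
  truth <- sim$truth$plantedEdges
  for (i in seq_len(nrow(truth))) {
    hit <- (et$node_a == truth$feature_a[i] & et$node_b == truth$feature_b[i]) |
           (et$node_b == truth$feature_a[i] & et$node_a == truth$feature_b[i])
    expect_true(any(hit))
    expect_identical(et$sign[hit], truth$sign[i])
  }
})

test_that("diversity-metabolite networks link orders to coupled metabolites", {
  sim <- generateOtuTable(30, 25, dominance = 1.3, seed = 5)
  prof <- diversityProfile(sim$table, 0:4)
  # one metabolite an exact positive function of q1, one exact negative of q2
  m <- rbind(metPos = 2 * prof[, "q1"], metNeg = max(prof[, "q2"]) + 1 -
               prof[, "q2"])
  met <- FeatureTable(m, "metabolite")
  dmn <- buildDMN(sim$table, met, q = 0:4)
  et <- edgeTable(dmn)
  posEdge <- et[(et$node_a == "q1" & et$node_b == "metPos") |
                (et$node_b == "q1" & et$node_a == "metPos"), ]
  negEdge <- et[(et$node_a == "q2" & et$node_b == "metNeg") |
                (et$node_b == "q2" & et$node_a == "metNeg"), ]
  expect_identical(posEdge$sign, "pos")
  expect_equal(posEdge$r, 1, tolerance = 1e-9)
  expect_identical(negEdge$sign, "neg")
  expect_equal(negEdge$r, -1, tolerance = 1e-9)
  kinds <- nodeTable(dmn)
  expect_setequal(unique(kinds$kind), c("diversity_order", "metabolite"))
})
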