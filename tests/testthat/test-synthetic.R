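test_that("generator output is bit-identical for identical seeds", {
  pl <- data.frame(sign = c("pos", "neg"), r = 0.8)
  a <- generateOtuTable(10, 20, pl, seed = 123)
  b <- generateOtuTable(10, 20, pl, seed = 123)
  expect_identical(abundances(a$table), abundances(b$table))
  expect_identical(a$truth, b$truth)
  c <- generateOtuTable(10, 20, pl, seed = 124)
  expect_false(identical(abundances(a$table), abundances(c$table)))

  s1 <- simulateMilkStudy(seed = 9)
  s2 <- simulateMilkStudy(seed = 9)
  expect_identical(abundances(s1$otu), abundances(s2$otu))
  expect_identical(abundances(s1$metabolites), abundances(s2$metabolites))
})

test_that("generated tables satisfy the FeatureTable invariants", {
  sim <- simulateMilkStudy(seed = 3)
  expect_true(validObject(sim$otu))
  expect_true(validObject(sim$metabolites))
  expect_identical(featureKind(sim$otu), "otu")
  expect_identical(featureKind(sim$metabolites), "metabolite")
  expect_identical(ncol(sim$otu), 25L)
  expect_setequal(names(sim$groups), sampleIds(sim$otu))
  expect_identical(as.integer(table(sim$groups)[c("pre", "post", "healthy")]),
                   c(8L, 8L, 9L))
  # every planted edge resolves against the emitted table
  expect_true(all(unlist(sim$truth$plantedEdges[, c("feature_a",
                                                    "feature_b")]) %in%
                  featureIds(sim$otu)))
  expect_error(generateOtuTable(10, 5,
    data.frame(sign = rep("pos", 4), r = 0.8)), "more planted")
})

test_that("dominance steepens the diversity profile", {
  ratios <- vapply(1:20, function(s) {
    hi <- diversityProfile(generateOtuTable(6, 40, dominance = 2.5,
                                            seed = s)$table)
    lo <- diversityProfile(generateOtuTable(6, 40, dominance = 0.8,
                                            seed = s)$table)
    c(hi = mean(hi[, "q2"] / hi[, "q0"]), lo = mean(lo[, "q2"] / lo[, "q0"]))
  }, numeric(2))
  expect_true(mean(ratios["hi", ]) < mean(ratios["lo", ]))
})

test_that("planted loadings hit their target correlation within sampling error", {
  devs <- vapply(1:20, function(s) {
    sim <- generateOtuTable(200, 10,
                            planted = data.frame(sign = "pos", r = 0.9),
                            dominance = 1, seed = s)
    m <- abundances(sim$table)
    cor(m["OTU_001", ], m["OTU_002", ])
  }, numeric(1))
  expect_true(all(abs(devs - 0.9) < 0.1))
})

test_that("diversity-coupled metabolites behave as specified", {
  sim <- generateOtuTable(40, 30, dominance = 1.5, seed = 21)
  d1 <- diversityProfile(sim$table, 1)[, "q1"]
  # noiseless coupling gives a perfect +/-1 correlation with q1
  met <- generateMetaboliteTable(sim$table,
    data.frame(name = c("up", "down"), sign = c("pos", "neg"), effect = 2),
    noiseSd = 0, seed = 22)
  m <- abundances(met$table)
  expect_equal(cor(m["up", ], d1), 1, tolerance = 1e-9)
  expect_equal(cor(m["down", ], d1), -1, tolerance = 1e-9)
  expect_true(all(m > 0))

  # a zero effect yields no significant diversity edge in most runs
  falseHits <- vapply(1:20, function(s) {
    otu <- generateOtuTable(30, 25, dominance = 1.5, seed = 300 + s)
    nul <- generateMetaboliteTable(otu$table,
      data.frame(name = "null", sign = "pos", effect = 0),
      noiseSd = 1, seed = 400 + s)
    dmn <- buildDMN(otu$table, nul$table, q = 1)
    nEdges(dmn) > 0
  }, logical(1))
  expect_lte(sum(falseHits), 2L)  # >= 90% of seeds edge-free
})
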