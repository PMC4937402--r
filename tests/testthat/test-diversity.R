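test_that("Hill numbers reproduce their closed-form special cases", {
  # equally abundant community: qD = S at every order
  expect_equal(hillNumber(rep(0.25, 4), q = c(0, 0.5, 1, 2, 4)),
               rep(4, 5), tolerance = 1e-12)
  # q = 0 is species richness
  expect_identical(hillNumber(c(0.5, 0.3, 0.2), 0), 3)
  # q = 2 is the reciprocal Simpson index: 1 / 0.38
  expect_equal(hillNumber(c(0.5, 0.3, 0.2), 2), 1 / 0.38,
               tolerance = 1e-12)
  # q = 1 limit: exp(ln 2)
  expect_equal(hillNumber(c(0.5, 0.5), 1), 2, tolerance = 1e-12)

  expect_error(hillNumber(numeric(), 1), "empty")
  expect_error(hillNumber(c(2, 3), 1), "sum to 1")
  expect_error(hillNumber(c(0.5, 0.5, 0), 1), "positive")
})

test_that("Hill identities and q-monotonicity hold on random abundance vectors", {
  set.seed(42)
  for (i in 1:25) {
    s <- sample(2:40, 1)
    p <- runif(s)^2
    p <- p / sum(p)
    qgrid <- sort(runif(6, 0, 5))
    d <- hillNumber(p, qgrid)
    # non-increasing in q, bounded by 1 and S
    expect_true(all(diff(d) <= 1e-9))
    expect_true(all(d >= 1 - 1e-9 & d <= s + 1e-9))
    # independent direct formulas
    expect_equal(hillNumber(p, 0), as.numeric(length(p)))
    expect_equal(hillNumber(p, 1), exp(-sum(p * log(p))), tolerance = 1e-10)
    expect_equal(hillNumber(p, 2), 1 / sum(p^2), tolerance = 1e-10)
    # near-1 orders route through the limit continuously
    expect_equal(hillNumber(p, 1 - 1e-7), hillNumber(p, 1),
                 tolerance = 1e-4)
  }
})

test_that("profiles drop zeros, scale-invariantly, and reject all-zero samples", {
  m <- cbind(even = c(10, 10, 10, 10), dom = c(97, 1, 1, 1))
  rownames(m) <- paste0("f", 1:4)
  pr <- diversityProfile(FeatureTable(m, "otu"), q = 0:4)
  expect_equal(unname(pr["even", ]), rep(4, 5))
  expect_identical(unname(pr["dom", "q0"]), 4)
  expect_true(pr["dom", "q4"] < pr["dom", "q1"] &&
              pr["dom", "q1"] < 4)
  # rescaling counts by a positive constant changes nothing
  expect_equal(diversityProfile(m * 17, q = 0:4), pr)
  # zero rows are dropped before computing
  expect_equal(diversityProfile(rbind(m, zero = c(0, 0)))["even", "q0"], 4)
  expect_error(diversityProfile(cbind(m, bad = 0)), "all-zero.*bad")
})

test_that("group means and pooled t-tests match hand computation", {
  prof <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
                 dimnames = list(paste0("s", 1:6), "q1"))
  groups <- setNames(rep(c("a", "b"), each = 3), rownames(prof))
  gm <- groupMeanProfile(prof, groups)
  expect_equal(gm["a", "q1"], 2)
  expect_equal(gm["b", "q1"], 11)
  # single-sample group mean equals the sample value
  one <- groupMeanProfile(prof[c(1, 4, 5), , drop = FALSE],
                          groups[c(1, 4, 5)])
  expect_equal(one["a", "q1"], 1)

  # textbook pooled-variance t on a worked example
  res <- compareGroupsT(prof, groups, "a", "b")
  sp2 <- (2 * var(1:3) + 2 * var(10:12)) / 4
  tManual <- (2 - 11) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, tManual, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(tManual), df = 4), tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  prof2 <- rbind(prof[1:3, , drop = FALSE],
                 matrix(1:3, ncol = 1, dimnames = list(paste0("t", 1:3), "q1")))
  g2 <- setNames(rep(c("a", "b"), each = 3), rownames(prof2))
  res2 <- compareGroupsT(prof2, g2, "a", "b")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  expect_error(compareGroupsT(prof[c(1, 4), , drop = FALSE],
                              groups[c(1, 4)], "a", "b"), "at least two")
})

test_that("bundled milk profiles reproduce the published group contrasts", {
  md <- milkDiversityData()
  gm <- groupMeanProfile(md$profiles, md$groups)
  expect_equal(round(gm["healthy", "q1"], 3), 19.238)
  expect_lte(abs(gm["pre", "q1"] - 8.856), 5e-4 + 1e-12)
  res <- compareGroupsT(md$profiles, md$groups, "healthy", "pre")
  expect_true(all(res$p < 0.001))
  # excluding the longitudinal baseline samples reproduces the
  # alternative q = 0 group means 54.857 / 53.857
  resEx <- compareGroupsT(md$profiles, md$groups, "pre", "post",
                          exclude = c("0A", "0B"))
  expect_equal(round(resEx$meanA[resEx$q == "q0"], 3), 54.857)
  expect_equal(round(resEx$meanB[resEx$q == "q0"], 3), 53.857)
})
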