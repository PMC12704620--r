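test_that("normalization rescales onto the simplex and rejects zeros", {
  expect_equal(normalizeMid(c(2, 2, 0)), c(0.5, 0.5, 0))
  expect_equal(normalizeMid(c(1, 0, 0)), c(1, 0, 0))
  set.seed(11)
  x <- runif(7)
  expect_lt(abs(sum(normalizeMid(x)) - 1), 1e-12)
  expect_error(normalizeMid(rep(0, 3)), "all-zero")
  expect_error(normalizeMid(c(-1, 2)), "non-negative")
})

test_that("MID convolution matches exhaustive isotopologue pairing", {
  # identity element and binomial case
  x <- c(0.2, 0.3, 0.5)
  expect_equal(convolveMids(c(1, 0), x)[1:3], x)
  expect_equal(sum(convolveMids(c(1, 0), x)), 1)
  expect_equal(convolveMids(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))

  set.seed(42)
  for (i in 1:20) {
    a <- randomMid(3)
    b <- randomMid(3)
    expect_equal(convolveMids(a, b), bruteConvolve(a, b), tolerance = 1e-12)
    expect_lt(abs(sum(convolveMids(a, b)) - 1), 1e-12)
  }
})

test_that("convolution is commutative and associative", {
  set.seed(7)
  for (i in 1:10) {
    a <- randomMid(2); b <- randomMid(3); c <- randomMid(4)
    expect_equal(convolveMids(a, b), convolveMids(b, a), tolerance = 1e-12)
    expect_equal(convolveMids(convolveMids(a, b), c),
                 convolveMids(a, convolveMids(b, c)), tolerance = 1e-12)
  }
})

test_that("hypergeometric marginalization matches subset enumeration", {
  expect_equal(marginalizeCarbons(c(1, 0, 0, 0), 2), c(1, 0, 0))
  # 2 of 3 carbons labeled, keep 2: subsets {12},{13},{23} -> 1/3 keep both
  expect_equal(marginalizeCarbons(c(0, 0, 1, 0), 2), c(0, 2/3, 1/3))
  expect_equal(marginalizeCarbons(c(0, 0, 0, 0, 1), 3), c(0, 0, 0, 1))

  set.seed(5)
  for (n in 3:6) {
    x <- randomMid(n)
    for (keep in seq_len(n - 1)) {
      expect_equal(marginalizeCarbons(x, keep), bruteMarginalize(x, keep),
                   tolerance = 1e-12)
    }
  }
  expect_error(marginalizeCarbons(c(0.5, 0.5), 1), "n_keep")
})

test_that("marginalization preserves mean enrichment exactly", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    keep <- sample(seq_len(n - 1), 1)
    x <- randomMid(n)
    expect_equal(meanEnrichment(marginalizeCarbons(x, keep)),
                 meanEnrichment(x), tolerance = 1e-12)
  }
})

test_that("natural-abundance correction inverts the forward smearing", {
  # p_nat = 0 reduces to normalization
  expect_equal(correctNaturalAbundance(c(2, 1, 1), 2, p_nat = 0),
               c(0.5, 0.25, 0.25))
  # closed-form pattern of an unlabeled 2-carbon compound
  p <- 0.0107
  raw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  expect_equal(correctNaturalAbundance(raw, 2, p), c(1, 0, 0),
               tolerance = 1e-9)
  # round trip through the forward matrix on random clean MIDs
  set.seed(3)
  for (n in c(3, 5, 6)) {
    x <- randomMid(n)
    C <- naturalAbundanceMatrix(n, p)
    expect_equal(correctNaturalAbundance(as.numeric(C %*% x), n, p), x,
                 tolerance = 1e-9)
  }
  expect_error(correctNaturalAbundance(c(1, 0), 1, p_nat = 0.6), "0.5")
})

test_that("forward smearing columns are probability vectors", {
  C <- naturalAbundanceMatrix(6, 0.0107)
  expect_equal(unname(colSums(C)), rep(1, 7), tolerance = 1e-12)
  expect_true(all(C >= 0))
})

test_that("mean enrichment implements both conventions", {
  expect_equal(meanEnrichment(c(1, 0, 0)), 0)
  expect_equal(meanEnrichment(c(0, 0, 1)), 1)
  expect_equal(meanEnrichment(c(0.25, 0.5, 0.25)), 0.5)
  x <- c(0.4, 0.6, 0)
  expect_equal(meanEnrichment(x, "labeled_fraction"), 0.6)
  expect_equal(meanEnrichment(x), 0.3)
})
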