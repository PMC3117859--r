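# Expression statistics: RPM, Poisson thresholds, clusters, Var/CV/DI/kappa.

test_that("RPM normalization is exact", {
  expect_identical(normalizeRpm(500, 1e6), 500)
  expect_identical(normalizeRpm(0, 1e6), 0)
  expect_equal(normalizeRpm(123, 7.5e6), 16.4)
  expect_error(normalizeRpm(1, 0), "mappedTotal")
})

test_that("Poisson threshold matches direct pmf summation", {
  # lambda = 0.1, alpha = 1e-4 -> T = 4 (oracle-verified)
  expect_identical(poissonThreshold(2e5, 1e8, window = 50,
                                    alpha = 1e-4), 4L)
  expect_identical(oraclePoissonThreshold(0.1, 1e-4), 4L)
  # limit case: lambda -> 0 gives T = 1
  expect_identical(poissonThreshold(1, 1e12, window = 50,
                                    alpha = 1e-4), 1L)
  for (lambda in c(0.01, 0.5, 1, 5, 20)) {
    for (alpha in c(1e-2, 1e-4)) {
      expect_identical(
        poissonThreshold(lambda * 1e6, 1e6 * 50, window = 50,
                         alpha = alpha),
        oraclePoissonThreshold(lambda, alpha),
        info = paste(lambda, alpha))
    }
  }
  expect_error(poissonThreshold(0, 1e6), "lambda")
  expect_error(poissonThreshold(10, 1e6, alpha = 0), "alpha")
})

test_that("Poisson threshold is monotone in alpha and lambda", {
  lams <- c(0.05, 0.2, 1, 3, 10)
  alphas <- c(1e-2, 1e-3, 1e-4, 1e-5)
  for (l in lams) {
    t <- vapply(alphas, function(a)
      poissonThreshold(l * 1e6, 5e7, alpha = a), integer(1))
    expect_true(all(diff(t) >= 0))     # non-increasing in alpha
  }
  for (a in alphas) {
    t <- vapply(lams, function(l)
      poissonThreshold(l * 1e6, 5e7, alpha = a), integer(1))
    expect_true(all(diff(t) >= 0))     # non-decreasing in lambda
  }
})

test_that("empirical threshold agrees with analytic on uniform reads", {
  genomeLength <- 1e6L
  nReads <- 20000L
  agree <- 0L
  nSeeds <- 25L
  tA <- poissonThreshold(nReads, genomeLength, window = 50)
  for (s in seq_len(nSeeds)) {
    set.seed(1000 + s)
    starts <- sample.int(genomeLength, nReads, replace = TRUE)
    tE <- poissonThreshold(genomeLength = genomeLength, window = 50,
                           mode = "empirical", readStarts = starts,
                           nBins = 50000L, seed = s)
    if (tE == tA) agree <- agree + 1L
  }
  expect_gte(agree / nSeeds, 0.95)
})

test_that("cluster definition chains loci by inclusive 10 kb gaps", {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 6001, 18002), width = 1),
    name = c("a", "b", "c"))
  cl <- defineClusters(gr, mid = 10000)
  # gaps 5 kb and 12 kb -> clusters {a,b} and {c}
  expect_identical(cl$cluster, c(1L, 1L, 2L))
  # gap of exactly 10000 stays in the same cluster (inclusive rule)
  gr2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 11001), width = 1),
    name = c("a", "b"))
  expect_identical(unique(defineClusters(gr2, 10000)$cluster), 1L)
  # 10001 separates
  gr3 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 11002), width = 1),
    name = c("a", "b"))
  expect_identical(defineClusters(gr3, 10000)$cluster, c(1L, 2L))
  # singleton
  expect_identical(nrow(defineClusters(gr2[1])), 1L)
})

test_that("cluster Var is the Jensen-Shannon divergence in bits", {
  m <- matrix(c(10, 30, 10, 30), ncol = 2,
              dimnames = list(c("x", "y"), c("A", "B")))
  expect_equal(clusterVar(m, "A", "B", pseudocount = 0), 0)
  # maximal divergence: disjoint member usage
  expect_equal(jsDivergence(c(1, 0), c(0, 1)), 1)
  # oracle-verified hand value for (0.5,0.5) vs (0.9,0.1)
  expect_equal(jsDivergence(c(0.5, 0.5), c(0.9, 0.1)),
               oracleJsdBits(c(0.5, 0.5), c(0.9, 0.1)))
  expect_equal(jsDivergence(c(0.5, 0.5), c(0.9, 0.1)), 0.14679,
               tolerance = 1e-4)
  # symmetry and boundedness over random cases
  set.seed(5)
  for (i in 1:50) {
    p <- runif(4); q <- runif(4)
    v1 <- jsDivergence(p, q); v2 <- jsDivergence(q, p)
    expect_equal(v1, v2)
    expect_gte(v1, 0); expect_lte(v1, 1)
  }
  expect_true(is.na(clusterVar(matrix(0, 2, 2,
    dimnames = list(NULL, c("A", "B"))), "A", "B")))
})

test_that("cluster CV matches arithmetic oracles", {
  expect_equal(clusterCv(matrix(c(100, 100, 100), 1)), 0)
  # degenerate one-member cluster on printed novel-miRNA counts
  expect_equal(clusterCv(matrix(c(11447, 24797, 14171), 1)), 0.4198,
               tolerance = 1e-3)
  expect_equal(clusterCv(matrix(c(0, 0, 10), 1)), sqrt(3))
  expect_true(is.na(clusterCv(matrix(0, 2, 3))))
})

test_that("differential index is the relative deviation and rows sum
           to zero", {
  m <- matrix(c(100, 100, 100, 90, 100, 110, 30, 60, 90),
              nrow = 3, byrow = TRUE)
  di <- diffIndex(m)
  expect_equal(di[1, ], c(0, 0, 0))
  expect_equal(di[2, ], c(-0.1, 0, 0.1))
  expect_equal(di[3, ], c(-0.5, 0, 0.5))
  set.seed(8)
  r <- matrix(rexp(60), 20)
  expect_equal(rowSums(diffIndex(r)), rep(0, 20), tolerance = 1e-12)
})

test_that("kappa agreement follows the formula and its invariances", {
  # perfect agreement with both classes present
  m <- cbind(A = c(rep(100, 5), rep(0, 5)),
             B = c(rep(100, 5), rep(0, 5)))
  expect_equal(kappaAgreement(m, "A", "B")$kappa, 1)
  # formula oracle: N=100, both call 80 expressed, overlap 70 -> Po=0.8
  a <- c(rep(40, 80), rep(0, 20))
  b <- c(rep(40, 70), rep(0, 10), rep(40, 10), rep(0, 10))
  ka <- kappaAgreement(cbind(A = a, B = b), "A", "B")
  expect_equal(ka$pe, 0.68)
  expect_equal(ka$kappa, 0.375)
  expect_equal(ka$z, 0.375 / sqrt(0.68 / (100 * 0.32)))
  # swapping the libraries leaves kappa unchanged
  expect_equal(kappaAgreement(cbind(A = a, B = b), "B", "A")$kappa,
               ka$kappa)
  # statistically independent calls give kappa near 0 on average
  set.seed(12)
  kap <- replicate(10, {
    ind <- cbind(A = sample(c(0, 100), 1000, replace = TRUE),
                 B = sample(c(0, 100), 1000, replace = TRUE))
    kappaAgreement(ind, "A", "B")$kappa
  })
  expect_lt(abs(mean(kap)), 0.05)
  expect_error(kappaAgreement(matrix(0, 0, 2,
    dimnames = list(NULL, c("A", "B"))), "A", "B"), "empty")
})

test_that("sharing summary reproduces the printed worked example", {
  s <- sharingSummary(304, c(326, 329, 326))
  expect_equal(s$percentShared, 100 * 304 / 329)
  expect_equal(round(s$percentShared, 1), 92.4)
  expect_error(sharingSummary(400, c(326, 329, 326)), "exceed")
})

test_that("consistency report runs end to end on a simulated study", {
  st <- smallStudy()
  se <- mirnaExpressionMatrix(truthCounts(st$truth),
                              rep(st$cfg@libraryDepth, 3))
  cl <- defineClusters(precursorLoci(st$truth))
  rep <- consistencyReport(se, cl, expressedThreshold = 30)
  expect_true(all(rep$var$var >= 0 & rep$var$var <= 1, na.rm = TRUE))
  expect_true(all(rep$cv$cv >= 0, na.rm = TRUE))
  expect_true(all(rep$kappa$kappa >= -1 & rep$kappa$kappa <= 1))
  expect_equal(unname(rowSums(rep$di)), rep(0, nrow(rep$di)),
               tolerance = 1e-12)
})
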