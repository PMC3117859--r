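# Target prediction, bipartite network, degree-dN/dS correlation,
# preferential-attachment null, rank-sum comparison and enrichment.

test_that("seed-match site types follow the canonical rules", {
  mir <- "AUCAAGUAGGCUACCUAGCUAG"     # seed (pos 2-8) = UCAAGUA
  hit8 <- predictSites(mir, "GGGTACTTGAAGGG")
  expect_identical(hit8$site_type, "8mer")
  hitM8 <- predictSites(mir, "GGGTACTTGAGGGG")
  expect_identical(hitM8$site_type, "7mer-m8")
  hitA1 <- predictSites(mir, "GGGGACTTGAAGGG")
  expect_identical(hitA1$site_type, "7mer-A1")
  expect_identical(nrow(predictSites(mir, "CCCCCCCCCCCC")), 0L)
  expect_error(predictSites("ACGUACG", "ACGT"), ">= 8")
})

test_that("conservation classification counts species at the aligned
           position", {
  mir <- "AUCAAGUAGGCUACCUAGCUAG"
  ref <- "GGGTACTTGAAGGG"
  site <- predictSites(mir, ref)
  mkAln <- function(nWith, nWithout) {
    rows <- c(list(ref), rep(list("GG-GTACTTGAAGG-G"), nWith - 1),
              rep(list("GGGTACAAAAAGG--G"), nWithout))
    # pad reference with gaps to the same width
    rows[[1]] <- "GGGTACTTGAAGG-G-"
    setNames(unlist(rows), paste0("sp", seq_along(rows)))
  }
  aln <- mkAln(4, 2)
  cc <- classifyConservation(site, aln, mir, minSpecies = 4)
  expect_true(cc$conserved)
  expect_identical(cc$nSpecies, 4L)
  expect_false(classifyConservation(site, aln, mir,
                                    minSpecies = 5)$conserved)
  # site only in the reference row
  alnRefOnly <- mkAln(1, 5)
  expect_false(classifyConservation(site, alnRefOnly, mir,
                                    minSpecies = 4)$conserved)
  # all six rows identical
  alnAll <- mkAln(6, 0)
  expect_true(classifyConservation(site, alnAll, mir,
                                   minSpecies = 6)$conserved)
})

test_that("network construction dedups edges and conserves degrees", {
  tt <- data.frame(mirna = c("m1", "m1", "m2", "m1"),
                   gene = c("g1", "g2", "g1", "g1"))
  net <- buildNetwork(tt)
  expect_identical(nrow(edgeTable(net)), 3L)
  expect_identical(unname(geneDegrees(net)["g1"]), 2L)
  expect_identical(sum(mirnaDegrees(net)), sum(geneDegrees(net)))
  expect_identical(sum(geneDegrees(net)), nrow(edgeTable(net)))
  # random tables: edge count equals distinct-pair count
  set.seed(3)
  rt <- data.frame(mirna = sample(paste0("m", 1:10), 200, TRUE),
                   gene = sample(paste0("g", 1:30), 200, TRUE))
  net2 <- buildNetwork(rt)
  expect_identical(nrow(edgeTable(net2)),
                   nrow(unique(rt[, c("mirna", "gene")])))
})

test_that("binned degree-dN/dS correlation detects exact linear decay", {
  # 5 degree values x 12 genes each, dnds exactly linear in degree
  genes <- sprintf("g%03d", 1:60)
  deg <- rep(1:5, each = 12)
  tt <- do.call(rbind, lapply(seq_along(genes), function(i)
    data.frame(mirna = paste0("m", seq_len(deg[i])), gene = genes[i])))
  ev <- data.frame(gene = genes, dnds = 0.5 - 0.05 * deg,
                   utr_length = 1000L)
  out <- degreeDndsCorrelation(buildNetwork(tt), ev,
                               minGenesPerBin = 10)
  expect_equal(out$r, -1)
  expect_identical(out$nBins, 5L)
  # the t-transform p-value for the printed correlation/bin pair
  r <- -0.564; df <- 15
  p <- 2 * pt(r * sqrt(df) / sqrt(1 - r^2), df)
  expect_equal(round(p, 3), 0.018)
  expect_error(degreeDndsCorrelation(buildNetwork(tt), ev,
                                     minGenesPerBin = 13), "3 degree")
})

test_that("per-kb degree normalization rescales before binning", {
  genes <- sprintf("g%03d", 1:60)
  deg <- rep(c(2, 4, 6), each = 20)
  tt <- do.call(rbind, lapply(seq_along(genes), function(i)
    data.frame(mirna = paste0("m", seq_len(deg[i])), gene = genes[i])))
  set.seed(21)
  ev <- data.frame(gene = genes, dnds = 0.5 - 0.05 * deg +
                     rnorm(60, 0, 0.01), utr_length = 2000L)
  net <- buildNetwork(tt)
  # per-1kb normalization halves the degrees (UTRs are 2 kb), so the
  # bins move from {2,4,6} to {1,2,3}; the relation is still negative
  d1 <- degreeDndsCorrelation(net, ev, minGenesPerBin = 5,
                              normalizePerKb = 1)
  expect_identical(d1$nBins, 3L)
  expect_lt(d1$r, -0.9)
  d2 <- degreeDndsCorrelation(net, ev, minGenesPerBin = 5,
                              normalizePerKb = 2)
  expect_lt(d2$r, -0.9)
  raw <- degreeDndsCorrelation(net, ev, minGenesPerBin = 5,
                               binned = FALSE)
  expect_identical(raw$n, 60L)
  expect_lt(raw$r, 0)
})

test_that("preferential-attachment null meets its contract and is
           heavier-tailed than uniform pairing", {
  net <- baRandomNetwork(50, 500, 1500, seed = 4)
  expect_identical(nrow(edgeTable(net)), 1500L)
  expect_identical(anyDuplicated(edgeTable(net)), 0L)
  expect_true(all(edgeTable(net)$mirna %in% mirnaNodes(net)))
  expect_identical(sum(mirnaDegrees(net)), 1500L)
  # determinism
  net2 <- baRandomNetwork(50, 500, 1500, seed = 4)
  expect_identical(edgeTable(net), edgeTable(net2))
  expect_error(baRandomNetwork(3, 3, 100), "infeasible")
  # heavier tail than Erdos-Renyi with same n, m in >= 90% of seeds
  erMax <- function(seed) {
    set.seed(seed)
    e <- unique(data.frame(m = sample(30, 600, TRUE),
                           g = sample(300, 600, TRUE)))
    while (nrow(e) < 600)
      e <- unique(rbind(e, data.frame(m = sample(30, 600 - nrow(e), TRUE),
                                      g = sample(300, 600 - nrow(e),
                                                 TRUE))))
    max(table(e$m))
  }
  wins <- 0L
  nSeeds <- 40L
  for (s in seq_len(nSeeds)) {
    ba <- baRandomNetwork(30, 300, 600, seed = s)
    if (max(mirnaDegrees(ba)) > erMax(10000 + s)) wins <- wins + 1L
  }
  expect_gte(wins / nSeeds, 0.9)
})

test_that("the preferential-attachment null has significantly lower
           degrees than a planted hub-bearing network", {
  for (s in 1:3) {
    tt <- generateTargetTable(50, 500, slope = -0.05, seed = 300 + s,
                              meanDegree = 3)
    net <- buildNetwork(tt$targets)
    ba <- baRandomNetwork(50, 500, nrow(edgeTable(net)), seed = 400 + s)
    w <- compareDegreeDistributions(mirnaDegrees(net), mirnaDegrees(ba))
    expect_lt(w$p, 0.05)
    expect_gt(median(mirnaDegrees(net)), median(mirnaDegrees(ba)))
  }
})

test_that("rank-sum comparison matches exact enumeration and the
           approximation agrees at the boundary", {
  expect_equal(compareDegreeDistributions(c(1, 2, 3), c(1, 2, 3))$p, 1)
  out <- compareDegreeDistributions(c(1, 2, 3), c(10, 11, 12))
  expect_identical(out$method, "exact")
  expect_equal(out$p, 0.1)
  expect_equal(out$p, oracleRankSumP(c(1, 2, 3), c(10, 11, 12)))
  # exact vs normal approximation within 0.02 at combined n = 12
  a <- c(1, 3, 5, 7, 9, 11); b <- c(2, 4, 6, 8, 10, 14)
  pE <- compareDegreeDistributions(a, b)$p
  pN <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))$p.value
  expect_lt(abs(pE - pN), 0.02)
  expect_equal(pE, oracleRankSumP(a, b))
  expect_error(compareDegreeDistributions(numeric(0), 1), "empty")
})

test_that("hypergeometric enrichment and BH correction match exact
           combinatorics", {
  uni <- paste0("g", 1:20)
  pw <- list(P = uni[1:5])
  res <- enrichment(uni[1:5], uni, pw)
  expect_equal(res$p, 1 / choose(20, 5))
  # overlap at expectation is unremarkable
  res2 <- enrichment(uni[1:8], uni, list(P = uni[c(1, 2, 9:12)]))
  ovAtExp <- res2$p
  expect_gt(ovAtExp, 0.5)
  # BH step-up on a known p-list
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(6)
  ps <- runif(20)
  expect_equal(p.adjust(ps, "BH"), oracleBH(ps))
  q <- oracleBH(ps)
  expect_true(all(q >= ps))                      # q >= raw p
  expect_true(all(diff(q[order(ps)]) >= -1e-12)) # monotone in p
  expect_error(enrichment("g1", character(0), pw), "empty")
})
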