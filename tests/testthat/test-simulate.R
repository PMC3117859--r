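# Synthetic-data generator: contracts, determinism, planted structure.

test_that("configuration invariants are enforced", {
  expect_error(simulationConfig(composition = c(mirna = 0.9,
                                                other_ncrna = 0.2,
                                                "repeat" = 0, exon = 0,
                                                intron = 0,
                                                unannotated = 0)),
               "sum to 1")
  expect_error(simulationConfig(index6 = c("ACGTAC", "ACGTAC", "GATCGA")),
               "distinct")
  expect_error(simulationConfig(nLibraries = 0L), "positive")
})

test_that("generated genomes honor the length contract and determinism", {
  cfg <- simulationConfig(seed = 3L, nChromosomes = 2L,
                          chromosomeLength = 50000L)
  g1 <- generateGenome(cfg)
  expect_length(g1$genome, 2L)
  expect_true(all(Biostrings::width(g1$genome) == 50000L))
  expect_false(any(grepl("[^ACGT]",
                         as.character(g1$genome))))
  g2 <- generateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  g3 <- generateGenome(simulationConfig(seed = 4L, nChromosomes = 2L,
                                        chromosomeLength = 50000L))
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))
  # annotation intervals are non-overlapping within each category
  ann <- g1$annotation
  for (cat in unique(S4Vectors::mcols(ann)$category)) {
    sub <- ann[S4Vectors::mcols(ann)$category == cat]
    expect_identical(
      sum(GenomicRanges::countOverlaps(sub, sub,
                                       ignore.strand = TRUE) > 1), 0L)
  }
})

test_that("planted precursors form clusters and fold into hairpins", {
  st <- smallStudy()
  gr <- precursorLoci(st$truth)
  mc <- S4Vectors::mcols(gr)
  # exactly one cluster of 3, members within the configured gap
  incl <- which(!is.na(mc$cluster))
  expect_length(incl, 3L)
  starts <- sort(GenomicRanges::start(gr)[incl])
  expect_true(all(diff(starts) <= 2 * st$cfg@clusterGapBases))
  # singletons >= 50 kb from anything else
  singles <- which(is.na(mc$cluster))
  for (s in singles) {
    d <- GenomicRanges::distance(gr[s], gr[-s], ignore.strand = TRUE)
    expect_true(all(d[!is.na(d)] >= 50000 - 200))
  }
  # every planted hairpin folds with >= 16 pairs and a single loop
  for (i in seq_along(gr)) {
    f <- foldRna(mc$hairpin[i])
    ev <- evaluateCandidate(f, mc$matureStart[i], mc$matureEnd[i])
    expect_true(ev$pass, info = mc$precursor_id[i])
    expect_gte(lengths(regmatches(f$structure,
                                  gregexpr("\\(", f$structure))), 16)
  }
  # mature sequence is strand-correct: the genomic subsequence on "-"
  # strand precursors is the reverse complement of the stored hairpin
  neg <- which(as.character(GenomicRanges::strand(gr)) == "-")
  if (length(neg)) {
    i <- neg[1]
    sub <- as.character(Biostrings::subseq(
      st$genome[[as.character(GenomicRanges::seqnames(gr)[i])]],
      GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
    expect_identical(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub))), mc$hairpin[i])
  }
})

test_that("simulated libraries are deterministic, depth-conserving and
           composition-faithful", {
  st <- smallStudy()
  cfg <- st$cfg
  # determinism: regenerating with the same seed reproduces the reads
  st2 <- simulateStudy(cfg)
  expect_identical(st$reads, st2$reads)
  expect_identical(truthCounts(st$truth), truthCounts(st2$truth))
  # conservation: per-category truth counts sum exactly to the depth
  cc <- truthCategoryCounts(st$truth)
  expect_true(all(colSums(cc) == cfg@libraryDepth))
  # raw reads are fixed-length
  expect_true(all(nchar(unlist(st$reads)) == cfg@readLength))
  # miRNA composition close to configured fraction at this depth
  frac <- cc["mirna", ] / cfg@libraryDepth
  expect_true(all(abs(frac - 0.60) < 0.03))
})

test_that("zero between-library noise gives identical true proportions", {
  cfg <- smallConfig(seed = 5L, betweenLibraryNoise = 0)
  g <- generateGenome(cfg)
  p <- plantPrecursors(g, cfg)
  ab <- p$truth@abundance
  expect_true(all(ab[, 1] == ab[, 2]) && all(ab[, 2] == ab[, 3]))
})

test_that("insert length histogram peaks at 22-23 nt", {
  st <- smallStudy()
  pp <- preprocessReads(st$reads, st$indexMap, st$cfg@adapter3)
  h <- lengthHistogram(pp$tags)
  expect_true(names(h)[which.max(h)] %in% c("22", "23"))
})

test_that("target tables plant the requested degree-dN/dS relation", {
  tt <- generateTargetTable(30, 0, slope = -0.02, seed = 1)
  expect_identical(nrow(tt$targets), 0L)        # empty case, no error
  tt <- generateTargetTable(30, 400, slope = -0.02, seed = 1)
  deg <- table(tt$targets$gene)
  ev <- tt$geneEvolution
  d <- as.integer(deg[ev$gene]); d[is.na(d)] <- 0L
  # expected dN/dS decreases with degree; 3'UTR independent of dN/dS
  expect_lt(cor(d, ev$dnds), 0)
  expect_lt(abs(cor(ev$utr_length, ev$dnds)), 0.15)
})

test_that("the packaged novel-miRNA reference table matches its source", {
  t1 <- loadTable1Fixture()
  expect_identical(nrow(t1), 23L)
  expect_identical(length(unique(t1$group)), 19L)
  m744 <- t1[t1$name == "miR-744-5p", ]
  expect_identical(as.integer(m744[, grep("^reads_", names(t1))]),
                   c(11447L, 24797L, 14171L))
  m1843 <- t1[t1$name == "miR-1843-5p", ]
  expect_identical(m1843$precursor_location,
                   "chr1:205580537-205580616:-")
  # one name with two printed loci stays a single precursor group
  expect_identical(sum(t1$group == "miR-1185"), 1L)
})
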