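# Mapping, known-miRNA quantification and category priority rules.

.toyGenome <- function() {
  set.seed(9)
  base <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
  Biostrings::DNAStringSet(c(chrT = base))
}

test_that("exact mapping finds forward, reverse and absent tags", {
  genome <- .toyGenome()
  fwd <- as.character(Biostrings::subseq(genome[[1]], 101, 122))
  rcv <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(genome[[1]], 201, 222)))
  absent <- strrep("ACGT", 6)   # vanishingly unlikely in 500 nt
  mp <- mapTags(c(fwd, rcv, absent), genome)
  al <- mp$alignments
  mc <- S4Vectors::mcols(al)
  fHit <- al[mc$tag == fwd]
  expect_identical(as.character(GenomicRanges::strand(fHit)), "+")
  expect_identical(GenomicRanges::start(fHit), 101L)
  expect_identical(GenomicRanges::end(fHit), 122L)
  rHit <- al[mc$tag == rcv]
  expect_identical(as.character(GenomicRanges::strand(rHit)), "-")
  expect_identical(GenomicRanges::start(rHit), 201L)
  expect_true(absent %in% mp$unmapped)
  # reported aligned substring equals the tag (exact-match contract)
  expect_identical(
    as.character(Biostrings::subseq(genome[[1]], 101, 122)), fwd)
})

test_that("known-miRNA quantification follows identity, multi-precursor
           and loop-shift rules", {
  arm5 <- "ACGTGACGTGACGTGACGTGAC"               # 22 nt
  loop <- "TTTTTTTT"
  hp <- paste0(arm5, loop,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(arm5))))
  ref <- data.frame(
    precursor_id = c("p1", "p2"), sequence = c(hp, hp),
    mature_id = c("m1-5p", "m2-5p"), matureStart = 1L,
    matureEnd = 22L, stringsAsFactors = FALSE)
  loopTag <- substr(hp, 19, 40)  # spans the loop, shift 18 from arm
  tags <- list(L1 = data.frame(sequence = c(arm5, loopTag),
                               count = c(7L, 5L)))
  se <- quantifyKnown(tags, ref)
  cnt <- SummarizedExperiment::assay(se, "counts")
  # identical paralog precursors both receive the tag count
  expect_identical(cnt["m1-5p", "L1"], 7L)
  expect_identical(cnt["m2-5p", "L1"], 7L)
  # loop-overlapping tag (shift > 4) is not counted anywhere
  expect_identical(sum(cnt), 14L)
  # within-shift tag counts; beyond-shift does not
  shifted <- substr(hp, 4, 25)
  far <- substr(hp, 7, 28)
  se2 <- quantifyKnown(list(L1 = data.frame(
    sequence = c(shifted, far), count = c(2L, 3L))), ref[1, ])
  expect_identical(SummarizedExperiment::assay(se2)[1, 1], 2L)
  # records without mature annotation are skipped with a warning
  refNA <- ref; refNA$matureStart[2] <- NA
  expect_warning(quantifyKnown(tags, refNA), "skipped")
})

test_that("category priority resolves multi-category tags", {
  tagA <- strrep("ACGTT", 5)
  mkAln <- function(tag, starts, strands = "+") GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, width = nchar(tag)), strands,
    tag = tag, n_hits = length(starts))
  tracks <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(100, 100, 300, 300, 500), width = 100),
    c("+", "+", "*", "*", "+"),
    category = c("tRNA", "known_miRNA", "exon", "intron", "rRNA"),
    source = c("rfam", "n/a", "n/a", "n/a", "genbank"))
  # tRNA (Rfam) beats known miRNA
  calls <- assignCategories(mkAln(tagA, 120), tracks)
  expect_identical(calls$category, "tRNA")
  expect_identical(calls$source, "rfam")
  # Genbank beats Rfam within the ncRNA tier (multi-hit tag)
  calls <- assignCategories(mkAln(tagA, c(120, 520)), tracks)
  expect_identical(calls$category, "rRNA")
  expect_identical(calls$source, "genbank")
  # exon beats intron at the same locus (strand-blind)
  calls <- assignCategories(mkAln(tagA, 320, "-"), tracks)
  expect_identical(calls$category, "exon")
  # miRNA overlap is strand-aware: antisense tag falls through to unann
  calls <- assignCategories(mkAln(tagA, 120, "-"), tracks)
  expect_identical(calls$category, "unann")
  # no overlap anywhere
  calls <- assignCategories(mkAln(tagA, 900), tracks)
  expect_identical(calls$category, "unann")
  expect_error(
    assignCategories(mkAln(tagA, 120), GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(1, 10), "+", category = "mystery",
      source = "n/a")),
    "unknown category")
})

test_that("each mapped tag gets exactly one category (partition)", {
  st <- smallStudy()
  pp <- preprocessReads(st$reads, st$indexMap, st$cfg@adapter3)
  allTags <- unique(unlist(lapply(pp$tags, `[[`, "sequence")))
  mp <- mapTags(allTags, st$genome)
  tracks <- c(st$annotation,
              knownMirnaTrack(st$truth)[, c("category", "source")])
  calls <- assignCategories(mp$alignments, tracks)
  mapped <- unique(S4Vectors::mcols(mp$alignments)$tag)
  expect_identical(sort(calls$tag), sort(mapped))
  expect_identical(anyDuplicated(calls$tag), 0L)
})

test_that("length histogram weights by count and handles empty input", {
  df <- data.frame(sequence = strrep("A", 22), count = 5L)
  expect_identical(lengthHistogram(df), c(`22` = 5L))
  expect_identical(lengthHistogram(
    data.frame(sequence = character(0), count = integer(0))), integer(0))
})
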