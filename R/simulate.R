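# Synthetic small RNA-seq study generator with planted ground truth.
#
# The generator emulates the statistical structure of a multiplexed
# three-library ESC small-RNA profiling experiment: 35 nt raw reads
# (6 nt index + insert + 3' adapter fill), clean-read lengths peaking at
# 22-23 nt, ~60% of reads from known miRNA hairpins, <15% from other
# annotated RNA classes and ~25% unannotated (novel hairpins + intergenic
# background), log-normal miRNA abundances spanning several orders of
# magnitude, and high concordance between libraries.

.insertLenProbs <- c(`18` = 0.03, `19` = 0.05, `20` = 0.10, `21` = 0.17,
                     `22` = 0.35, `23` = 0.30)

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a simulation configuration
#'
#' Constructor for \linkS4class{SimulationConfig} with defaults emulating a
#' three-library primate ESC profiling study. See the class documentation
#' for the meaning of each field.
#'
#' @param seed integer master seed; every generator operation derives its
#'   stream from it, so identical seeds give byte-identical outputs.
#' @param nChromosomes,chromosomeLength,nPrecursors,nClusters,clusterGapBases
#'   genome and planted-locus geometry.
#' @param libraryDepth,nLibraries sequencing depth and multiplexing.
#' @param composition named read-category fractions summing to 1.
#' @param novelFraction fraction of precursors withheld from the known
#'   annotation (their reads land in the unannotated pool).
#' @param expressionDispersion log10 SD of planted abundances (heavy-tailed
#'   counts over a wide dynamic range).
#' @param betweenLibraryNoise multiplicative log-normal noise SD between
#'   libraries (0 = identical true proportions).
#' @param adapter5,adapter3,index6,readLength library chemistry layout.
#' @return a validated \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, libraryDepth = 2e4)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 4L,
                             chromosomeLength = 700000L,
                             nPrecursors = 28L,
                             nClusters = 2L,
                             clusterGapBases = 5000L,
                             libraryDepth = 100000L,
                             nLibraries = 3L,
                             composition = c(mirna = 0.60,
                                             other_ncrna = 0.06,
                                             "repeat" = 0.03,
                                             exon = 0.03,
                                             intron = 0.03,
                                             unannotated = 0.25),
                             novelFraction = 0.3,
                             expressionDispersion = 1.0,
                             betweenLibraryNoise = 0.15,
                             adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                             adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                             index6 = c("ACGTAC", "TGCAGT", "GATCGA",
                                        "CTAGCT", "GTACGA", "TCATGC")[
                                          seq_len(nLibraries)],
                             readLength = 35L) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("configuration error: composition fractions must sum to 1")
  new("SimulationConfig",
      seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      chromosomeLength = as.integer(chromosomeLength),
      nPrecursors = as.integer(nPrecursors),
      nClusters = as.integer(nClusters),
      clusterGapBases = as.integer(clusterGapBases),
      libraryDepth = as.integer(libraryDepth),
      nLibraries = as.integer(nLibraries),
      composition = composition[.CATEGORIES],
      novelFraction = novelFraction,
      expressionDispersion = expressionDispersion,
      betweenLibraryNoise = betweenLibraryNoise,
      adapter5 = adapter5, adapter3 = adapter3,
      index6 = index6,
      readLength = as.integer(readLength))
}

# Annotation interval blueprint: length and database source per category.
.trackSpecs <- data.frame(
  category = c("rRNA", "tRNA", "scRNA", "snRNA", "snoRNA",
               "repeat", "exon", "intron"),
  len = c(500L, 90L, 150L, 120L, 100L, 400L, 500L, 900L),
  source = c("genbank", "genbank", "rfam", "rfam", "genbank",
             "n/a", "n/a", "n/a"),
  stringsAsFactors = FALSE
)

#' Generate a random genome with non-miRNA annotation tracks
#'
#' Draws one uniform-random DNA sequence per chromosome and lays down
#' non-overlapping annotation intervals (rRNA, tRNA, scRNA, snRNA, snoRNA,
#' repeat, exon, intron) in the first ~40\% of each chromosome, leaving the
#' remainder free for planted precursors and intergenic background.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{genome} (\link[Biostrings]{DNAStringSet}) and
#'   \code{annotation} (\link[GenomicRanges]{GRanges} with metadata columns
#'   \code{category} and \code{source}; ncRNA intervals stranded, others
#'   unstranded).
#' @export
generateGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  L <- config@chromosomeLength
  chroms <- paste0("chr", seq_len(config@nChromosomes))
  seqs <- vapply(chroms, function(ch) .randomDna(L), character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms

  ann <- list()
  for (ch in chroms) {
    pos <- 2000L
    limit <- as.integer(0.40 * L)
    k <- 0L
    while (pos < limit) {
      spec <- .trackSpecs[(k %% nrow(.trackSpecs)) + 1L, ]
      end <- pos + spec$len - 1L
      if (end >= limit) break
      strand <- if (spec$source == "n/a") "*" else sample(c("+", "-"), 1)
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = ch, start = pos, end = end, strand = strand,
        category = spec$category, source = spec$source)
      pos <- end + sample(200:500, 1)
      k <- k + 1L
    }
  }
  ann <- do.call(rbind, ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand,
    category = ann$category, source = ann$source)
  GenomeInfoDb::seqlevels(gr) <- chroms
  list(genome = genome, annotation = gr)
}

# Draw a random mature 5' arm that cannot collide with adapter trimming.
.drawArm <- function(len, forbidden) {
  repeat {
    arm <- .randomDna(len)
    if (!grepl(forbidden, arm, fixed = TRUE) &&
        !grepl(forbidden, .revcomp(arm), fixed = TRUE))
      return(arm)
  }
}

# Introduce nMismatch point substitutions that break Watson-Crick pairing.
.mutate <- function(seq, nMismatch) {
  if (nMismatch == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  idx <- sample(seq_along(chars), nMismatch)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Plant miRNA precursor hairpins into a genome
#'
#' Writes \code{nPrecursors} hairpin sequences into the genome: each is an
#' 8 nt lower stem, a 21-23 nt mature arm, a 6-12 nt loop and the
#' reverse-complemented arm carrying 0-2 mismatches, so the 5' arm and the
#' reverse complement of the 3' arm form well over 16 Watson-Crick pairs
#' and any folding engine recovers a single hairpin. \code{nClusters}
#' groups of three consecutive precursors are placed within
#' \code{clusterGapBases} of each other; all remaining precursors sit at
#' least 50 kb from any other planted locus. A \code{novelFraction} of
#' precursors is marked unknown (excluded from the known annotation) to
#' exercise novel-miRNA discovery.
#'
#' Mature-arm lengths are tied to abundance rank so that the dominant
#' expressed species are 22-23 nt, matching the observed clean-read length
#' mode; low-abundance precursors may carry 21 nt arms.
#'
#' @param genomeSet list returned by [generateGenome()].
#' @param config the \linkS4class{SimulationConfig} used to generate it.
#' @return list with the modified \code{genome}, the unchanged
#'   \code{annotation}, and \code{truth}, a \linkS4class{GroundTruth}
#'   holding the precursor loci and per-library true abundances.
#' @export
plantPrecursors <- function(genomeSet, config) {
  set.seed(config@seed + 1L)
  genome <- genomeSet$genome
  L <- config@chromosomeLength
  chroms <- names(genome)
  n <- config@nPrecursors
  if (config@nClusters * 3L > n)
    stop("placement error: nClusters * 3 exceeds nPrecursors")

  # One slot per planted unit (cluster or singleton); slot spacing leaves
  # >= 50 kb between a full cluster extent and the next locus.
  zoneStart <- as.integer(0.45 * L)
  spacing <- 50000L + 2L * config@clusterGapBases + 1000L
  slotsPerChrom <- max(0L, (L - 2000L - zoneStart) %/% spacing)
  slots <- expand.grid(chrom = chroms, i = seq_len(slotsPerChrom),
                       stringsAsFactors = FALSE)
  slots$pos <- zoneStart + (slots$i - 1L) * spacing
  nUnits <- config@nClusters + (n - 3L * config@nClusters)
  if (nUnits > nrow(slots))
    stop("placement error: genome too small to place precursors ",
         ">= 50 kb apart; enlarge chromosomes or reduce nPrecursors")
  slots <- slots[sample(nrow(slots), nUnits), , drop = FALSE]

  # Abundance ranks decide arm length: dominant species are 22-23 nt.
  baseAbundance <- 10 ^ rnorm(n, 0, config@expressionDispersion)
  rk <- rank(-baseAbundance, ties.method = "first")
  armLens <- integer(n)
  armLens[rk] <- rep(c(22L, 23L), length.out = n)
  lowRanks <- which(rk > ceiling(0.7 * n))
  if (length(lowRanks))
    armLens[sample(lowRanks, max(1L, length(lowRanks) %/% 3L))] <- 21L

  adapter6 <- substr(config@adapter3, 1L, 6L)
  recs <- list()
  seqs <- as.character(genome)
  unit <- 0L
  pid <- 0L
  clusterOf <- c(rep(seq_len(config@nClusters), each = 3L),
                 rep(NA_integer_, n - 3L * config@nClusters))
  for (u in seq_len(nUnits)) {
    isCluster <- u <= config@nClusters
    nMembers <- if (isCluster) 3L else 1L
    pos <- slots$pos[u]
    ch <- slots$chrom[u]
    for (m in seq_len(nMembers)) {
      pid <- pid + 1L
      armLen <- armLens[pid]
      loopLen <- sample(6:12, 1)
      ext <- .randomDna(8L)
      arm5 <- .drawArm(armLen, adapter6)
      nMm <- sample(0:2, 1)
      arm3 <- .mutate(.revcomp(arm5), nMm)
      loop <- .randomDna(loopLen)
      hairpin <- paste0(ext, arm5, loop, arm3, .revcomp(ext))
      hlen <- nchar(hairpin)
      strand <- sample(c("+", "-"), 1)
      arm <- sample(c("5p", "3p"), 1)
      if (arm == "5p") {
        mStart <- 9L; mEnd <- 8L + armLen; mature <- arm5
      } else {
        mStart <- 8L + armLen + loopLen + 1L
        mEnd <- mStart + armLen - 1L
        mature <- arm3
      }
      written <- if (strand == "+") hairpin else .revcomp(hairpin)
      substr(seqs[ch], pos, pos + hlen - 1L) <- written
      recs[[pid]] <- data.frame(
        chrom = ch, start = pos, end = pos + hlen - 1L, strand = strand,
        precursor_id = sprintf("pre-%03d", pid),
        hairpin = hairpin, mature = mature, arm = arm,
        matureStart = mStart, matureEnd = mEnd,
        cluster = clusterOf[pid], stringsAsFactors = FALSE)
      if (isCluster && m < nMembers)
        pos <- pos + hlen + sample(seq(500L, config@clusterGapBases - hlen),
                                   1)
    }
  }
  recs <- do.call(rbind, recs)
  nKnown <- round((1 - config@novelFraction) * n)
  known <- logical(n)
  known[sample(n, nKnown)] <- TRUE
  recs$known <- known
  recs$name <- sprintf("sim-miR-%03d-%s", seq_len(n), recs$arm)

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  gr <- GenomicRanges::GRanges(
    seqnames = recs$chrom, ranges = IRanges::IRanges(recs$start, recs$end),
    strand = recs$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    recs[c("precursor_id", "name", "hairpin", "mature", "arm",
           "matureStart", "matureEnd", "known", "cluster")])
  GenomeInfoDb::seqlevels(gr) <- chroms

  # Per-library true abundance with multiplicative between-library noise.
  ab <- matrix(baseAbundance, nrow = n, ncol = config@nLibraries)
  if (config@betweenLibraryNoise > 0)
    ab <- ab * exp(matrix(rnorm(n * config@nLibraries, 0,
                                config@betweenLibraryNoise), nrow = n))
  rownames(ab) <- recs$name
  colnames(ab) <- paste0("lib", seq_len(config@nLibraries))

  truth <- new("GroundTruth", precursors = gr, abundance = ab,
               counts = matrix(0L, 0, 0),
               categoryCounts = matrix(0L, 0, 0),
               targets = data.frame(), geneEvolution = data.frame())
  list(genome = genome, annotation = genomeSet$annotation, truth = truth)
}

#' Known-miRNA annotation track of a simulated study
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @return GRanges of the planted precursors flagged as known, with
#'   \code{category = "known_miRNA"}; suitable as the miRNA locus track for
#'   [assignCategories()].
#' @export
knownMirnaTrack <- function(truth) {
  gr <- truth@precursors[S4Vectors::mcols(truth@precursors)$known]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    category = rep("known_miRNA", length(gr)),
    source = rep("n/a", length(gr)),
    precursor_id = S4Vectors::mcols(gr)$precursor_id)
  gr
}

#' Reference precursor set of a simulated study
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param known keep only precursors present in the known annotation.
#' @return data.frame with one row per precursor: \code{precursor_id},
#'   \code{sequence} (hairpin), \code{mature_id}, \code{matureStart},
#'   \code{matureEnd} (1-based inclusive, precursor orientation) -- the
#'   miRBase-style reference consumed by [quantifyKnown()].
#' @export
precursorReference <- function(truth, known = TRUE) {
  mc <- S4Vectors::mcols(truth@precursors)
  keep <- if (known) mc$known else rep(TRUE, length(truth@precursors))
  data.frame(precursor_id = mc$precursor_id[keep],
             sequence = mc$hairpin[keep],
             mature_id = mc$name[keep],
             matureStart = mc$matureStart[keep],
             matureEnd = mc$matureEnd[keep],
             stringsAsFactors = FALSE)
}

# Sample fragment inserts from a set of annotation intervals (strand-aware,
# vectorized).
.sampleFragments <- function(n, intervals, seqs, lens, weights = NULL) {
  if (n == 0L) return(character(0))
  idx <- sample(seq_along(intervals$start), n, replace = TRUE,
                prob = weights)
  w <- intervals$end[idx] - intervals$start[idx] + 1L
  l <- pmin(lens, w)
  off <- as.integer(floor(runif(n) * (w - l + 1L)))
  s <- intervals$start[idx] + off
  frag <- substring(seqs[intervals$chrom[idx]], s, s + l - 1L)
  neg <- !is.na(intervals$strand[idx]) & intervals$strand[idx] == "-"
  if (any(neg)) frag[neg] <- .revcomp(frag[neg])
  frag
}

#' Simulate multiplexed 35 nt small RNA sequencing libraries
#'
#' Draws \code{libraryDepth} reads per library. Each read is the library's
#' 6 nt index, an insert, and enough of the 3' adapter to fill the raw read
#' length. Insert categories follow the configured composition
#' (multinomial, so per-category truth counts sum exactly to the depth):
#' miRNA reads are exact mature sequences of known precursors sampled
#' proportionally to the planted log-normal abundances; other-ncRNA,
#' repeat, exon and intron reads are random fragments of the corresponding
#' annotation intervals; the unannotated pool is split between mature
#' products of the withheld (novel) precursors and uniform intergenic
#' fragments.
#'
#' @param planted list from [plantPrecursors()] (genome + annotation +
#'   truth).
#' @param config the \linkS4class{SimulationConfig}.
#' @param novelShare fraction of the unannotated pool drawn from novel
#'   precursor mature products (rest is intergenic background).
#' @param outdir optional directory; if given, one FASTQ per library is
#'   written (\code{libN.fastq}, constant Q40 qualities).
#' @return list with \code{reads} (list of character vectors of raw reads
#'   per library), \code{truth} (GroundTruth with realized \code{counts}
#'   and \code{categoryCounts} filled in), and \code{indexMap} (named
#'   vector index -> library id).
#' @export
simulateLibraries <- function(planted, config, novelShare = 0.3,
                              outdir = NULL) {
  set.seed(config@seed + 2L)
  if (config@libraryDepth < 1000L)
    warning("library depth < 1000: downstream statistics will be unstable")
  truth <- planted$truth
  genome <- planted$genome
  seqs <- as.character(genome)
  mc <- S4Vectors::mcols(truth@precursors)
  comp <- config@composition
  depth <- config@libraryDepth
  nLib <- config@nLibraries
  libIds <- paste0("lib", seq_len(nLib))

  ann <- planted$annotation
  annDf <- data.frame(chrom = as.character(GenomicRanges::seqnames(ann)),
                      start = GenomicRanges::start(ann),
                      end = GenomicRanges::end(ann),
                      strand = as.character(GenomicRanges::strand(ann)),
                      category = S4Vectors::mcols(ann)$category,
                      stringsAsFactors = FALSE)
  # Intergenic space: outside annotation and planted loci, with margin.
  occupied <- GenomicRanges::reduce(c(
    GenomicRanges::granges(ann) + 200L,
    GenomicRanges::granges(truth@precursors) + 200L),
    ignore.strand = TRUE)
  full <- GenomicRanges::GRanges(
    names(genome), IRanges::IRanges(1L, Biostrings::width(genome)))
  interg <- GenomicRanges::setdiff(full, occupied, ignore.strand = TRUE)
  interg <- interg[GenomicRanges::width(interg) >= 40L]
  intergDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(interg)),
    start = GenomicRanges::start(interg), end = GenomicRanges::end(interg),
    strand = NA_character_, stringsAsFactors = FALSE)
  intergW <- intergDf$end - intergDf$start + 1L

  lens <- as.integer(names(.insertLenProbs))
  drawLens <- function(n) sample(lens, n, replace = TRUE,
                                 prob = .insertLenProbs)

  knownIdx <- which(mc$known)
  novelIdx <- which(!mc$known)
  counts <- matrix(0L, nrow = length(truth@precursors), ncol = nLib,
                   dimnames = list(mc$name, libIds))
  catCounts <- matrix(0L, nrow = length(.CATEGORIES), ncol = nLib,
                      dimnames = list(.CATEGORIES, libIds))
  reads <- vector("list", nLib)
  names(reads) <- libIds

  for (l in seq_len(nLib)) {
    nCat <- as.vector(rmultinom(1, depth, comp[.CATEGORIES]))
    names(nCat) <- .CATEGORIES
    catCounts[, l] <- nCat
    inserts <- character(0)

    # known miRNA mature products
    if (length(knownIdx) && nCat["mirna"] > 0) {
      p <- truth@abundance[knownIdx, l]
      ck <- as.vector(rmultinom(1, nCat["mirna"], p / sum(p)))
      counts[knownIdx, l] <- counts[knownIdx, l] + ck
      inserts <- c(inserts, rep(mc$mature[knownIdx], ck))
    }
    # other annotated classes
    for (cat in c("other_ncrna", "repeat", "exon", "intron")) {
      nc <- nCat[cat]
      if (nc == 0) next
      cats <- if (cat == "other_ncrna") .NCRNA_SUBTYPES else cat
      iv <- annDf[annDf$category %in% cats, , drop = FALSE]
      inserts <- c(inserts, .sampleFragments(nc, iv, seqs, drawLens(nc)))
    }
    # unannotated: novel precursor products + intergenic background
    nu <- nCat["unannotated"]
    if (nu > 0) {
      split <- as.vector(rmultinom(1, nu, c(novelShare, 1 - novelShare)))
      if (length(novelIdx) && split[1] > 0) {
        p <- truth@abundance[novelIdx, l]
        cn <- as.vector(rmultinom(1, split[1], p / sum(p)))
        counts[novelIdx, l] <- counts[novelIdx, l] + cn
        inserts <- c(inserts, rep(mc$mature[novelIdx], cn))
      } else split[2] <- nu
      if (split[2] > 0) {
        iv <- intergDf
        iv$strand <- NA_character_
        frag <- .sampleFragments(split[2], iv, seqs, drawLens(split[2]),
                                 weights = intergW)
        flip <- runif(split[2]) < 0.5
        if (any(flip)) frag[flip] <- .revcomp(frag[flip])
        inserts <- c(inserts, frag)
      }
    }
    adapterFill <- strrep(config@adapter3,
                          ceiling(config@readLength / nchar(config@adapter3)))
    raw <- paste0(config@index6[l], inserts,
                  substring(adapterFill, 1L,
                            config@readLength - 6L - nchar(inserts)))
    reads[[l]] <- sample(raw)
  }

  truth@counts <- counts
  truth@categoryCounts <- catCounts
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (l in seq_len(nLib)) {
      x <- Biostrings::DNAStringSet(reads[[l]])
      names(x) <- sprintf("read%07d", seq_along(x))
      Biostrings::writeXStringSet(
        x, file.path(outdir, paste0(libIds[l], ".fastq")), format = "fastq",
        qualities = Biostrings::BStringSet(
          rep(strrep("I", config@readLength), length(x))))
    }
  }
  list(reads = reads, truth = truth,
       indexMap = setNames(libIds, config@index6))
}

#' Run the full generator
#'
#' Convenience wrapper: [generateGenome()], [plantPrecursors()],
#' [simulateLibraries()] in sequence.
#'
#' @inheritParams simulateLibraries
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{genome}, \code{annotation}, \code{truth},
#'   \code{reads}, \code{indexMap}.
#' @export
simulateStudy <- function(config, novelShare = 0.3, outdir = NULL) {
  g <- generateGenome(config)
  p <- plantPrecursors(g, config)
  s <- simulateLibraries(p, config, novelShare = novelShare,
                         outdir = outdir)
  list(genome = p$genome, annotation = p$annotation, truth = s$truth,
       reads = s$reads, indexMap = s$indexMap)
}

#' Generate a target table with a planted degree--dN/dS relation
#'
#' Draws per-gene miRNA-target degrees uniformly over
#' \code{1..(2*meanDegree - 1)} and gene dN/dS so that the expected dN/dS
#' decreases linearly with degree when \code{slope < 0} (no relation when
#' \code{slope = 0}); 3'UTR lengths are drawn independently of dN/dS. The
#' uniform degree distribution keeps per-degree bin occupancy balanced,
#' so the downstream binned correlation test is calibrated.
#'
#' @param nMirnas,nGenes table dimensions.
#' @param slope change in expected dN/dS per unit gene degree (<= 0).
#' @param seed integer seed.
#' @param meanDegree mean number of miRNAs targeting a gene.
#' @param dndsBase,dndsNoise intercept and residual SD of the dN/dS model.
#' @return list with \code{targets} (data.frame mirna, gene) and
#'   \code{geneEvolution} (data.frame gene, dnds, utr_length).
#' @export
generateTargetTable <- function(nMirnas, nGenes, slope, seed,
                                meanDegree = 8, dndsBase = 0.45,
                                dndsNoise = 0.08) {
  set.seed(seed)
  if (nGenes == 0L)
    return(list(targets = data.frame(mirna = character(0),
                                     gene = character(0)),
                geneEvolution = data.frame(gene = character(0),
                                           dnds = numeric(0),
                                           utr_length = integer(0))))
  genes <- sprintf("gene%04d", seq_len(nGenes))
  mirnas <- sprintf("miR-%03d", seq_len(nMirnas))
  deg <- pmin(sample.int(2L * meanDegree - 1L, nGenes, replace = TRUE),
              nMirnas)
  dnds <- pmax(dndsBase + slope * deg + rnorm(nGenes, 0, dndsNoise), 0.01)
  utr <- pmax(200L, as.integer(round(exp(rnorm(nGenes, log(1000), 0.5)))))
  tt <- do.call(rbind, lapply(which(deg > 0), function(g) {
    data.frame(mirna = sample(mirnas, deg[g]), gene = genes[g],
               stringsAsFactors = FALSE)
  }))
  if (is.null(tt)) tt <- data.frame(mirna = character(0),
                                    gene = character(0))
  list(targets = tt,
       geneEvolution = data.frame(gene = genes, dnds = dnds,
                                  utr_length = utr,
                                  stringsAsFactors = FALSE))
}

#' Packaged reference table of novel rhesus ESC miRNAs
#'
#' The 23 mature novel miRNAs (19 precursor hairpins) identified in three
#' rhesus macaque embryonic stem cell lines (IVF1.2, IVF3.2, IVF3.3) that
#' are homologous to annotated miRNAs of other species, shipped with the
#' package as tab-separated text: mature sequence, precursor location(s)
#' (1-based inclusive; two locations separated by \code{;} where one mature
#' species arises from two loci), name, and the read count in each line.
#'
#' @return data.frame with columns \code{mature_sequence},
#'   \code{precursor_location}, \code{name}, three \code{reads_*} columns,
#'   and a derived \code{group} column (precursor group: the miRNA name
#'   with its -5p/-3p arm suffix stripped).
#' @examples
#' t1 <- loadTable1Fixture()
#' nrow(t1)                     # 23 mature miRNAs
#' length(unique(t1$group))     # 19 precursor groups
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "resc_novel_mirnas.tsv",
                      package = "mirstem", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$group <- sub("-[35]p$", "", df$name)
  df
}

#' Simulate cross-species ESC miRNA expression profiles
#'
#' Generates per-sample RPM matrices for several species sharing a core of
#' homologous miRNA families plus species-restricted named clusters, with
#' a configurable similarity structure (by default the first two species
#' are more correlated with each other than with the third, mirroring
#' human/macaque vs mouse).
#'
#' @param seed integer seed.
#' @param species character vector of species ids (first two = sister pair).
#' @param nCoreFamilies number of families expressed in all species.
#' @param nSamples samples (replicates) per species.
#' @param clusters named list: for each named miRNA cluster, a character
#'   vector of species in which it is expressed. Default plants a
#'   mouse-only cluster, a mouse+macaque imprinted-region-like cluster and
#'   a human-enriched C19MC-like cluster.
#' @param clusterSize mature miRNAs per named cluster.
#' @param sisterSd,outgroupSd,sampleSd log2-scale SDs controlling
#'   between-species and between-sample variation.
#' @return list with \code{samples} (per species, a families x samples RPM
#'   matrix), \code{homology} (data.frame mirna, family), \code{clusters}
#'   (the definitions, as family ids), and \code{truth} (core family ids
#'   and the planted presence table).
#' @export
simulateSpeciesProfiles <- function(seed = 1L,
                                    species = c("hsa", "mml", "mmu"),
                                    nCoreFamilies = 100L,
                                    nSamples = 3L,
                                    clusters = list(
                                      "miR-467-like" = "mmu",
                                      "imprinted-like" = c("mml", "mmu"),
                                      "C19MC-like" = "hsa"),
                                    clusterSize = 5L,
                                    sisterSd = 0.6, outgroupSd = 2.0,
                                    sampleSd = 0.25) {
  set.seed(seed)
  core <- sprintf("fam%03d", seq_len(nCoreFamilies))
  clFams <- lapply(seq_along(clusters), function(i)
    sprintf("%s-m%d", names(clusters)[i], seq_len(clusterSize)))
  names(clFams) <- names(clusters)
  fams <- c(core, unlist(clFams, use.names = FALSE))

  base <- rnorm(nCoreFamilies, 6, 2.5)   # log2 RPM of core families
  samples <- list()
  for (s in seq_along(species)) {
    sd <- if (s <= 2) sisterSd else outgroupSd
    mu <- setNames(rep(-Inf, length(fams)), fams)
    mu[core] <- base + rnorm(nCoreFamilies, 0, sd)
    for (cl in names(clFams))
      if (species[s] %in% clusters[[cl]])
        mu[clFams[[cl]]] <- rnorm(clusterSize, 7, 1)
    m <- sapply(seq_len(nSamples), function(j) {
      x <- ifelse(is.finite(mu), 2 ^ (mu + rnorm(length(mu), 0, sampleSd)),
                  0)
      round(x, 3)
    })
    rownames(m) <- fams
    colnames(m) <- paste0(species[s], "_s", seq_len(nSamples))
    samples[[species[s]]] <- m
  }
  homology <- data.frame(mirna = paste0(rep(species, each = length(fams)),
                                        "-", fams),
                         family = rep(fams, length(species)),
                         stringsAsFactors = FALSE)
  presence <- sapply(species, function(sp)
    vapply(names(clusters), function(cl) sp %in% clusters[[cl]], logical(1)))
  list(samples = samples, homology = homology, clusters = clFams,
       truth = list(core = core, presence = presence))
}
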