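# Novel miRNA discovery from unannotated mapped tags: cluster tags into
# candidate loci, extract flanking windows under both arm hypotheses,
# fold them with a stacking-aware base-pair maximization DP, and apply
# hairpin, arm-placement and energy criteria plus cross-library read
# support filters.

#' Cluster unannotated tag alignments into candidate loci
#'
#' Same-strand alignments within \code{maxGap} of each other are merged
#' into loci; each locus records its total read support per library, and
#' the highest-count tag ("mature" candidate) with its genomic position.
#'
#' @param alignments GRanges of unannotated tag hits (metadata column
#'   \code{tag}).
#' @param tags named list (per library) of data.frames \code{sequence},
#'   \code{count}.
#' @param maxGap maximum merge gap in bases (default 200).
#' @return GRanges of loci with metadata columns \code{locus_id},
#'   \code{topTag}, \code{topStart}, \code{topEnd}, and matrix columns
#'   \code{support} (all tags) and \code{matureSupport} (top tag only),
#'   one column per library.
#' @export
clusterUnannotated <- function(alignments, tags, maxGap = 200L) {
  libs <- names(tags)
  loci <- GenomicRanges::reduce(alignments, min.gapwidth = maxGap + 1L,
                                ignore.strand = FALSE)
  if (!length(loci)) {
    S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
      locus_id = character(0), topTag = character(0),
      topStart = integer(0), topEnd = integer(0))
    return(loci)
  }
  countOf <- lapply(tags, function(df)
    setNames(as.numeric(df$count), df$sequence))
  totalOf <- Reduce(`+`, lapply(libs, function(l) {
    v <- countOf[[l]][S4Vectors::mcols(alignments)$tag]
    ifelse(is.na(v), 0, v)
  }))
  ov <- GenomicRanges::findOverlaps(alignments, loci,
                                    ignore.strand = FALSE)
  q <- S4Vectors::queryHits(ov)
  sj <- S4Vectors::subjectHits(ov)
  support <- matrix(0, nrow = length(loci), ncol = length(libs),
                    dimnames = list(NULL, libs))
  topTag <- character(length(loci))
  topStart <- topEnd <- integer(length(loci))
  matureSupport <- support
  tagName <- S4Vectors::mcols(alignments)$tag
  for (i in seq_along(loci)) {
    aIdx <- q[sj == i]
    tg <- tagName[aIdx]
    # locus support counts each distinct tag once even if multi-hit here
    uniq <- !duplicated(tg)
    for (l in libs) {
      v <- countOf[[l]][tg[uniq]]
      support[i, l] <- sum(v, na.rm = TRUE)
    }
    best <- aIdx[which.max(totalOf[aIdx])]
    topTag[i] <- tagName[best]
    topStart[i] <- GenomicRanges::start(alignments)[best]
    topEnd[i] <- GenomicRanges::end(alignments)[best]
    for (l in libs) {
      v <- countOf[[l]][topTag[i]]
      matureSupport[i, l] <- ifelse(is.na(v), 0, v)
    }
  }
  S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
    locus_id = sprintf("locus-%04d", seq_along(loci)),
    topTag = topTag, topStart = topStart, topEnd = topEnd,
    support = I(support), matureSupport = I(matureSupport))
  loci
}

#' Extract candidate hairpin windows around a mature tag
#'
#' Two windows per locus, one per arm hypothesis: with the tag as the 5'
#' arm, a short flank upstream and a long flank downstream (in transcript
#' orientation); with the tag as the 3' arm, mirrored. Windows are
#' clipped at chromosome boundaries and the returned sequence is
#' strand-oriented (reverse-complemented for "-" loci).
#'
#' @param chrom,start,end,strand genomic position of the mature tag
#'   (1-based inclusive).
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param flankUp,flankDown short and long flank lengths (defaults 20 and
#'   160 nt).
#' @return data.frame with one row per hypothesis (\code{arm} = "5p"/"3p"):
#'   genomic \code{start}, \code{end}, oriented \code{sequence}, and the
#'   1-based \code{matureStart}, \code{matureEnd} of the tag within the
#'   oriented window.
#' @export
extractWindows <- function(chrom, start, end, strand, genome,
                           flankUp = 20L, flankDown = 160L) {
  L <- Biostrings::width(genome)[match(chrom, names(genome))]
  win <- function(a, b) c(max(1L, a), min(L, b))
  if (strand == "+") {
    w5 <- win(start - flankUp, end + flankDown)
    w3 <- win(start - flankDown, end + flankUp)
  } else {
    w5 <- win(start - flankDown, end + flankUp)
    w3 <- win(start - flankUp, end + flankDown)
  }
  rows <- lapply(list(`5p` = w5, `3p` = w3), function(w) {
    seq <- as.character(Biostrings::subseq(genome[[chrom]], w[1], w[2]))
    if (strand == "-") {
      seq <- .revcomp(seq)
      ms <- w[2] - end + 1L
      me <- w[2] - start + 1L
    } else {
      ms <- start - w[1] + 1L
      me <- end - w[1] + 1L
    }
    data.frame(start = w[1], end = w[2], sequence = seq,
               matureStart = ms, matureEnd = me,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$arm <- c("5p", "3p")
  rownames(out) <- NULL
  out[, c("arm", "start", "end", "sequence", "matureStart", "matureEnd")]
}

#' Fold an RNA/DNA sequence into its maximum-score nested structure
#'
#' Dynamic program over nested (pseudoknot-free) structures maximizing a
#' stacking-aware score: pair scores GC = 3, AU = 2, GU = 1, plus 1 for
#' each pair stacked directly on another; hairpin loops are at least 3 nt.
#' The reported energy estimate is \eqn{-0.9 \times} score, a kcal/mol
#' proxy (more negative = more stable).
#'
#' @param sequence character scalar over A/C/G/T/U.
#' @return list with \code{structure} (dot-bracket string, same length as
#'   the input), \code{score} (integer) and \code{energy} (kcal/mol
#'   proxy, \eqn{\le 0}).
#' @examples
#' foldRna("GGGGGAAAACCCCC")   # 5 GC pairs closing a 4 nt loop
#' @export
foldRna <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTU]", sequence))
    stop("input error: sequence must contain only A/C/G/T/U")
  r <- .foldDp(sequence)
  list(structure = r$structure, score = r$score,
       energy = -0.9 * r$score)
}

# pair table from a dot-bracket string: partner index per position, 0 if
# unpaired
.pairTable <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure string")
  pt
}

#' Evaluate a folded window as a miRNA hairpin candidate
#'
#' Pass criteria: (a) the structure is a single hairpin (exactly one
#' terminal loop); (b) the mature tag lies entirely on one arm with at
#' least \code{minPairedMature} of its bases paired to the opposite arm;
#' (c) the energy estimate is at most \code{energyMax}; (d) the terminal
#' loop is 3-20 nt. A Dicer-like 2 nt star offset is reported but not
#' required.
#'
#' @param fold list from [foldRna()].
#' @param matureStart,matureEnd 1-based mature tag span in the window.
#' @param energyMax maximum allowed energy estimate (default -18
#'   kcal/mol).
#' @param minPairedMature minimum mature bases paired to the opposite arm
#'   (default 14).
#' @param loopRange allowed terminal loop length (default 3-20 nt).
#' @return list with \code{pass} (logical), \code{reasons} (character:
#'   subset of "structure", "loop", "arm", "energy"), \code{loopLength},
#'   \code{nPaired}, \code{dicerOverhang}.
#' @export
evaluateCandidate <- function(fold, matureStart, matureEnd,
                              energyMax = -18, minPairedMature = 14L,
                              loopRange = c(3L, 20L)) {
  reasons <- character(0)
  structure <- fold$structure
  loops <- gregexpr("\\(\\.+\\)", structure)[[1]]
  nLoops <- if (loops[1] == -1L) 0L else length(loops)
  loopLength <- NA_integer_
  nPaired <- 0L
  dicer <- NA
  if (nLoops != 1L) {
    reasons <- c(reasons, "structure")
  } else {
    loopStart <- loops[1] + 1L
    loopLength <- attr(loops, "match.length")[1] - 2L
    loopEnd <- loopStart + loopLength - 1L
    if (loopLength < loopRange[1] || loopLength > loopRange[2])
      reasons <- c(reasons, "loop")
    pt <- .pairTable(structure)
    span <- matureStart:matureEnd
    span <- span[span >= 1 & span <= nchar(structure)]
    partners <- pt[span]
    if (all(span < loopStart)) {
      nPaired <- sum(partners > loopEnd)
    } else if (all(span > loopEnd)) {
      nPaired <- sum(partners > 0 & partners < loopStart)
    } else {
      reasons <- c(reasons, "arm")   # mature spans the terminal loop
    }
    if (!("arm" %in% reasons) && nPaired < minPairedMature)
      reasons <- c(reasons, "arm")
    p1 <- pt[span[1]]; p2 <- pt[span[length(span)]]
    if (p1 > 0 && p2 > 0)
      dicer <- abs(abs(p1 - p2) - (matureEnd - matureStart)) <= 4
  }
  if (fold$energy > energyMax) reasons <- c(reasons, "energy")
  list(pass = length(reasons) == 0L, reasons = reasons,
       loopLength = loopLength, nPaired = nPaired,
       dicerOverhang = dicer)
}

# Locate and evaluate the hairpin supporting a mature tag inside an
# arm-hypothesis window. The fixed outer window deliberately over-covers
# the precursor, and flanking sequence folds into extra loops under
# score maximization; so the window is folded once to find the pairing
# partners of the mature tag, the enclosing span is excised, refolded in
# isolation and evaluated against the hairpin criteria.
.scanHairpin <- function(window, energyMax, minPairedMature, margin = 4L) {
  n <- nchar(window$sequence)
  ms <- window$matureStart; me <- window$matureEnd
  f0 <- foldRna(window$sequence)
  pt <- .pairTable(f0$structure)
  span <- ms:me
  span <- span[span >= 1 & span <= n]
  partners <- pt[span]
  partners <- partners[partners > 0]
  if (length(partners) < 2L) return(list(found = FALSE))
  a <- max(1L, min(c(span, partners)) - margin)
  b <- min(n, max(c(span, partners)) + margin)
  sub <- substr(window$sequence, a, b)
  f <- foldRna(sub)
  ev <- evaluateCandidate(f, ms - a + 1L, me - a + 1L,
                          energyMax = energyMax,
                          minPairedMature = minPairedMature)
  if (ev$pass)
    list(found = TRUE, subStart = a, subEnd = b, fold = f, eval = ev)
  else
    list(found = FALSE)
}

#' Predict novel miRNAs from unannotated tag loci
#'
#' Pipeline: cluster unannotated alignments into loci
#' ([clusterUnannotated()]); keep loci whose mature (top) tag has at
#' least \code{minReads} in every library (support gating before the
#' expensive folding step); extract both arm-hypothesis windows
#' ([extractWindows()]) and scan nested sub-windows for a passing hairpin
#' ([foldRna()] + [evaluateCandidate()]); finally apply the shared-call
#' filter ([callNovel()]).
#'
#' @param alignments GRanges of unannotated tag hits.
#' @param tags per-library list of tag data.frames.
#' @param genome named DNAStringSet.
#' @param minReads minimum mature read support per library (default 30).
#' @param requireAllLibraries require the support in every library
#'   (default TRUE).
#' @param maxGap,flankUp,flankDown,energyMax,minPairedMature tuning of
#'   the clustering, window and hairpin criteria.
#' @return data.frame of called novel miRNAs: \code{name},
#'   \code{mature_sequence}, \code{precursor_location} (chrom:start-end:
#'   strand of the passing sub-window), \code{structure}, \code{energy},
#'   and one count column per library. Zero-row when nothing passes.
#' @export
novelMirnas <- function(alignments, tags, genome, minReads = 30L,
                        requireAllLibraries = TRUE, maxGap = 200L,
                        flankUp = 20L, flankDown = 160L,
                        energyMax = -18, minPairedMature = 14L) {
  libs <- names(tags)
  empty <- data.frame(name = character(0), mature_sequence = character(0),
                      precursor_location = character(0),
                      structure = character(0), energy = numeric(0))
  loci <- clusterUnannotated(alignments, tags, maxGap = maxGap)
  if (!length(loci)) return(empty)
  mc <- S4Vectors::mcols(loci)
  ms <- mc$matureSupport
  keep <- if (requireAllLibraries)
    apply(ms >= minReads, 1, all) else rowSums(ms) >= minReads
  loci <- loci[keep]
  mc <- S4Vectors::mcols(loci)
  if (!length(loci)) return(empty)

  out <- list()
  for (i in seq_along(loci)) {
    ch <- as.character(GenomicRanges::seqnames(loci)[i])
    str <- as.character(GenomicRanges::strand(loci)[i])
    if (str == "*") str <- "+"
    wins <- extractWindows(ch, mc$topStart[i], mc$topEnd[i], str, genome,
                           flankUp = flankUp, flankDown = flankDown)
    for (k in seq_len(nrow(wins))) {
      sc <- .scanHairpin(wins[k, ], energyMax, minPairedMature)
      if (sc$found) {
        # sub-window coordinates back to genome
        if (str == "+") {
          gs <- wins$start[k] + sc$subStart - 1L
          ge <- wins$start[k] + sc$subEnd - 1L
        } else {
          ge <- wins$end[k] - sc$subStart + 1L
          gs <- wins$end[k] - sc$subEnd + 1L
        }
        rec <- data.frame(
          locus_id = mc$locus_id[i],
          mature_sequence = mc$topTag[i],
          precursor_location = sprintf("%s:%d-%d:%s", ch, gs, ge, str),
          structure = sc$fold$structure, energy = sc$fold$energy,
          arm = wins$arm[k], stringsAsFactors = FALSE)
        for (l in libs) rec[[l]] <- S4Vectors::mcols(loci)$matureSupport[i, l]
        out[[length(out) + 1L]] <- rec
        break
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # Group -5p/-3p products (and strand mirror images of near-palindromic
  # hairpins) whose passing precursor windows overlap into one precursor.
  loc <- do.call(rbind, strsplit(res$precursor_location, ":"))
  rng <- do.call(rbind, strsplit(loc[, 2], "-"))
  winGr <- GenomicRanges::GRanges(
    loc[, 1], IRanges::IRanges(as.integer(rng[, 1]), as.integer(rng[, 2])))
  red <- GenomicRanges::reduce(winGr, ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(winGr, red, ignore.strand = TRUE))
  res$precursor_group <- sprintf("novel-pre-%03d", grp)
  # one record per (group, mature sequence): drop strand duplicates
  res <- res[!duplicated(res[c("precursor_group", "mature_sequence")]), ,
             drop = FALSE]
  cn <- callNovel(res$mature_sequence, res$precursor_group,
                  as.matrix(res[, libs, drop = FALSE]),
                  minReads = minReads,
                  requireAllLibraries = requireAllLibraries)
  res <- res[res$mature_sequence %in% cn$calls$mature_id, , drop = FALSE]
  res$name <- sprintf("novel-mir-%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("name", "precursor_group", "mature_sequence",
          "precursor_location", "arm", "structure", "energy", libs)]
}

#' Apply read-support filters and -5p/-3p grouping to mature miRNAs
#'
#' Keeps mature products with at least \code{minReads} in every library
#' (or, with \code{requireAllLibraries = FALSE}, summed over libraries)
#' and groups the -5p/-3p products of one hairpin under one precursor
#' group. The threshold is inclusive (a count of exactly \code{minReads}
#' passes).
#'
#' @param matureIds character vector of mature identifiers.
#' @param groupIds character vector of precursor group keys, same length
#'   (e.g. the miRNA name with the arm suffix stripped, or a locus id).
#' @param counts numeric matrix, one row per mature, one column per
#'   library.
#' @param minReads support threshold (default 30).
#' @param requireAllLibraries see above (default TRUE).
#' @return list with \code{calls} (data.frame \code{mature_id},
#'   \code{group}), \code{nMature} and \code{nPrecursors}.
#' @examples
#' t1 <- loadTable1Fixture()
#' cnt <- as.matrix(t1[, grep("^reads_", names(t1))])
#' callNovel(t1$name, t1$group, cnt)$nMature       # 23
#' callNovel(t1$name, t1$group, cnt)$nPrecursors   # 19
#' @export
callNovel <- function(matureIds, groupIds, counts, minReads = 30L,
                      requireAllLibraries = TRUE) {
  counts <- as.matrix(counts)
  keep <- if (requireAllLibraries)
    apply(counts >= minReads, 1, all) else rowSums(counts) >= minReads
  calls <- data.frame(mature_id = matureIds[keep],
                      group = groupIds[keep], stringsAsFactors = FALSE)
  list(calls = calls, nMature = nrow(calls),
       nPrecursors = length(unique(calls$group)))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles a sequence while preserving its dinucleotide composition
#' (random Eulerian walk over the dinucleotide transition multigraph,
#' with a mononucleotide fallback if no complete walk is found); the
#' standard negative control for RNA secondary-structure criteria.
#'
#' @param sequence character scalar.
#' @param maxTries walk attempts before falling back (default 100).
#' @return shuffled sequence of identical length and (in the Eulerian
#'   case) dinucleotide counts.
#' @export
dinucleotideShuffle <- function(sequence, maxTries = 100L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 3L) return(sequence)
  succ <- split(chars[-1], chars[-n])
  for (try in seq_len(maxTries)) {
    bag <- lapply(succ, sample)
    walk <- character(n)
    walk[1] <- chars[1]
    ok <- TRUE
    for (i in 2:n) {
      v <- walk[i - 1]
      if (!length(bag[[v]])) { ok <- FALSE; break }
      walk[i] <- bag[[v]][1]
      bag[[v]] <- bag[[v]][-1]
    }
    if (ok && !sum(lengths(bag))) return(paste(walk, collapse = ""))
  }
  paste(sample(chars), collapse = "")
}
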