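# Genome mapping, known-miRNA quantification and hierarchical category
# annotation of collapsed tags. Mapping is exact-match on both strands
# (the simulator emits exact reads); category conflicts are resolved by
# the priority rules
#   rRNA/tRNA/scRNA/snRNA/snoRNA (Genbank > Rfam) > known miRNA >
#   repeat > exon > intron,
# applied over ALL genomic hits of a multi-mapping tag; tags overlapping
# nothing are "unann". Coordinates are 1-based inclusive at interfaces
# (GFF convention).

.ncrnaPriority <- setNames(seq_along(.NCRNA_SUBTYPES), .NCRNA_SUBTYPES)

.categoryPriority <- function(category, source) {
  ifelse(category %in% .NCRNA_SUBTYPES,
         ifelse(source == "genbank", 10L, 20L) +
           .ncrnaPriority[category],
         ifelse(category == "known_miRNA", 30L,
         ifelse(category == "repeat", 40L,
         ifelse(category == "exon", 50L,
         ifelse(category == "intron", 60L, 99L)))))
}

#' Map tags to a genome by exact search on both strands
#'
#' All exact occurrences of every tag on either strand are found with a
#' preprocessed dictionary search ([Biostrings::matchPDict()] per tag
#' width); for each tag up to \code{maxHits} hits are reported
#' (\code{n_hits} records the true total). Tags with no occurrence are
#' returned as unmapped.
#'
#' @param tagSeqs character vector of distinct tag sequences.
#' @param genome named \link[Biostrings]{DNAStringSet}.
#' @param maxHits cap on reported hits per tag (default 20).
#' @return list with \code{alignments} (GRanges; metadata columns
#'   \code{tag}, \code{n_hits}) and \code{unmapped} (character vector).
#' @export
mapTags <- function(tagSeqs, genome, maxHits = 20L) {
  tagSeqs <- unique(tagSeqs)
  hits <- list()
  for (w in unique(nchar(tagSeqs))) {
    sub <- tagSeqs[nchar(tagSeqs) == w]
    pd <- Biostrings::PDict(sub)
    for (ch in names(genome)) {
      subj <- genome[[ch]]
      L <- length(subj)
      for (str in c("+", "-")) {
        s <- if (str == "+") subj else Biostrings::reverseComplement(subj)
        m <- Biostrings::matchPDict(pd, s)
        nh <- S4Vectors::elementNROWS(m)
        if (!sum(nh)) next
        ir <- unlist(m)
        st <- BiocGenerics::start(ir); en <- BiocGenerics::end(ir)
        if (str == "-") {
          tmp <- st
          st <- L - en + 1L
          en <- L - tmp + 1L
        }
        hits[[length(hits) + 1L]] <- data.frame(
          tag = rep(sub, nh), chrom = ch, start = st, end = en,
          strand = str, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    gr <- GenomicRanges::GRanges()
    return(list(alignments = gr, unmapped = tagSeqs))
  }
  df <- do.call(rbind, hits)
  nHits <- table(df$tag)
  df$n_hits <- as.integer(nHits[df$tag])
  # cap reported hits per tag
  df <- df[unlist(lapply(split(seq_len(nrow(df)), df$tag), head,
                         n = maxHits), use.names = FALSE), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom, ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, tag = df$tag, n_hits = df$n_hits)
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  list(alignments = gr, unmapped = setdiff(tagSeqs, df$tag))
}

#' Quantify known miRNAs from collapsed tags
#'
#' Matches tags to reference precursor sequences: a tag occurring exactly
#' within a precursor, with its start within \code{maxShift} nt of an
#' annotated mature-arm start, adds its count to that mature miRNA (tags
#' overlapping only the loop are not counted). A tag matching several
#' precursors is counted toward each (all-hits rule; see Details). A
#' precursor's absolute expression is the sum over its mature products.
#'
#' @details With \code{maxMismatch = 1} a slower per-tag scan tolerating
#' one substitution is used; the default is exact matching. Reference rows
#' without mature-arm coordinates are skipped with a warning.
#'
#' @param tags named list (per library) of data.frames with columns
#'   \code{sequence}, \code{count} (as from [preprocessReads()]).
#' @param reference data.frame with columns \code{precursor_id},
#'   \code{sequence}, \code{mature_id}, \code{matureStart},
#'   \code{matureEnd} (1-based, precursor orientation).
#' @param maxShift positional tolerance around the mature start (default 4).
#' @param maxMismatch 0 (exact, default) or 1.
#' @return \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{counts} (mature miRNA x library) and rowData
#'   \code{precursor_id}.
#' @export
quantifyKnown <- function(tags, reference, maxShift = 4L,
                          maxMismatch = 0L) {
  bad <- is.na(reference$matureStart) | is.na(reference$matureEnd)
  if (any(bad)) {
    warning(sum(bad), " reference record(s) without mature annotation ",
            "skipped")
    reference <- reference[!bad, , drop = FALSE]
  }
  libs <- names(tags)
  allTags <- unique(unlist(lapply(tags, `[[`, "sequence"),
                           use.names = FALSE))
  counts <- matrix(0L, nrow = nrow(reference), ncol = length(libs),
                   dimnames = list(reference$mature_id, libs))
  if (length(allTags) && nrow(reference)) {
    # (tag, reference row) support pairs
    asgTag <- character(0); asgRow <- integer(0)
    precSeqs <- unique(reference$sequence)
    for (w in unique(nchar(allTags))) {
      sub <- allTags[nchar(allTags) == w]
      pd <- if (maxMismatch == 0L) Biostrings::PDict(sub) else NULL
      for (ps in precSeqs) {
        subj <- Biostrings::DNAString(ps)
        rows <- which(reference$sequence == ps)
        if (maxMismatch == 0L) {
          m <- Biostrings::matchPDict(pd, subj)
          nh <- S4Vectors::elementNROWS(m)
          if (!sum(nh)) next
          starts <- BiocGenerics::start(unlist(m))
          tagIdx <- rep(seq_along(sub), nh)
        } else {
          starts <- integer(0); tagIdx <- integer(0)
          for (i in seq_along(sub)) {
            mm <- Biostrings::matchPattern(sub[i], subj,
                                           max.mismatch = maxMismatch)
            if (length(mm)) {
              starts <- c(starts, BiocGenerics::start(mm))
              tagIdx <- c(tagIdx, rep(i, length(mm)))
            }
          }
          if (!length(starts)) next
        }
        for (r in rows) {
          ok <- abs(starts - reference$matureStart[r]) <= maxShift
          ts <- unique(sub[tagIdx[ok]])
          asgTag <- c(asgTag, ts)
          asgRow <- c(asgRow, rep(r, length(ts)))
        }
      }
    }
    if (length(asgTag)) {
      asg <- unique(data.frame(tag = asgTag, row = asgRow,
                               stringsAsFactors = FALSE))
      for (l in libs) {
        df <- tags[[l]]
        cnt <- setNames(df$count, df$sequence)
        sel <- asg[asg$tag %in% df$sequence, , drop = FALSE]
        if (!nrow(sel)) next
        add <- tapply(as.numeric(cnt[sel$tag]), sel$row, sum)
        counts[as.integer(names(add)), l] <-
          counts[as.integer(names(add)), l] + as.integer(add)
      }
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      precursor_id = reference$precursor_id,
      row.names = reference$mature_id))
}

#' Build a miRNA expression matrix with per-library mapped totals
#'
#' @param counts integer matrix, mature miRNAs x libraries.
#' @param mappedTotals numeric vector of mapped reads per library.
#' @return SummarizedExperiment with assay \code{counts} and colData
#'   column \code{mappedTotal}.
#' @export
mirnaExpressionMatrix <- function(counts, mappedTotals) {
  stopifnot(ncol(counts) == length(mappedTotals))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(mappedTotal = mappedTotals,
                                   row.names = colnames(counts)))
}

#' Resolve each mapped tag to a single annotation category
#'
#' Overlaps every genomic hit of every tag with the annotation tracks
#' (strand-aware for the five structural ncRNA classes and miRNA loci,
#' strand-blind for repeat/exon/intron) and keeps, per tag, the
#' highest-priority category over all hits; Genbank-sourced ncRNA beats
#' Rfam within the ncRNA tier, and a tag with no overlap anywhere is
#' \code{"unann"}.
#'
#' @param alignments GRanges from [mapTags()] (metadata column \code{tag}).
#' @param tracks GRanges with metadata columns \code{category} (one of
#'   rRNA, tRNA, scRNA, snRNA, snoRNA, known_miRNA, repeat, exon, intron)
#'   and \code{source} (genbank / rfam / n-a).
#' @return data.frame with one row per tag: \code{tag}, \code{category},
#'   \code{source}.
#' @export
assignCategories <- function(alignments, tracks) {
  cat <- S4Vectors::mcols(tracks)$category
  known <- c(.NCRNA_SUBTYPES, "known_miRNA", "repeat", "exon", "intron")
  if (!all(cat %in% known))
    stop("input error: unknown category in track: ",
         paste(setdiff(cat, known), collapse = ", "))
  tagNames <- unique(S4Vectors::mcols(alignments)$tag)
  prio <- setNames(rep(99L, length(tagNames)), tagNames)
  src <- setNames(rep("n/a", length(tagNames)), tagNames)

  stranded <- cat %in% c(.NCRNA_SUBTYPES, "known_miRNA")
  catOf <- setNames(rep("unann", length(tagNames)), tagNames)
  applyHits <- function(tr, ignoreStrand) {
    if (!length(tr)) return(invisible())
    ov <- GenomicRanges::findOverlaps(alignments, tr, minoverlap = 1L,
                                      ignore.strand = ignoreStrand)
    if (!length(ov)) return(invisible())
    t <- S4Vectors::mcols(alignments)$tag[S4Vectors::queryHits(ov)]
    cc <- S4Vectors::mcols(tr)$category[S4Vectors::subjectHits(ov)]
    ss <- S4Vectors::mcols(tr)$source[S4Vectors::subjectHits(ov)]
    p <- .categoryPriority(cc, ss)
    o <- order(p)
    first <- !duplicated(t[o])
    t1 <- t[o][first]; p1 <- p[o][first]
    cc1 <- cc[o][first]; ss1 <- ss[o][first]
    better <- p1 < prio[t1]
    prio[t1[better]] <<- p1[better]
    src[t1[better]] <<- ss1[better]
    catOf[t1[better]] <<- cc1[better]
    invisible()
  }
  applyHits(tracks[stranded], FALSE)
  applyHits(tracks[!stranded], TRUE)
  data.frame(tag = tagNames, category = unname(catOf[tagNames]),
             source = unname(src[tagNames]), stringsAsFactors = FALSE)
}

#' Summarize category calls into read counts and fractions
#'
#' @param calls data.frame from [assignCategories()].
#' @param tagCounts named numeric vector: total read count per tag
#'   (summed over libraries); defaults to 1 per tag.
#' @return data.frame with \code{category}, \code{reads},
#'   \code{fraction}, sorted by decreasing reads (the pie-chart table).
#' @export
categorySummary <- function(calls, tagCounts = NULL) {
  w <- if (is.null(tagCounts)) rep(1, nrow(calls)) else
    as.numeric(tagCounts[calls$tag])
  agg <- tapply(w, calls$category, sum)
  df <- data.frame(category = names(agg), reads = as.numeric(agg),
                   stringsAsFactors = FALSE)
  df$fraction <- df$reads / sum(df$reads)
  df[order(-df$reads), , drop = FALSE]
}

#' Clean-tag length histogram
#'
#' @param tags data.frame with \code{sequence} and \code{count} (one
#'   library) or a named list of such data.frames (summed).
#' @return named integer vector length -> read count; sums to the total
#'   clean reads.
#' @export
lengthHistogram <- function(tags) {
  if (is.data.frame(tags)) tags <- list(tags)
  lens <- unlist(lapply(tags, function(df) rep(nchar(df$sequence),
                                               df$count)))
  if (!length(lens)) return(integer(0))
  tab <- table(lens)
  setNames(as.integer(tab), names(tab))
}
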