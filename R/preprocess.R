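# Read preprocessing: demultiplexing, 3' adapter trimming, clean-read
# filtering and tag collapsing. Raw reads are fixed-length (35 nt by
# default): 6 nt multiplex index + insert + 3' adapter fill. Adapter
# matching is exact-prefix; the simulator emits exact adapters, and a
# mismatch-tolerant mode is deliberately out of scope.

#' Demultiplex raw reads by their leading 6 nt index
#'
#' Assigns each read to the library whose index exactly matches the first
#' six bases, strips the index, and counts non-matching reads as
#' discarded.
#'
#' @param reads character vector of raw read sequences.
#' @param indexMap named character vector: names are 6 nt indices, values
#'   library ids; indices must be pairwise distinct.
#' @return list with \code{reads} (named list of index-stripped reads per
#'   library) and \code{discarded} (number of reads whose index matched no
#'   library, reason \code{"index"}).
#' @examples
#' demultiplex(c("AAACCCTGGT", "TTTTTTTGGT"), c(AAACCC = "L1"))
#' @export
demultiplex <- function(reads, indexMap) {
  if (any(nchar(names(indexMap)) != 6L))
    stop("configuration error: all indices must be 6 nt")
  if (anyDuplicated(names(indexMap)))
    stop("configuration error: duplicate index in map")
  idx <- substr(reads, 1L, 6L)
  lib <- indexMap[idx]
  keep <- !is.na(lib)
  stripped <- substr(reads[keep], 7L, nchar(reads[keep]))
  out <- split(stripped, lib[keep])
  # preserve declared library order, materialize empty libraries
  out <- lapply(setNames(nm = unname(indexMap)), function(l)
    if (l %in% names(out)) out[[l]] else character(0))
  list(reads = out, discarded = sum(!keep))
}

#' Trim the 3' adapter from index-stripped reads
#'
#' The insert is the prefix before the leftmost exact occurrence of the
#' first \code{minOverlap} bases of the 3' adapter. Reads without any
#' adapter match are rejected (reason \code{"no_adapter"}); an adapter
#' match at position 1 yields an empty insert, which the length filter
#' discards downstream.
#'
#' @param reads character vector (index already removed).
#' @param adapter3 3' adapter sequence, length >= \code{minOverlap}.
#' @param minOverlap minimum adapter prefix that must be seen (default 6).
#' @return list with \code{inserts} (trimmed sequences, adapter found) and
#'   \code{rejected} (count with no adapter match).
#' @export
trimAdapter3 <- function(reads, adapter3, minOverlap = 6L) {
  if (nchar(adapter3) < minOverlap)
    stop("adapter3 must be at least minOverlap bases")
  probe <- substr(adapter3, 1L, minOverlap)
  pos <- regexpr(probe, reads, fixed = TRUE)
  hit <- pos > 0L
  list(inserts = substr(reads[hit], 1L, pos[hit] - 1L),
       rejected = sum(!hit))
}

#' Filter inserts to clean tags
#'
#' Keeps inserts of 18-30 nt with at most \code{maxAmbiguous} non-ACGT
#' bases (the low-quality stand-in; simulated qualities are constant).
#'
#' @param inserts character vector of trimmed inserts.
#' @param minLen,maxLen clean length bounds (defaults 18 and 30).
#' @param maxAmbiguous maximum tolerated non-ACGT bases (default 0).
#' @return list with \code{clean} (kept inserts) and \code{discards}
#'   (named counts by reason: \code{short}, \code{long},
#'   \code{ambiguous}).
#' @export
filterClean <- function(inserts, minLen = 18L, maxLen = 30L,
                        maxAmbiguous = 0L) {
  n <- nchar(inserts)
  nAmb <- nchar(gsub("[ACGT]", "", inserts))
  short <- n < minLen
  long <- !short & n > maxLen
  amb <- !short & !long & nAmb > maxAmbiguous
  keep <- !(short | long | amb)
  list(clean = inserts[keep],
       discards = c(short = sum(short), long = sum(long),
                    ambiguous = sum(amb)))
}

#' Collapse clean inserts to unique tags with counts
#'
#' @param clean character vector of clean inserts for one library.
#' @return data.frame with columns \code{sequence} and \code{count},
#'   sorted by decreasing count; counts sum to \code{length(clean)}.
#' @export
collapseTags <- function(clean) {
  if (!length(clean))
    return(data.frame(sequence = character(0), count = integer(0)))
  tab <- table(clean)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$sequence), , drop = FALSE]
}

#' Preprocess raw multiplexed reads into collapsed clean tags
#'
#' Full filtering stage: demultiplex, trim the 3' adapter, keep 18-30 nt
#' unambiguous inserts, collapse to unique tags per library, and account
#' for every raw read (raw = clean + sum of discards, exactly).
#'
#' @param reads character vector of raw reads (all libraries pooled) or a
#'   list as produced by [simulateLibraries()] (concatenated internally).
#' @param indexMap named character vector index -> library id.
#' @param adapter3 3' adapter sequence.
#' @param minOverlap,minLen,maxLen,maxAmbiguous see [trimAdapter3()] and
#'   [filterClean()].
#' @param blocklist optional character vector of contaminant sequences to
#'   drop after filtering (default none).
#' @return list with \code{tags} (per library, a data.frame sequence +
#'   count) and \code{stats} (per library: raw, clean and a discard-reason
#'   histogram; plus \code{unassigned} for index misses).
#' @export
preprocessReads <- function(reads, indexMap, adapter3, minOverlap = 6L,
                            minLen = 18L, maxLen = 30L, maxAmbiguous = 0L,
                            blocklist = character(0)) {
  if (is.list(reads)) reads <- unlist(reads, use.names = FALSE)
  dm <- demultiplex(reads, indexMap)
  tags <- list()
  stats <- list(unassigned = dm$discarded)
  for (lib in names(dm$reads)) {
    r <- dm$reads[[lib]]
    tr <- trimAdapter3(r, adapter3, minOverlap)
    fc <- filterClean(tr$inserts, minLen, maxLen, maxAmbiguous)
    clean <- fc$clean
    nContam <- 0L
    if (length(blocklist)) {
      contam <- clean %in% blocklist
      nContam <- sum(contam)
      clean <- clean[!contam]
    }
    tags[[lib]] <- collapseTags(clean)
    stats[[lib]] <- list(
      raw = length(r), clean = length(clean),
      discards = c(no_adapter = tr$rejected, fc$discards,
                   contaminant = nContam))
  }
  list(tags = tags, stats = stats)
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the conventional \code{>tagN_xCOUNT} form.
#'
#' @param tags data.frame from [collapseTags()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTagFasta <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
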