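# End-to-end profiling driver tying the modules together.

#' Run the full small-RNA profiling pipeline on a (simulated) study
#'
#' Preprocesses the raw libraries, maps the collapsed tags to the genome,
#' resolves annotation categories, quantifies known miRNAs against the
#' precursor reference, and (optionally) predicts novel miRNAs from the
#' unannotated tags.
#'
#' @param study list with \code{reads}, \code{indexMap}, \code{genome},
#'   \code{annotation}, \code{truth} (as from [simulateStudy()]).
#' @param config the \linkS4class{SimulationConfig} of the study (supplies
#'   the adapter sequence).
#' @param minReads novel-call support threshold (default 30).
#' @param callNovelMirnas run the novel-miRNA stage (default TRUE).
#' @return list with \code{tags}, \code{stats}, \code{alignments},
#'   \code{unmapped}, \code{categories} (per-tag calls),
#'   \code{categoryTable} (read-weighted summary), \code{expression}
#'   (SummarizedExperiment with counts and mapped totals), \code{novel}
#'   (data.frame or NULL).
#' @export
runProfiling <- function(study, config, minReads = 30L,
                         callNovelMirnas = TRUE) {
  pp <- preprocessReads(study$reads, study$indexMap, config@adapter3)
  allTags <- unique(unlist(lapply(pp$tags, `[[`, "sequence"),
                           use.names = FALSE))
  mp <- mapTags(allTags, study$genome)
  tracks <- c(study$annotation,
              knownMirnaTrack(study$truth)[, c("category", "source")])
  calls <- assignCategories(mp$alignments, tracks)
  tagTotals <- setNames(numeric(length(allTags)), allTags)
  for (df in pp$tags) {
    tagTotals[df$sequence] <- tagTotals[df$sequence] + df$count
  }
  categoryTable <- categorySummary(calls, tagTotals)
  mappedTags <- unique(S4Vectors::mcols(mp$alignments)$tag)
  mappedTotals <- vapply(pp$tags, function(df)
    sum(df$count[df$sequence %in% mappedTags]), numeric(1))
  seRaw <- quantifyKnown(pp$tags, precursorReference(study$truth))
  se <- mirnaExpressionMatrix(SummarizedExperiment::assay(seRaw, "counts"),
                              mappedTotals)
  SummarizedExperiment::rowData(se) <- SummarizedExperiment::rowData(seRaw)
  novel <- NULL
  if (callNovelMirnas) {
    unannTags <- calls$tag[calls$category == "unann"]
    aln <- mp$alignments[
      S4Vectors::mcols(mp$alignments)$tag %in% unannTags]
    novel <- novelMirnas(aln, pp$tags, study$genome, minReads = minReads)
  }
  list(tags = pp$tags, stats = pp$stats, alignments = mp$alignments,
       unmapped = mp$unmapped, categories = calls,
       categoryTable = categoryTable, expression = se, novel = novel)
}
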