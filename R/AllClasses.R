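#' @import methods
#' @importFrom stats cor cor.test hclust as.dist p.adjust phyper ppois
#'   rlnorm rnorm runif rpois sd setNames wilcox.test quantile rmultinom
#' @importFrom utils read.delim head
#' @useDynLib mirstem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom GenomicRanges GRanges
NULL

.CATEGORIES <- c("mirna", "other_ncrna", "repeat", "exon", "intron",
                 "unannotated")
.NCRNA_SUBTYPES <- c("rRNA", "tRNA", "scRNA", "snRNA", "snoRNA")

#' Simulation configuration for synthetic small RNA-seq studies
#'
#' Holds every tunable of the synthetic-data generator: genome geometry,
#' number and clustering of planted miRNA precursor loci, sequencing depth
#' and multiplexing layout, and the read-category composition the libraries
#' should exhibit. Defaults emulate a three-library primate embryonic stem
#' cell profiling experiment: ~60\% of clean reads from known miRNAs, <15\%
#' from other annotated RNA classes, ~25\% unannotated, with clean-read
#' lengths peaking at 22-23 nt.
#'
#' @slot seed integer seed controlling all randomness downstream.
#' @slot nChromosomes,chromosomeLength genome geometry (bases).
#' @slot nPrecursors number of planted miRNA precursor hairpins.
#' @slot nClusters number of genomic miRNA clusters (3 members each).
#' @slot clusterGapBases maximum gap between clustered precursors.
#' @slot libraryDepth reads per library.
#' @slot nLibraries number of multiplexed libraries (default 3).
#' @slot composition named fractions over
#'   \code{c("mirna","other_ncrna","repeat","exon","intron","unannotated")},
#'   summing to 1.
#' @slot novelFraction fraction of planted precursors left out of the
#'   known-miRNA annotation (their reads count as unannotated).
#' @slot expressionDispersion log10-scale SD of planted miRNA abundances.
#' @slot betweenLibraryNoise multiplicative (log-normal) between-library
#'   noise SD on abundances; 0 means identical true proportions.
#' @slot adapter5,adapter3 adapter sequences; raw reads are 35 nt:
#'   6 nt index + insert + 3' adapter prefix.
#' @slot index6 one 6 nt multiplex index per library, pairwise distinct.
#' @slot readLength raw read length (default 35).
#'
#' @seealso [simulationConfig()], [generateGenome()], [simulateLibraries()]
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  nChromosomes = "integer",
  chromosomeLength = "integer",
  nPrecursors = "integer",
  nClusters = "integer",
  clusterGapBases = "integer",
  libraryDepth = "integer",
  nLibraries = "integer",
  composition = "numeric",
  novelFraction = "numeric",
  expressionDispersion = "numeric",
  betweenLibraryNoise = "numeric",
  adapter5 = "character",
  adapter3 = "character",
  index6 = "character",
  readLength = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  comp <- object@composition
  if (!identical(sort(names(comp)), sort(.CATEGORIES)))
    msg <- c(msg, sprintf("composition must be named over {%s}",
                          paste(.CATEGORIES, collapse = ", ")))
  else if (abs(sum(comp) - 1) > 1e-9)
    msg <- c(msg, "composition fractions must sum to 1 (tolerance 1e-9)")
  if (any(comp < 0)) msg <- c(msg, "composition fractions must be >= 0")
  for (s in c("nChromosomes", "chromosomeLength", "nPrecursors",
              "libraryDepth", "nLibraries", "readLength"))
    if (slot(object, s) < 1L)
      msg <- c(msg, sprintf("%s must be a positive count", s))
  if (object@nClusters < 0L) msg <- c(msg, "nClusters must be >= 0")
  if (any(nchar(object@index6) != 6L))
    msg <- c(msg, "every multiplex index must be exactly 6 nt")
  if (anyDuplicated(object@index6))
    msg <- c(msg, "multiplex indices must be pairwise distinct")
  if (length(object@index6) != object@nLibraries)
    msg <- c(msg, "need one multiplex index per library")
  if (object@novelFraction < 0 || object@novelFraction > 1)
    msg <- c(msg, "novelFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated study
#'
#' Container written by the generator and consumed by recovery tests:
#' planted precursor loci (as a \link[GenomicRanges]{GRanges} with hairpin
#' sequence, mature-arm coordinates and known/novel status), per-miRNA true
#' abundances and realized per-library read counts, per-category read
#' counts, and (optionally) planted target-table structure.
#'
#' @slot precursors GRanges of planted hairpin loci; metadata columns
#'   \code{precursor_id}, \code{hairpin} (sequence, precursor strand),
#'   \code{mature} (mature product sequence), \code{arm} ("5p"/"3p"),
#'   \code{matureStart},\code{matureEnd} (1-based within the hairpin),
#'   \code{known} (logical), \code{cluster} (cluster id or NA).
#' @slot abundance numeric matrix (miRNA x library) of true expected read
#'   proportions within the miRNA budget.
#' @slot counts integer matrix (miRNA x library) of realized read counts;
#'   filled by [simulateLibraries()].
#' @slot categoryCounts integer matrix (category x library) of realized
#'   reads per source category; columns sum to the library depth.
#' @slot targets data.frame of planted (mirna, gene) target pairs.
#' @slot geneEvolution data.frame with columns \code{gene}, \code{dnds},
#'   \code{utr_length}.
#' @export
setClass("GroundTruth", representation(
  precursors = "GRanges",
  abundance = "matrix",
  counts = "matrix",
  categoryCounts = "matrix",
  targets = "data.frame",
  geneEvolution = "data.frame"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@precursors)
  if (length(object@precursors)) {
    mlen <- mc$matureEnd - mc$matureStart + 1L
    if (any(mlen < 19L | mlen > 25L))
      msg <- c(msg, "every planted mature arm must be 19-25 nt")
    if (any(mc$matureStart < 1L) ||
        any(mc$matureEnd > nchar(mc$hairpin)))
      msg <- c(msg, "mature arms must lie within their precursor")
  }
  if (length(msg)) msg else TRUE
})

#' Bipartite miRNA-target network
#'
#' A bipartite graph with miRNA nodes on one side and target-gene nodes on
#' the other; edges are distinct miRNA-gene interactions. A gene's degree
#' is the number of miRNAs targeting it.
#'
#' @slot mirnas,genes character node identifiers (disjoint sets).
#' @slot edges data.frame with columns \code{mirna}, \code{gene}; one row
#'   per distinct interaction.
#' @seealso [buildNetwork()], [baRandomNetwork()], [geneDegrees()]
#' @export
setClass("MTNetwork", representation(
  mirnas = "character",
  genes = "character",
  edges = "data.frame"
))

setValidity("MTNetwork", function(object) {
  msg <- character()
  if (!all(c("mirna", "gene") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns 'mirna' and 'gene'")
  else {
    if (anyDuplicated(object@edges[c("mirna", "gene")]))
      msg <- c(msg, "edges must be distinct miRNA-gene pairs")
    if (!all(object@edges$mirna %in% object@mirnas) ||
        !all(object@edges$gene %in% object@genes))
      msg <- c(msg, "edge endpoints must be declared nodes (bipartite)")
  }
  if (length(intersect(object@mirnas, object@genes)))
    msg <- c(msg, "miRNA and gene node sets must be disjoint")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  genome: %d chromosome(s) x %s bp\n", object@nChromosomes,
              format(object@chromosomeLength, big.mark = ",")))
  cat(sprintf("  precursors: %d (%d cluster(s), gap <= %d bp, %.0f%% novel)\n",
              object@nPrecursors, object@nClusters, object@clusterGapBases,
              100 * object@novelFraction))
  cat(sprintf("  libraries: %d x %s reads (%d nt raw)\n", object@nLibraries,
              format(object@libraryDepth, big.mark = ","),
              object@readLength))
  cat("  composition:",
      paste(sprintf("%s=%.3f", names(object@composition),
                    object@composition), collapse = " "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  known <- S4Vectors::mcols(object@precursors)$known
  cat(sprintf("  precursors: %d (%d known, %d novel)\n",
              length(object@precursors), sum(known), sum(!known)))
  if (nrow(object@counts))
    cat(sprintf("  realized counts: %d miRNA x %d libraries\n",
                nrow(object@counts), ncol(object@counts)))
  if (nrow(object@targets))
    cat(sprintf("  planted targets: %d pairs over %d genes\n",
                nrow(object@targets), nrow(object@geneEvolution)))
})

setMethod("show", "MTNetwork", function(object) {
  cat(sprintf("MTNetwork: %d miRNA + %d gene nodes, %d edges\n",
              length(object@mirnas), length(object@genes),
              nrow(object@edges)))
})

#' @describeIn MTNetwork-class miRNA node identifiers.
#' @param x an \code{MTNetwork}.
#' @export
mirnaNodes <- function(x) x@mirnas

#' @describeIn MTNetwork-class gene node identifiers.
#' @export
geneNodes <- function(x) x@genes

#' @describeIn MTNetwork-class edge table (distinct miRNA-gene pairs).
#' @export
edgeTable <- function(x) x@edges

#' @describeIn MTNetwork-class named degree vector over miRNA nodes.
#' @export
mirnaDegrees <- function(x) {
  d <- table(factor(x@edges$mirna, levels = x@mirnas))
  setNames(as.integer(d), names(d))
}

#' @describeIn MTNetwork-class named degree vector over gene nodes (number
#'   of miRNAs targeting each gene).
#' @export
geneDegrees <- function(x) {
  d <- table(factor(x@edges$gene, levels = x@genes))
  setNames(as.integer(d), names(d))
}

#' @describeIn GroundTruth-class planted precursor loci.
#' @param x a \code{GroundTruth}.
#' @export
precursorLoci <- function(x) x@precursors

#' @describeIn GroundTruth-class realized per-miRNA per-library counts.
#' @export
truthCounts <- function(x) x@counts

#' @describeIn GroundTruth-class realized per-category per-library counts.
#' @export
truthCategoryCounts <- function(x) x@categoryCounts

#' @describeIn GroundTruth-class planted miRNA-gene target pairs.
#' @export
truthTargets <- function(x) x@targets

#' @describeIn GroundTruth-class gene evolutionary-rate table.
#' @export
geneEvolution <- function(x) x@geneEvolution
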