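# Seed-match target prediction, bipartite miRNA-target network
# construction, degree-vs-evolutionary-rate correlation with a
# preferential-attachment null, and hypergeometric pathway enrichment.

.seedMatchDna <- function(mirna, from, to) {
  # reverse complement of miRNA positions from..to, in DNA alphabet
  seed <- chartr("Uu", "Tt", toupper(substr(mirna, from, to)))
  .revcomp(seed)
}

#' Predict canonical seed-match target sites in a 3'UTR
#'
#' The seed is miRNA positions 2-8. A UTR 7-mer equal to the reverse
#' complement of the seed is a 7mer-m8 site; the same match followed by
#' an adenosine (opposite miRNA position 1) is an 8mer; the reverse
#' complement of positions 2-7 followed by A is a 7mer-A1. Every
#' occurrence is reported (overlaps allowed); each 6-mer core match is
#' classified by its best supported type.
#'
#' @param mirna mature miRNA sequence (RNA or DNA alphabet, >= 8 nt).
#' @param utr 3'UTR sequence (DNA alphabet).
#' @param mirnaId,geneId identifiers copied into the output.
#' @return data.frame with columns \code{mirna}, \code{gene},
#'   \code{position} (1-based UTR start of the site), \code{site_type}.
#' @export
predictSites <- function(mirna, utr, mirnaId = "mir", geneId = "gene") {
  if (nchar(mirna) < 8L) stop("miRNA must be >= 8 nt")
  utr <- toupper(utr)
  core <- .seedMatchDna(mirna, 2L, 7L)      # 6-mer, matches positions 2-7
  m8 <- .seedMatchDna(mirna, 8L, 8L)        # base pairing miRNA pos 8
  out <- list()
  start <- 1L
  repeat {
    p <- regexpr(core, substr(utr, start, nchar(utr)), fixed = TRUE)
    if (p < 0) break
    pos <- start + p - 1L                    # core match at utr[pos..pos+5]
    hasM8 <- pos > 1L && substr(utr, pos - 1L, pos - 1L) == m8
    hasA1 <- substr(utr, pos + 6L, pos + 6L) == "A"
    type <- if (hasM8 && hasA1) "8mer"
            else if (hasM8) "7mer-m8"
            else if (hasA1) "7mer-A1"
            else NA_character_
    if (!is.na(type)) {
      sitePos <- if (hasM8) pos - 1L else pos
      out[[length(out) + 1L]] <- data.frame(
        mirna = mirnaId, gene = geneId, position = sitePos,
        site_type = type, stringsAsFactors = FALSE)
    }
    start <- pos + 1L
  }
  if (!length(out))
    return(data.frame(mirna = character(0), gene = character(0),
                      position = integer(0), site_type = character(0)))
  do.call(rbind, out)
}

#' Classify a target site as conserved across aligned orthologous UTRs
#'
#' A site is conserved if the same site type occurs at the aligned
#' position in at least \code{minSpecies} of the species present in the
#' alignment (the reference row counts).
#'
#' @param site one row from [predictSites()] run on the ungapped
#'   reference UTR.
#' @param alignment named character vector of aligned UTR rows (equal
#'   lengths, gaps as "-"); first element is the reference.
#' @param mirna the mature miRNA sequence used for the prediction.
#' @param minSpecies conservation threshold (default 4).
#' @param flank columns added on each side of the mapped site span to
#'   absorb small gap-induced shifts (default 2).
#' @return list with \code{conserved} (logical) and \code{nSpecies}
#'   (species exhibiting the site).
#' @export
classifyConservation <- function(site, alignment, mirna,
                                 minSpecies = 4L, flank = 2L) {
  ref <- alignment[[1]]
  refChars <- strsplit(ref, "")[[1]]
  unGapped <- cumsum(refChars != "-")
  siteLen <- if (site$site_type == "8mer") 8L else 7L
  colStart <- match(site$position, unGapped)
  colEnd <- match(site$position + siteLen - 1L, unGapped)
  if (is.na(colStart) || is.na(colEnd))
    stop("site position outside alignment")
  colStart <- max(1L, colStart - flank)
  colEnd <- min(nchar(ref), colEnd + flank)
  n <- 0L
  for (row in alignment) {
    local <- gsub("-", "", substr(row, colStart, colEnd))
    hits <- predictSites(mirna, local)
    if (site$site_type %in% hits$site_type) n <- n + 1L
  }
  list(conserved = n >= minSpecies, nSpecies = n)
}

#' Build a bipartite miRNA-target network from a target table
#'
#' Duplicate (miRNA, gene) rows collapse to a single edge: the network
#' counts interactions, not sites.
#'
#' @param targets data.frame with columns \code{mirna}, \code{gene}.
#' @return an \linkS4class{MTNetwork}.
#' @export
buildNetwork <- function(targets) {
  e <- unique(targets[, c("mirna", "gene"), drop = FALSE])
  rownames(e) <- NULL
  new("MTNetwork", mirnas = unique(e$mirna), genes = unique(e$gene),
      edges = e)
}

#' Correlation between gene degree and evolutionary rate
#'
#' Genes are grouped by their (optionally 3'UTR-length-normalized,
#' rounded) degree; bins with fewer than \code{minGenesPerBin} genes are
#' dropped, and the Pearson correlation between bin degree and bin mean
#' dN/dS is computed with a two-sided t test (df = nBins - 2).
#'
#' @param network an \linkS4class{MTNetwork}.
#' @param evolution data.frame with \code{gene}, \code{dnds},
#'   \code{utr_length}.
#' @param minGenesPerBin minimum bin occupancy (default 10).
#' @param normalizePerKb NULL (raw degree) or 1 or 2: degree is divided
#'   by utr_length / (1000 * k) before rounding.
#' @param binned set FALSE for the raw per-gene correlation.
#' @return list with \code{r}, \code{p}, \code{nBins} (or \code{n} for
#'   the unbinned variant).
#' @export
degreeDndsCorrelation <- function(network, evolution,
                                  minGenesPerBin = 10L,
                                  normalizePerKb = NULL,
                                  binned = TRUE) {
  deg <- geneDegrees(network)
  ev <- evolution[evolution$gene %in% names(deg), , drop = FALSE]
  d <- as.numeric(deg[ev$gene])
  if (!is.null(normalizePerKb))
    d <- d / (ev$utr_length / (1000 * normalizePerKb))
  if (!binned) {
    ct <- cor.test(d, ev$dnds)
    return(list(r = unname(ct$estimate), p = ct$p.value, n = length(d)))
  }
  bin <- round(d)
  tab <- table(bin)
  keepBins <- names(tab)[tab >= minGenesPerBin]
  if (length(keepBins) < 3L)
    stop("fewer than 3 degree bins after filtering")
  binDeg <- as.numeric(keepBins)
  binDnds <- vapply(keepBins, function(b) mean(ev$dnds[bin == as.numeric(b)]),
                    numeric(1))
  ct <- cor.test(binDeg, binDnds)
  list(r = unname(ct$estimate), p = ct$p.value, nBins = length(keepBins))
}

#' Bipartite preferential-attachment random network
#'
#' Adaptation of the Barabasi-Albert construction to a bipartite graph:
#' all nodes are added in random order, each attaching to one existing
#' opposite-side node chosen with probability proportional to degree + 1
#' (the +1 lets degree-0 nodes attach); further edges are then added by
#' degree-proportional sampling of both endpoints until exactly
#' \code{nEdges} distinct edges exist. Deterministic given the seed.
#'
#' @param nMirnas,nGenes,nEdges graph size; \code{nEdges} must be
#'   feasible for a simple bipartite graph.
#' @param seed integer seed.
#' @return an \linkS4class{MTNetwork}.
#' @export
baRandomNetwork <- function(nMirnas, nGenes, nEdges, seed = 1L) {
  if (nEdges > as.double(nMirnas) * nGenes)
    stop("infeasible edge count for a simple bipartite graph")
  set.seed(seed)
  mirnas <- sprintf("miR-%03d", seq_len(nMirnas))
  genes <- sprintf("gene%04d", seq_len(nGenes))
  degM <- setNames(integer(nMirnas), mirnas)
  degG <- setNames(integer(nGenes), genes)
  edges <- character(0)    # "mirna\tgene" keys
  em <- character(0); eg <- character(0)
  addEdge <- function(m, g) {
    key <- paste0(m, "\t", g)
    if (key %in% edges) return(FALSE)
    edges <<- c(edges, key)
    em <<- c(em, m); eg <<- c(eg, g)
    degM[m] <<- degM[m] + 1L
    degG[g] <<- degG[g] + 1L
    TRUE
  }
  order <- sample(c(mirnas, genes))
  seenM <- character(0); seenG <- character(0)
  for (v in order) {
    isM <- v %in% mirnas
    if (isM) {
      if (length(seenG) && length(edges) < nEdges) {
        g <- sample(seenG, 1, prob = degG[seenG] + 1)
        addEdge(v, g)
      }
      seenM <- c(seenM, v)
    } else {
      if (length(seenM) && length(edges) < nEdges) {
        m <- sample(seenM, 1, prob = degM[seenM] + 1)
        addEdge(m, v)
      }
      seenG <- c(seenG, v)
    }
  }
  while (length(edges) < nEdges) {
    m <- sample(mirnas, 1, prob = degM + 1)
    g <- sample(genes, 1, prob = degG + 1)
    addEdge(m, g)
  }
  new("MTNetwork", mirnas = mirnas, genes = genes,
      edges = data.frame(mirna = em, gene = eg,
                         stringsAsFactors = FALSE))
}

#' Compare two degree distributions with a Wilcoxon rank-sum test
#'
#' Two-sided; exact enumeration when the combined sample size is at most
#' 12 and there are no ties, otherwise the normal approximation with tie
#' and continuity corrections.
#'
#' @param degA,degB numeric degree samples (non-empty).
#' @return list with \code{p}, \code{W}, \code{method}.
#' @export
compareDegreeDistributions <- function(degA, degB) {
  if (!length(degA) || !length(degB)) stop("empty degree sample")
  exact <- length(degA) + length(degB) <= 12L &&
    !anyDuplicated(c(degA, degB))
  wt <- suppressWarnings(
    wilcox.test(degA, degB, exact = exact, correct = TRUE))
  list(p = wt$p.value, W = unname(wt$statistic),
       method = if (exact) "exact" else "normal approximation")
}

#' Hypergeometric pathway enrichment with Benjamini-Hochberg correction
#'
#' Upper-tail hypergeometric p-value per pathway (probability of at
#' least the observed overlap between the target set and the pathway,
#' drawing from the universe), with BH q-values over all tested
#' pathways.
#'
#' @param targetSet character vector of genes of interest (subset of the
#'   universe).
#' @param universe character vector of all genes.
#' @param pathways named list of character vectors (subsets of the
#'   universe).
#' @param qCutoff significance threshold on q (default 0.05).
#' @return data.frame per pathway: \code{pathway}, \code{overlap},
#'   \code{pathwaySize}, \code{p}, \code{q}, \code{significant}.
#' @export
enrichment <- function(targetSet, universe, pathways, qCutoff = 0.05) {
  if (!length(universe)) stop("empty universe")
  targetSet <- intersect(targetSet, universe)
  res <- do.call(rbind, lapply(names(pathways), function(pw) {
    genes <- intersect(pathways[[pw]], universe)
    ov <- length(intersect(targetSet, genes))
    p <- phyper(ov - 1L, length(genes),
                length(universe) - length(genes), length(targetSet),
                lower.tail = FALSE)
    data.frame(pathway = pw, overlap = ov, pathwaySize = length(genes),
               p = p, stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q <= qCutoff
  res
}
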