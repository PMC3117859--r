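# Expression-consistency statistics for miRNA profiles: RPM
# normalization, Poisson background thresholds, genomic miRNA clusters
# (<= 10 kb inter-miRNA distance), and four concordance measures --
# entropy-based divergence (Var), coefficient of variation (C.V.),
# differential index (D.I.) and Cohen's kappa with Z-score.

#' Reads-per-million normalization
#'
#' @param count read count(s).
#' @param mappedTotal mapped reads in the library (> 0).
#' @return count / mappedTotal * 1e6.
#' @export
normalizeRpm <- function(count, mappedTotal) {
  if (any(mappedTotal <= 0)) stop("mappedTotal must be > 0")
  count / mappedTotal * 1e6
}

#' RPM-normalize an expression matrix
#'
#' @param se SummarizedExperiment from [mirnaExpressionMatrix()] (assay
#'   \code{counts}, colData \code{mappedTotal}).
#' @return numeric matrix of RPM values.
#' @export
rpmMatrix <- function(se) {
  cnt <- SummarizedExperiment::assay(se, "counts")
  tot <- SummarizedExperiment::colData(se)$mappedTotal
  sweep(cnt, 2, tot, function(x, t) normalizeRpm(x, t))
}

#' Poisson background read threshold
#'
#' Smallest integer count T such that a 50 bp (by default) genomic window
#' would reach T reads with probability below \code{alpha} under a
#' uniform-background Poisson model. In \code{analytic} mode the rate is
#' \eqn{\lambda =} totalMappedReads x window / genomeLength; in
#' \code{empirical} mode \eqn{\lambda} is estimated as the mean read
#' count over \code{nBins} randomly placed windows (given the read start
#' positions), then the same tail rule is applied.
#'
#' @param totalMappedReads total mapped reads (analytic mode).
#' @param genomeLength genome size in bases.
#' @param window bin width in bases (default 50).
#' @param alpha upper-tail probability (default 1e-4).
#' @param mode "analytic" or "empirical".
#' @param readStarts integer vector of read start positions on a
#'   concatenated genome coordinate (required for empirical mode).
#' @param nBins number of sampled windows in empirical mode (default
#'   210000, i.e. 10,000 bins for each of 21 chromosomes).
#' @param seed seed for the empirical window placement.
#' @return integer threshold T with P(X >= T) < alpha.
#' @export
poissonThreshold <- function(totalMappedReads = NULL, genomeLength,
                             window = 50L, alpha = 1e-4,
                             mode = c("analytic", "empirical"),
                             readStarts = NULL, nBins = 210000L,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  lambda <- if (mode == "analytic") {
    totalMappedReads * window / genomeLength
  } else {
    if (is.null(readStarts)) stop("empirical mode needs readStarts")
    set.seed(seed)
    starts <- sample.int(max(1L, genomeLength - window + 1L), nBins,
                         replace = TRUE)
    srt <- sort(readStarts)
    lo <- findInterval(starts - 1L, srt)
    hi <- findInterval(starts + window - 1L, srt)
    mean(hi - lo)
  }
  if (lambda <= 0) stop("lambda must be > 0")
  t <- 1L
  while (ppois(t - 1L, lambda, lower.tail = FALSE) >= alpha) t <- t + 1L
  t
}

#' Define genomic miRNA clusters by inter-miRNA distance
#'
#' Per chromosome, loci sorted by start are chained while the gap between
#' consecutive loci is at most \code{mid} (inclusive); singletons are
#' allowed.
#'
#' @param loci GRanges of miRNA loci (names or a \code{name} metadata
#'   column identify members).
#' @param mid maximum inter-miRNA distance in bases (default 10000).
#' @return data.frame with columns \code{name}, \code{chrom},
#'   \code{start}, \code{cluster} (integer id); cluster members are
#'   consecutive loci.
#' @export
defineClusters <- function(loci, mid = 10000L) {
  nm <- S4Vectors::mcols(loci)$name
  if (is.null(nm)) nm <- names(loci)
  if (is.null(nm)) nm <- sprintf("mir%04d", seq_along(loci))
  df <- data.frame(name = nm,
                   chrom = as.character(GenomicRanges::seqnames(loci)),
                   start = GenomicRanges::start(loci),
                   end = GenomicRanges::end(loci),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  cl <- integer(nrow(df))
  cur <- 0L
  for (i in seq_len(nrow(df))) {
    newCluster <- i == 1L || df$chrom[i] != df$chrom[i - 1L] ||
      (df$start[i] - df$end[i - 1L] - 1L) > mid
    if (newCluster) cur <- cur + 1L
    cl[i] <- cur
  }
  df$cluster <- cl
  rownames(df) <- NULL
  df[, c("name", "chrom", "start", "cluster")]
}

.entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between two count vectors (bits)
#'
#' @param p,q non-negative count or proportion vectors of equal length.
#' @param pseudocount added to each entry before normalization (default
#'   0; [clusterVar()] uses 0.5).
#' @return JSD in bits, in [0, 1].
#' @export
jsDivergence <- function(p, q, pseudocount = 0) {
  p <- p + pseudocount; q <- q + pseudocount
  if (sum(p) <= 0 || sum(q) <= 0)
    stop("undefined: all-zero profile")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  .entropyBits(m) - (.entropyBits(p) + .entropyBits(q)) / 2
}

#' Expression variability (Var) of a miRNA cluster between two libraries
#'
#' Member-count proportions within the cluster are computed in each
#' library (pseudocount 0.5 avoids log 0) and compared with the
#' Jensen-Shannon divergence in bits: 0 for identical member usage, 1 bit
#' for disjoint usage.
#'
#' @param counts numeric matrix, cluster members x libraries.
#' @param libA,libB column names or indices of the pair.
#' @param pseudocount small-count correction (default 0.5).
#' @return Var in bits, or NA if the cluster has no reads in either
#'   library.
#' @export
clusterVar <- function(counts, libA, libB, pseudocount = 0.5) {
  if (nrow(counts) < 2L) stop("cluster must have >= 2 members")
  a <- counts[, libA]; b <- counts[, libB]
  if (sum(a) == 0 && sum(b) == 0) return(NA_real_)
  jsDivergence(a, b, pseudocount = pseudocount)
}

#' Coefficient of variation of cluster totals across libraries
#'
#' @param rpm numeric matrix of RPM values, cluster members x libraries
#'   (>= 2 libraries); a single member is a degenerate one-row cluster.
#' @return sample SD / mean of the per-library cluster totals, or NA if
#'   the mean is 0.
#' @export
clusterCv <- function(rpm) {
  rpm <- rbind(rpm)
  totals <- colSums(rpm)
  m <- mean(totals)
  if (m == 0) return(NA_real_)
  sd(totals) / m
}

#' Differential index: relative deviation from the per-miRNA mean
#'
#' @param rpm RPM matrix, miRNAs x libraries (expressed set only).
#' @return matrix of the same shape: (x - rowMean) / rowMean; rows with
#'   mean 0 are dropped. Rows sum to 0 exactly.
#' @export
diffIndex <- function(rpm) {
  m <- rowMeans(rpm)
  keep <- m > 0
  sweep(rpm[keep, , drop = FALSE], 1, m[keep], "/") - 1
}

#' Cohen's kappa agreement of expressed calls between two libraries
#'
#' Each miRNA in the union set is called expressed/not per library by an
#' absolute count threshold; kappa = (Po - Pe) / (1 - Pe) with Pe from
#' the marginal call frequencies, and Z = kappa / SE0 with
#' SE0 = sqrt(Pe / (N (1 - Pe))) under the no-agreement null.
#'
#' @param counts count matrix, miRNAs (union set) x libraries.
#' @param libA,libB the pair to compare.
#' @param expressedThreshold inclusive call threshold (default 30).
#' @return list with \code{kappa}, \code{z}, \code{po}, \code{pe},
#'   \code{n}.
#' @export
kappaAgreement <- function(counts, libA, libB, expressedThreshold = 30) {
  n <- nrow(counts)
  if (n == 0L) stop("empty miRNA set")
  a <- counts[, libA] >= expressedThreshold
  b <- counts[, libB] >= expressedThreshold
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  se0 <- sqrt(pe / (n * (1 - pe)))
  list(kappa = kappa, z = kappa / se0, po = po, pe = pe, n = n)
}

#' Consistency report over all clusters and library pairs
#'
#' Convenience driver producing the cluster-level Var and C.V. tables and
#' the library-pair kappa/Z table for an expression matrix.
#'
#' @param se SummarizedExperiment (counts + mappedTotal).
#' @param clusters data.frame from [defineClusters()] whose \code{name}
#'   matches rownames of \code{se}.
#' @param expressedThreshold absolute-count call threshold (default 30).
#' @return list of data.frames \code{var} (cluster x library pair),
#'   \code{cv} (per cluster), \code{kappa} (per library pair), and
#'   matrix \code{di}.
#' @export
consistencyReport <- function(se, clusters, expressedThreshold = 30) {
  cnt <- SummarizedExperiment::assay(se, "counts")
  rpm <- rpmMatrix(se)
  libs <- colnames(cnt)
  pairs <- utils::combn(libs, 2)
  multi <- split(clusters$name, clusters$cluster)
  multi <- multi[lengths(multi) >= 2]
  varTab <- do.call(rbind, lapply(names(multi), function(cl) {
    rows <- intersect(multi[[cl]], rownames(cnt))
    if (length(rows) < 2) return(NULL)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
      data.frame(cluster = cl, libA = pairs[1, k], libB = pairs[2, k],
                 var = clusterVar(cnt[rows, , drop = FALSE],
                                  pairs[1, k], pairs[2, k]))))
  }))
  cvTab <- do.call(rbind, lapply(names(multi), function(cl) {
    rows <- intersect(multi[[cl]], rownames(rpm))
    if (length(rows) < 2) return(NULL)
    data.frame(cluster = cl, cv = clusterCv(rpm[rows, , drop = FALSE]))
  }))
  kapTab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    ka <- kappaAgreement(cnt, pairs[1, k], pairs[2, k],
                         expressedThreshold)
    data.frame(libA = pairs[1, k], libB = pairs[2, k],
               kappa = ka$kappa, z = ka$z)
  }))
  expressed <- rowSums(cnt >= expressedThreshold) == ncol(cnt)
  list(var = varTab, cv = cvTab, kappa = kapTab,
       di = diffIndex(rpm[expressed, , drop = FALSE]))
}

#' Shared expressed miRNA summary across libraries
#'
#' Percentage of expressed miRNAs shared by all libraries, relative to
#' the largest per-library detection count: 100 x nShared /
#' max(detected).
#'
#' @param nShared number of miRNAs detected in every library.
#' @param detected per-library detection counts.
#' @return list with \code{percentShared}, \code{nShared},
#'   \code{detected}.
#' @examples
#' sharingSummary(304, c(326, 329, 326))$percentShared  # 92.4
#' @export
sharingSummary <- function(nShared, detected) {
  if (nShared > min(detected))
    stop("nShared cannot exceed the smallest detection count")
  list(percentShared = 100 * nShared / max(detected),
       nShared = nShared, detected = detected)
}

#' Count shared expressed miRNAs from an expression matrix
#'
#' @param counts count matrix, miRNAs x libraries.
#' @param threshold detection threshold (default 1 read; use 30 for the
#'   expressed-call convention).
#' @return [sharingSummary()] of the detection pattern.
#' @export
sharedExpressed <- function(counts, threshold = 1) {
  det <- counts >= threshold
  sharingSummary(sum(rowSums(det) == ncol(det)), colSums(det))
}
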