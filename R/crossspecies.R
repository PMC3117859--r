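# Cross-species ESC miRNA profile comparison: per-species mean RPM
# profiles, shared homologous family matrix, hierarchical clustering of
# species, and presence/absence contrasts of named miRNA clusters.

#' Mean expression profile of one species
#'
#' @param rpmSamples numeric matrix, miRNAs x samples (RPM-normalized).
#' @return named numeric vector: per-miRNA arithmetic mean over samples.
#' @export
meanProfile <- function(rpmSamples) {
  rpmSamples <- as.matrix(rpmSamples)
  if (!ncol(rpmSamples)) stop("need >= 1 sample")
  rowMeans(rpmSamples)
}

#' Shared homologous family matrix across species
#'
#' Maps each species' miRNAs to family keys and keeps the families
#' detected (RPM > 0) in every species.
#'
#' @param profiles named list of per-species mean profiles (named numeric
#'   vectors; names are species-level miRNA ids or family keys).
#' @param homology optional data.frame with columns \code{mirna},
#'   \code{family}; if NULL the profile names are already family keys.
#' @return numeric matrix families x species, restricted to the common
#'   set (possibly zero rows).
#' @export
sharedSet <- function(profiles, homology = NULL) {
  if (length(profiles) < 2L) stop("need >= 2 species profiles")
  fam <- lapply(profiles, function(p) {
    nm <- names(p)
    if (!is.null(homology)) {
      key <- homology$family[match(nm, homology$mirna)]
      nm <- ifelse(is.na(key), nm, key)
    }
    tapply(p, nm, sum)
  })
  common <- Reduce(intersect, lapply(fam, function(f)
    names(f)[f > 0]))
  m <- sapply(fam, function(f) as.numeric(f[common]))
  if (length(common) == 0L)
    m <- matrix(numeric(0), nrow = 0, ncol = length(profiles),
                dimnames = list(NULL, names(profiles)))
  else {
    m <- matrix(m, nrow = length(common),
                dimnames = list(common, names(profiles)))
  }
  m
}

#' Hierarchically cluster species by expression profile
#'
#' Distance 1 - Pearson correlation on log2(RPM + 1), average linkage.
#'
#' @param common numeric matrix families x species (>= 2 families,
#'   >= 3 species).
#' @return list with \code{hclust} (the tree), \code{newick} (Newick
#'   string of the species tree), \code{dist} (the distance matrix).
#' @export
clusterSpecies <- function(common) {
  if (ncol(common) < 3L) stop("need >= 3 species")
  if (nrow(common) < 2L) stop("need >= 2 families")
  x <- log2(common + 1)
  if (any(apply(x, 2, sd) == 0))
    stop("constant profile: correlation undefined")
  d <- as.dist(1 - cor(x))
  hc <- hclust(d, method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)),
       dist = d)
}

#' Contrast named miRNA clusters across species
#'
#' For each named cluster (e.g. a mouse-restricted cluster, an
#' imprinted-region cluster, a primate-specific C19MC-like cluster),
#' reports the summed member RPM per species and a present/absent call
#' (any member at or above the threshold).
#'
#' @param profiles named list of per-species mean profiles (family keys
#'   as names).
#' @param clusterDefs named list: cluster name -> character vector of
#'   member family keys.
#' @param presenceThresholdRpm call threshold (default 1 RPM).
#' @return data.frame: \code{cluster}, \code{species}, \code{rpm}
#'   (summed), \code{present}.
#' @export
contrastNamedClusters <- function(profiles, clusterDefs,
                                  presenceThresholdRpm = 1.0) {
  if (is.null(names(clusterDefs)) || any(!nzchar(names(clusterDefs))))
    stop("undefined cluster name")
  out <- list()
  for (cl in names(clusterDefs)) {
    members <- clusterDefs[[cl]]
    for (sp in names(profiles)) {
      v <- profiles[[sp]][members]
      v[is.na(v)] <- 0
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, species = sp, rpm = sum(v),
        present = any(v >= presenceThresholdRpm),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
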