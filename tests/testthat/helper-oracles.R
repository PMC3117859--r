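# Independent oracles used across test files. These deliberately avoid the
# package's own algorithms: the folding oracle enumerates every nested
# structure explicitly, the rank-sum oracle enumerates label assignments,
# and the statistics oracles are literal hand formulas.

# -- exhaustive folding oracle -------------------------------------------
# Enumerate all nested pseudoknot-free structures (min loop 3) of a short
# sequence and return the maximum stacking-aware score:
#   pair scores GC=3, AU/AT=2, GU/GT=1; +1 for each pair (i,j) with
#   (i+1,j-1) also paired.
oraclePairScore <- function(a, b) {
  a <- chartr("U", "T", a); b <- chartr("U", "T", b)
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AT", "TA")) return(2)
  if (key %in% c("GT", "TG")) return(1)
  0
}

# all pair-sets on chars[i..j]; each structure is a 2-column matrix
oracleStructures <- function(chars, i, j) {
  if (j - i + 1 < 5) return(list(matrix(numeric(0), ncol = 2)))
  out <- list()
  for (s in oracleStructures(chars, i + 1, j))   # i unpaired
    out[[length(out) + 1]] <- s
  for (k in (i + 4):j) {
    if (oraclePairScore(chars[i], chars[k]) == 0) next
    left <- oracleStructures(chars, i + 1, k - 1)
    right <- oracleStructures(chars, k + 1, j)
    for (l in left) for (r in right)
      out[[length(out) + 1]] <- rbind(c(i, k), l, r)
  }
  out
}

oracleFoldScore <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  best <- 0
  for (s in oracleStructures(chars, 1, n)) {
    if (!nrow(s)) next
    sc <- sum(apply(s, 1, function(p)
      oraclePairScore(chars[p[1]], chars[p[2]])))
    # stacking bonus: pair (i,j) with (i+1, j-1) also present
    key <- paste(s[, 1], s[, 2])
    sc <- sc + sum(paste(s[, 1] + 1, s[, 2] - 1) %in% key)
    if (sc > best) best <- sc
  }
  best
}

# -- exact rank-sum oracle -----------------------------------------------
# Two-sided p by exhaustive enumeration of group assignments.
oracleRankSumP <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  nA <- length(a)
  obs <- sum(r[seq_len(nA)])
  combos <- utils::combn(length(pooled), nA)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# -- entropy / divergence hand formulas ----------------------------------
oracleEntropyBits <- function(p) {
  p <- p / sum(p); p <- p[p > 0]
  -sum(p * log2(p))
}
oracleJsdBits <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  oracleEntropyBits(m) - (oracleEntropyBits(p) + oracleEntropyBits(q)) / 2
}

# -- Poisson tail oracle: direct pmf summation ---------------------------
oraclePoissonThreshold <- function(lambda, alpha, kMax = 200L) {
  pmf <- dpois(0:kMax, lambda)
  for (t in 1:kMax) {
    if (sum(pmf[(t + 1):(kMax + 1)]) < alpha) return(t)
  }
  stop("kMax too small")
}

# -- Benjamini-Hochberg step-up formula ----------------------------------
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
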