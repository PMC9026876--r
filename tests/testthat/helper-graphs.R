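# Shared builders and independent oracles for the test suite.

# simple path graph A-B-C-...
pathGraph <- function(n) {
  ids <- LETTERS[seq_len(n)]
  KnowledgeGraph(data.frame(source = ids[-n], target = ids[-1]))
}

# Erdos-Renyi-ish random KnowledgeGraph for property tests
randomGraph <- function(n, pEdge, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < pEdge
  KnowledgeGraph(data.frame(source = pairs[keep, 1], target = pairs[keep, 2]),
                 nodes = ids)
}

# Floyd-Warshall all-pairs hop distances, independent of igraph
fwOracle <- function(kg) {
  ids <- nodeIds(kg)
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  et <- layerTable(kg)
  for (i in seq_len(nrow(et))) {
    D[et$source[i], et$target[i]] <- 1
    D[et$target[i], et$source[i]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Direct linear-system solve of the restart walk, independent of the
# power-iteration implementation:  p = r s + (1-r) (W + s 1_dangling') p
rwrOracle <- function(kg, seeds, restart) {
  ids <- nodeIds(kg)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  et <- layerTable(kg)
  for (i in seq_len(nrow(et))) {
    A[et$source[i], et$target[i]] <- 1
    A[et$target[i], et$source[i]] <- 1
  }
  deg <- colSums(A)
  W <- A %*% diag(ifelse(deg > 0, 1 / deg, 0))
  s <- numeric(n); names(s) <- ids
  s[seeds] <- 1 / length(seeds)
  dang <- as.numeric(deg == 0)
  T <- W + outer(s, dang)
  p <- solve(diag(n) - (1 - restart) * T, restart * s)
  stats::setNames(as.numeric(p), ids)
}

# hand-built predictor whose raw output decreases monotonically in d_min;
# used where tests need a deterministic model without training
monotoneModel <- function() {
  new("RelationshipModel",
      weights = list(W1 = matrix(c(-2, 0, 0, 0, 0), 1, 5),
                     b1 = 0,
                     W2 = matrix(4, 1, 1), b2 = -2),
      center = rep(0, 5), scale = rep(1, 5),
      featureNames = c("d_min", "d_mean", "rwr_score", "jaccard_nbr",
                       "degree_log"),
      hyper = list(hidden = 1L), seed = 0L, metrics = list())
}

# rank-based AUROC of score for a logical label
aurocOf <- function(score, label) {
  n1 <- sum(label); n0 <- sum(!label)
  (sum(rank(score)[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

writeTempEdges <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}
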