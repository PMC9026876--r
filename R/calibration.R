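#' Degree-matched permutation null distribution
#'
#' Raw model scores of \code{N} proteins drawn uniformly (with replacement)
#' from the log2-degree bin of \code{candidateDegree}, excluding the motive
#' proteins themselves.  If the bin holds no eligible protein the nearest
#' non-empty bin is used, with a warning.  Reproducible under \code{seed}.
#'
#' @param graph a [KnowledgeGraph-class]
#' @param model a trained [RelationshipModel-class]
#' @param motiveProteins the motive effector set being scored against.
#' @param candidateDegree degree of the candidate the null is matched to.
#' @param N number of null draws (>= 100; default 1000).
#' @param seed integer sampling seed.
#' @param restart walk restart probability (must match the scorer's).
#' @param rwr,cap optional precomputed walk vector and distance cap, reused
#'   by the batch scorer.
#' @return a [NullDistribution-class] with scores sorted ascending.
#' @export
permutationNull <- function(graph, model, motiveProteins, candidateDegree,
                            N = 1000L, seed = 1L, restart = 0.3,
                            rwr = NULL, cap = NULL) {
  stopifnot(N >= 100)
  motiveProteins <- unique(normalizeAccession(motiveProteins))
  deg <- degreeSequence(graph)
  bins <- degreeBin(deg)
  b <- degreeBin(as.integer(candidateDegree))
  pool <- setdiff(nodeIds(graph), motiveProteins)
  binPool <- pool[bins[pool] == b]
  if (!length(binPool)) {
    d <- abs(bins[pool] - b)
    binPool <- pool[d == min(d)]
    warning("degree bin ", b, " empty; falling back to nearest bin ",
            bins[binPool[1]])
  }
  set.seed(as.integer(seed))
  draws <- sample(binPool, N, replace = TRUE)
  X <- featureMatrix(graph, draws, motiveProteins, restart = restart,
                     rwr = rwr, cap = cap)
  raw <- predictRaw(model, X)
  new("NullDistribution", scores = sort(raw), seed = as.integer(seed),
      bin = as.integer(b))
}

#' @rdname NullDistribution-accessors
#' @param x a [NullDistribution-class]
#' @export
setMethod("nullScores", "NullDistribution", function(x) x@scores)

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution: N=%d, degree bin %d, seed %d\n",
              length(object@scores), object@bin, object@seed))
})

#' Empirical p-value of a raw score against a null distribution
#'
#' Uses the add-one estimator \eqn{p = (1 + \#\{null \ge raw\}) / (N + 1)},
#' so p is never 0 and lies in (0, 1].
#'
#' @param raw numeric vector of raw model scores.
#' @param null a [NullDistribution-class]
#' @return numeric vector of empirical p-values.
#' @export
empiricalP <- function(raw, null) {
  s <- nullScores(null)
  N <- length(s)
  # count of null >= raw via the sorted vector
  nGreater <- N - findInterval(raw - 1e-15, s)
  (1 + nGreater) / (N + 1)
}

# log10(p) anchor points of the score scale
.annAnchors <- data.frame(
  logp = log10(c(0.001, 0.01, 0.05, 0.15, 0.25, 1.0)),
  score = c(100, 92, 78, 63, 38, 0)
)

#' Calibrate an empirical p-value to the 0-100 relationship score
#'
#' Piecewise-linear map in log10(p) through the published band anchors
#' (p = 0.01 -> 92, 0.05 -> 78, 0.15 -> 63, 0.25 -> 38), extended linearly
#' from (0.01, 92) to (0.001, 100) above the top anchor (clamped at 100) and
#' from (0.25, 38) to (1, 0) below the bottom one.  Strictly monotone
#' decreasing in p over (0.001, 1].
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of scores in [0, 100].
#' @examples
#' calibrateToAnn(c(0.01, 0.05, 0.15, 0.25, 1))
#' @export
calibrateToAnn <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  s <- stats::approx(.annAnchors$logp, .annAnchors$score, xout = log10(p),
                     rule = 2)$y
  pmin(pmax(s, 0), 100)
}

#' Relationship category of a 0-100 score
#'
#' Bands use closed lower bounds: very_high [92, 100], high [78, 92),
#' medium_high [63, 78), medium [38, 63), low [0, 38).  The first three
#' constitute a "strong" relationship.
#'
#' @param score numeric vector in [0, 100] (NA allowed for unscored cells).
#' @return character vector of categories.
#' @examples
#' scoreCategory(c(92, 86.48, 63, 50, 10))
#' @export
scoreCategory <- function(score) {
  lv <- c("low", "medium", "medium_high", "high", "very_high")
  ifelse(is.na(score), NA_character_,
         lv[findInterval(score, c(-Inf, 38, 63, 78, 92))])
}

.strongCategories <- c("very_high", "high", "medium_high")

#' Is a score in a strong-relationship band?
#' @param score numeric vector in [0, 100].
#' @return logical vector (NA for NA scores).
#' @export
isStrong <- function(score) {
  !is.na(score) & score >= 63
}

#' Calibration check: score fresh degree-matched null candidates
#'
#' Draws \code{nPerMotive} fresh proteins per motive from the non-effector
#' pool, scores them with the trained model, converts each raw score to an
#' empirical p-value against the cached per-(motive, degree-bin) permutation
#' null, and calibrates to the 0-100 scale -- exactly the path a real
#' candidate takes.  By construction the fraction of these null candidates
#' reaching a band should not exceed the band's nominal p (e.g. about 1\%
#' at or above the very-high boundary of 92).
#'
#' @param graph a [KnowledgeGraph-class]
#' @param model a trained [RelationshipModel-class]
#' @param map a [DiseaseMap-class]
#' @param nPerMotive fresh null draws per motive (default 1000).
#' @param nNull draws per cached null distribution (default 1000).
#' @param restart walk restart probability.
#' @param includeGeneral also check against the general pseudo-motive.
#' @param seed integer seed.
#' @return data.frame with columns \code{motive_id}, \code{uniprot_id},
#'   \code{score}.
#' @export
nullCalibration <- function(graph, model, map, nPerMotive = 1000L,
                            nNull = 1000L, restart = 0.3,
                            includeGeneral = TRUE, seed = 1L) {
  sets <- motiveSets(map, includeGeneral = includeGeneral)
  deg <- degreeSequence(graph)
  cap <- distanceCap(graph)
  out <- list()
  for (j in seq_along(sets)) {
    M <- intersect(normalizeAccession(sets[[j]]), nodeIds(graph))
    pool <- setdiff(nodeIds(graph), M)
    set.seed(.deriveSeed(seed, j, 997L))  # distinct from any bin-null seed
    draws <- sample(pool, nPerMotive, replace = TRUE)
    rwr <- rwrProximity(graph, M, restart = restart)
    X <- featureMatrix(graph, unique(draws), M, restart = restart,
                       rwr = rwr, cap = cap)
    raw <- stats::setNames(predictRaw(model, X), unique(draws))[draws]
    bins <- degreeBin(deg[draws])
    p <- numeric(length(draws))
    for (b in unique(bins)) {
      null <- permutationNull(graph, model, M, 2^max(b, 0), N = nNull,
                              seed = .deriveSeed(seed, j, b),
                              restart = restart, rwr = rwr, cap = cap)
      idx <- bins == b
      p[idx] <- empiricalP(raw[idx], null)
    }
    out[[j]] <- data.frame(motive_id = names(sets)[j], uniprot_id = draws,
                           score = calibrateToAnn(p),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
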