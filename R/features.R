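.featureNames <- c("d_min", "d_mean", "rwr_score", "jaccard_nbr", "degree_log")

# Neighbor accession sets, as a named list, for a subset of nodes.
.neighborSets <- function(kg, ids) {
  g <- kg@graph
  res <- igraph::adjacent_vertices(g, v = ids)
  lapply(res, function(v) v$name)
}

#' Proximity features for candidates against one motive protein set
#'
#' Computes, for each candidate, the feature vector the relationship
#' predictor consumes:
#' \describe{
#'   \item{d_min}{hops to the nearest motive protein (0 if the candidate is
#'     itself one);}
#'   \item{d_mean}{mean hops to the motive proteins (excluding the candidate
#'     itself when it belongs to the set);}
#'   \item{rwr_score}{probability mass at the candidate under a random walk
#'     with restart seeded on the motive proteins (the candidate is excluded
#'     from the seed set when it is a motive protein);}
#'   \item{jaccard_nbr}{Jaccard overlap between the candidate's neighborhood
#'     and the union neighborhood of the motive proteins;}
#'   \item{degree_log}{log(1 + degree) of the candidate.}
#' }
#' Unreachable distances are capped at [distanceCap()] (largest-component
#' diameter + 1) before entering the vector.  A candidate absent from the
#' graph receives the sentinel vector (capped distances, rwr 0, jaccard 0,
#' degree 0) and a \code{"missing_from_graph"} QC flag.
#'
#' @param graph a [KnowledgeGraph-class]
#' @param candidates character vector of candidate accessions.
#' @param motiveProteins non-empty accession set defining the motive.
#' @param restart restart probability for the walk.
#' @param rwr optional precomputed [rwrProximity()] vector for
#'   \code{motiveProteins} (reused across candidates by the batch scorer).
#' @param cap optional precomputed [distanceCap()].
#' @return numeric matrix (candidates x features) with a \code{qc} attribute:
#'   character vector of per-candidate QC flags (\code{""} when clean).
#' @export
featureMatrix <- function(graph, candidates, motiveProteins, restart = 0.3,
                          rwr = NULL, cap = NULL) {
  stopifnot(length(motiveProteins) >= 1)
  candidates <- normalizeAccession(candidates)
  motiveProteins <- unique(normalizeAccession(motiveProteins))
  nodes <- nodeIds(graph)
  M <- intersect(motiveProteins, nodes)
  if (is.null(cap)) cap <- distanceCap(graph)
  X <- matrix(0, length(candidates), length(.featureNames),
              dimnames = list(candidates, .featureNames))
  qc <- character(length(candidates))
  present <- candidates %in% nodes
  qc[!present] <- "missing_from_graph"
  X[!present, "d_min"] <- cap
  X[!present, "d_mean"] <- cap
  if (length(M) == 0) {
    qc[present] <- "motive_absent_from_graph"
    X[present, "d_min"] <- cap
    X[present, "d_mean"] <- cap
    deg <- degreeSequence(graph)
    X[present, "degree_log"] <- log1p(deg[candidates[present]])
    attr(X, "qc") <- qc
    return(X)
  }
  if (is.null(rwr)) rwr <- rwrProximity(graph, M, restart = restart)
  pres <- candidates[present]
  deg <- degreeSequence(graph)
  D <- igraph::distances(graph@graph, v = pres, to = M)
  D[is.infinite(D)] <- cap
  nbrM <- unique(unlist(.neighborSets(graph, M)))
  nbrC <- .neighborSets(graph, pres)
  for (i in seq_along(pres)) {
    cand <- pres[i]
    row <- which(candidates == cand)
    inM <- cand %in% M
    fill <- function(v)  # row may index several duplicated candidate rows
      matrix(v, nrow = length(row), ncol = length(v), byrow = TRUE)
    if (inM && length(M) == 1) {
      # degenerate: the candidate IS the whole motive set
      X[row, ] <- fill(c(0, 0, 1, 1, log1p(deg[cand])))
      next
    }
    dl <- D[i, , drop = TRUE]
    if (inM) {
      others <- M != cand
      dmin <- 0
      dmean <- mean(dl[others])
      Mx <- M[others]
      px <- rwrProximity(graph, Mx, restart = restart)
      rwrScore <- px[cand]
      nbrMx <- unique(unlist(.neighborSets(graph, Mx)))
    } else {
      dmin <- min(dl)
      dmean <- mean(dl)
      rwrScore <- rwr[cand]
      nbrMx <- nbrM
    }
    u <- union(nbrC[[i]], nbrMx)
    jac <- if (length(u)) length(intersect(nbrC[[i]], nbrMx)) / length(u) else 0
    X[row, ] <- fill(c(dmin, dmean, rwrScore, jac, log1p(deg[cand])))
  }
  attr(X, "qc") <- qc
  X
}

#' @rdname featureMatrix
#' @param candidate a single candidate accession.
#' @return \code{computeFeatures} returns a named numeric feature vector with
#'   a \code{qc} attribute.
#' @export
computeFeatures <- function(graph, candidate, motiveProteins, restart = 0.3) {
  X <- featureMatrix(graph, candidate, motiveProteins, restart = restart)
  v <- X[1, ]
  attr(v, "qc") <- attr(X, "qc")[1]
  v
}
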