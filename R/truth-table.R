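#' log2 degree bin used for degree matching
#'
#' Heavy-tailed interaction-network degrees are matched on a logarithmic
#' scale: bin = floor(log2(degree)), with isolated nodes (degree 0) in their
#' own bin (-1).
#'
#' @param degree integer vector of node degrees.
#' @return integer bin indices.
#' @export
degreeBin <- function(degree) {
  b <- rep(-1L, length(degree))
  names(b) <- names(degree)
  pos <- degree > 0
  b[pos] <- as.integer(floor(log2(degree[pos])))
  b
}

#' Build a labelled truth table of protein-motive pairs
#'
#' Positives are every (effector, its motive) assignment from the disease
#' map (including the general characterization pseudo-motive) whose effector
#' is present in the graph.  Negatives are degree-matched proteins (same
#' log2-degree bin as a positive, nearest non-empty bin as fallback) sampled
#' without replacement per motive at shortest-path distance at least
#' \code{minNegDistance} from the motive's effector set, \code{negPerPos}
#' per positive.  Reproducible under \code{seed}.
#'
#' @param map a [DiseaseMap-class] with at least one motive whose effectors
#'   are in the graph.
#' @param graph a [KnowledgeGraph-class]
#' @param negPerPos negatives sampled per positive (default 2).
#' @param minNegDistance minimum hop distance of a negative from the motive
#'   set (default 2: in small-world interaction networks, module
#'   neighborhoods cover most of the graph within two hops, so larger floors
#'   leave too few eligible proteins).
#' @param seed integer sampling seed.
#' @return a [TruthTable-class]
#' @export
buildTruthTable <- function(map, graph, negPerPos = 2, minNegDistance = 2,
                            seed = 1L) {
  sets <- motiveSets(map, includeGeneral = TRUE)
  nodes <- nodeIds(graph)
  deg <- degreeSequence(graph)
  bins <- degreeBin(deg)
  set.seed(as.integer(seed))
  rows <- list()
  anyPos <- FALSE
  for (m in names(sets)) {
    eff <- intersect(sets[[m]], nodes)
    if (!length(eff)) next
    anyPos <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      uniprot_id = eff, motive_id = m, label = "related",
      stringsAsFactors = FALSE)
    D <- igraph::distances(graph@graph, v = nodes, to = eff)
    dmin <- apply(D, 1, min)
    eligible <- nodes[dmin >= minNegDistance]
    chosen <- character(0)
    for (e in eff) {
      b <- bins[e]
      for (k in seq_len(negPerPos)) {
        poolBins <- bins[eligible]
        avail <- setdiff(eligible[poolBins == b], chosen)
        if (!length(avail)) {
          # widen to the nearest non-empty bin
          remaining <- setdiff(eligible, chosen)
          if (!length(remaining))
            stop("cannot find enough negatives for motive '", m,
                 "'; try a smaller minNegDistance")
          d2 <- abs(bins[remaining] - b)
          avail <- remaining[d2 == min(d2)]
        }
        pick <- if (length(avail) == 1) avail else sample(avail, 1)
        chosen <- c(chosen, pick)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      uniprot_id = chosen, motive_id = m, label = "unrelated",
      stringsAsFactors = FALSE)
  }
  if (!anyPos)
    stop("no motive has effectors present in the graph")
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  new("TruthTable", pairs = pairs, seed = as.integer(seed))
}

#' Accessor for TruthTable rows
#' @param x a [TruthTable-class]
#' @name TruthTable-accessors
#' @export
setMethod("truthPairs", "TruthTable", function(x) x@pairs)

setMethod("show", "TruthTable", function(object) {
  tab <- table(object@pairs$label)
  cat("TruthTable:", nrow(object@pairs), "pairs (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "), seed", object@seed, "\n")
})
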