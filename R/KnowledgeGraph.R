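#' Normalize a UniProt accession
#'
#' Uppercases and strips isoform suffixes (\code{"P07996-2"} becomes
#' \code{"P07996"}) so that identifiers from different sources collapse onto
#' canonical accessions.
#'
#' @param x character vector of accession-like identifiers.
#' @return character vector of normalized accessions.
#' @examples
#' normalizeAccession(c("p07996-2", "P14625"))
#' @export
normalizeAccession <- function(x) {
  sub("-[0-9]+$", "", toupper(trimws(x)))
}

.knownLayers <- c("physical", "signaling", "metabolic", "regulation",
                  "synthetic", "module")

#' Construct a KnowledgeGraph from an edge table
#'
#' Builds the collapsed simple undirected graph from layer-tagged edge
#' records.  Within each layer, duplicate unordered pairs are removed;
#' across layers the same pair may appear once per layer but counts once for
#' topology.
#'
#' @param edges data.frame with columns \code{source}, \code{target} and
#'   optionally \code{layer}, \code{provenance}.
#' @param nodes additional (possibly isolated) node accessions.
#' @param loadReport optional named list of load diagnostics.
#' @return a [KnowledgeGraph-class] object.
#' @export
KnowledgeGraph <- function(edges = NULL, nodes = character(0),
                           loadReport = list()) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        layer = character(0), provenance = character(0),
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(edges$layer)) edges$layer <- "physical"
    if (is.null(edges$provenance)) edges$provenance <- ""
    edges$source <- normalizeAccession(edges$source)
    edges$target <- normalizeAccession(edges$target)
    flip <- edges$source > edges$target
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
    edges <- edges[edges$source != edges$target, , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("source", "target", "layer")]), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- unique(c(normalizeAccession(nodes), edges$source, edges$target))
  nodes <- nodes[nzchar(nodes)]
  pairs <- unique(edges[, c("source", "target")])
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE, vertices = nodes)
  new("KnowledgeGraph", edgeTable = edges, graph = g, loadReport = loadReport)
}

#' Read a protein interaction edge list
#'
#' Reads a TSV edge list (\code{source<TAB>target[<TAB>provenance]}) or a SIF
#' file (\code{source relation target}, whitespace-delimited) into a
#' single-layer [KnowledgeGraph-class].  Lines starting with \code{#} and
#' blank lines are skipped.  Self-loops are dropped silently; duplicated
#' unordered pairs are deduplicated; both are counted in the load report.
#'
#' @param path file path.
#' @param layer layer tag for every edge in this file; one of
#'   \code{"physical"}, \code{"signaling"}, \code{"metabolic"},
#'   \code{"regulation"} (or \code{"synthetic"} for generated networks).
#' @param format \code{"tsv"}, \code{"sif"}, or \code{"auto"} (by file
#'   extension, default TSV).
#' @return a [KnowledgeGraph-class]; see [loadReport()] for diagnostics.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("P14625\tP07996", "P07996\tP08123"), tf)
#' kg <- readEdgeList(tf, layer = "physical")
#' edgeCount(kg)
#' @export
readEdgeList <- function(path, layer = "physical", format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  if (!layer %in% .knownLayers)
    stop("unknown layer tag '", layer, "'; expected one of: ",
         paste(.knownLayers, collapse = ", "))
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  src <- tgt <- prov <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    if (format == "tsv") {
      f <- strsplit(raw[ln], "\t", fixed = TRUE)[[1]]
      if (length(f) < 2)
        stop("malformed line ", ln, " in ", path, ": expected >= 2 tab-separated fields")
      src[i] <- f[1]; tgt[i] <- f[2]
      prov[i] <- if (length(f) >= 3) f[3] else ""
    } else {
      f <- strsplit(trimws(raw[ln]), "\\s+")[[1]]
      if (length(f) != 3)
        stop("malformed line ", ln, " in ", path, ": SIF needs 'source relation target'")
      src[i] <- f[1]; tgt[i] <- f[3]; prov[i] <- f[2]
    }
    if (!nzchar(trimws(src[i])) || !nzchar(trimws(tgt[i])))
      stop("empty identifier on line ", ln, " in ", path)
  }
  src <- normalizeAccession(src)
  tgt <- normalizeAccession(tgt)
  selfLoops <- sum(src == tgt)
  ok <- src != tgt
  a <- pmin(src[ok], tgt[ok])
  b <- pmax(src[ok], tgt[ok])
  dup <- duplicated(paste(a, b))
  edges <- data.frame(source = a[!dup], target = b[!dup],
                      layer = rep(layer, sum(!dup)),
                      provenance = prov[ok][!dup], stringsAsFactors = FALSE)
  rep <- list(lines = length(keep),
              unique_edges = nrow(edges),
              self_loops_dropped = selfLoops,
              duplicates_dropped = sum(dup))
  KnowledgeGraph(edges, nodes = unique(c(src, tgt)), loadReport = rep)
}

#' Merge connectivity layers into one map
#'
#' Node set is the union; an unordered pair present in k layers keeps its k
#' layer-tagged records but contributes a single edge to the collapsed
#' topology used by all proximity computations.
#'
#' @param graphs list of [KnowledgeGraph-class] objects sharing one ID
#'   namespace.
#' @return merged [KnowledgeGraph-class]; an empty list yields an empty graph.
#' @export
mergeGraphs <- function(graphs) {
  if (length(graphs) == 0) return(KnowledgeGraph())
  stopifnot(all(vapply(graphs, is, logical(1), "KnowledgeGraph")))
  edges <- do.call(rbind, lapply(graphs, function(g) g@edgeTable))
  nodes <- unique(unlist(lapply(graphs, nodeIds)))
  reps <- lapply(graphs, loadReport)
  KnowledgeGraph(edges, nodes = nodes,
                 loadReport = list(merged_from = length(graphs),
                                   layer_reports = reps))
}

#' @describeIn KnowledgeGraph-accessors node accessions
#' @export
setMethod("nodeIds", "KnowledgeGraph", function(x) igraph::V(x@graph)$name)

#' Accessors for KnowledgeGraph
#'
#' \code{nodeCount}/\code{edgeCount} report the collapsed simple topology;
#' \code{layerTable} returns the per-layer edge records; \code{loadReport}
#' the reader diagnostics.
#'
#' @param x a [KnowledgeGraph-class]
#' @name KnowledgeGraph-accessors
#' @export
setMethod("nodeCount", "KnowledgeGraph", function(x) igraph::vcount(x@graph))

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("edgeCount", "KnowledgeGraph", function(x) igraph::ecount(x@graph))

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("layerTable", "KnowledgeGraph", function(x) x@edgeTable)

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("loadReport", "KnowledgeGraph", function(x) x@loadReport)

#' Degree of every node in the collapsed simple graph
#'
#' @param x a [KnowledgeGraph-class]
#' @return named integer vector, accession to degree.
#' @name degreeSequence
#' @export
setMethod("degreeSequence", "KnowledgeGraph", function(x) {
  d <- igraph::degree(x@graph)
  storage.mode(d) <- "integer"
  d
})

setMethod("show", "KnowledgeGraph", function(object) {
  cat("KnowledgeGraph with", nodeCount(object), "proteins and",
      edgeCount(object), "interactions\n")
  if (nrow(object@edgeTable)) {
    tab <- table(object@edgeTable$layer)
    cat("  layer records:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
})

.checkNodes <- function(kg, ids) {
  missing <- setdiff(ids, nodeIds(kg))
  if (length(missing))
    stop("node(s) not in graph: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Shortest-path hop distance between two proteins
#'
#' Minimal number of edges on any path in the collapsed simple graph; 0 iff
#' the two accessions are identical, \code{Inf} (the UNREACHABLE sentinel)
#' iff the nodes lie in different components.
#'
#' @param graph a [KnowledgeGraph-class]
#' @param a,b node accessions present in the graph.
#' @return numeric hop count, or \code{Inf} if unreachable.
#' @export
shortestPathLength <- function(graph, a, b) {
  a <- normalizeAccession(a); b <- normalizeAccession(b)
  .checkNodes(graph, c(a, b))
  as.numeric(igraph::distances(graph@graph, v = a, to = b)[1, 1])
}

#' Random walk with restart proximity
#'
#' Stationary distribution of a walk on the collapsed simple graph that at
#' each step restarts with probability \code{restart} (uniformly over the
#' seed set) and otherwise moves uniformly over the current node's
#' neighbors.  A walker stranded on a node without neighbors restarts.
#' Solved by power iteration to \code{tol} in the sup norm.
#'
#' @param graph a [KnowledgeGraph-class]
#' @param seeds non-empty set of node accessions.
#' @param restart restart probability in (0, 1); default 0.3, the common
#'   choice for network propagation on interaction maps.
#' @param tol convergence tolerance; default 1e-10.
#' @param maxIter iteration cap.
#' @return named numeric vector over all nodes, summing to 1 within
#'   \code{tol}.
#' @export
rwrProximity <- function(graph, seeds, restart = 0.3, tol = 1e-10,
                         maxIter = 10000L) {
  stopifnot(length(seeds) >= 1, restart > 0, restart < 1, tol > 0)
  seeds <- unique(normalizeAccession(seeds))
  .checkNodes(graph, seeds)
  g <- graph@graph
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  s <- numeric(n); names(s) <- nm
  s[seeds] <- 1 / length(seeds)
  if (n == 1) return(s)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  W <- A %*% Matrix::Diagonal(n, inv)  # column-stochastic where deg > 0
  dangling <- deg == 0
  p <- s
  for (i in seq_len(maxIter)) {
    pNew <- restart * s +
      (1 - restart) * (as.numeric(W %*% p) + sum(p[dangling]) * s)
    if (max(abs(pNew - p)) < tol) {
      p <- pNew
      break
    }
    p <- pNew
  }
  names(p) <- nm
  p / sum(p)
}

#' Diameter-based cap for unreachable distances
#'
#' Returns diameter of the largest connected component plus one; used by the
#' feature builder to convert the \code{Inf} unreachable sentinel into a
#' finite hop count strictly larger than any realized distance.
#'
#' @param graph a [KnowledgeGraph-class]
#' @return integer cap.
#' @export
distanceCap <- function(graph) {
  g <- graph@graph
  if (igraph::vcount(g) == 0) return(1L)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  as.integer(igraph::diameter(sub, unconnected = FALSE)) + 1L
}
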