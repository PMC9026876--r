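#' Generate a scale-free interaction network
#'
#' Preferential attachment: the seed graph is a single edge, and every
#' subsequent node attaches to \code{edgesPerNode} distinct existing nodes
#' with probability proportional to degree.  The result is connected and
#' simple, with \code{edgesPerNode * (nNodes - 2) + 1} edges, and emulates
#' the heavy-tailed degree distribution of protein interaction maps.  Node
#' accessions are \code{SYN0001 ...}.
#'
#' @param nNodes number of proteins (>= 2).
#' @param edgesPerNode attachment edges per new node (>= 1, < nNodes).
#' @param seed integer generator seed.
#' @return a [KnowledgeGraph-class] with a single \code{synthetic} layer.
#' @export
generateGraph <- function(nNodes, edgesPerNode, seed = 1L) {
  if (nNodes < 2 || edgesPerNode < 1 || edgesPerNode >= nNodes)
    stop("need nNodes >= 2 and 1 <= edgesPerNode < nNodes")
  set.seed(as.integer(seed))
  g <- igraph::sample_pa(nNodes, power = 1, m = edgesPerNode,
                         directed = FALSE, algorithm = "psumtree")
  igraph::V(g)$name <- sprintf("SYN%04d", seq_len(nNodes))
  el <- igraph::as_edgelist(g)
  KnowledgeGraph(data.frame(source = el[, 1], target = el[, 2],
                            layer = "synthetic", provenance = "generated",
                            stringsAsFactors = FALSE),
                 loadReport = list(generator = "preferential_attachment",
                                   nNodes = nNodes,
                                   edgesPerNode = edgesPerNode,
                                   seed = as.integer(seed)))
}

# sample that never falls into the scalar 1:x trap
.sampleFrom <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# internal edge density of a node set in the collapsed graph
.setDensity <- function(g, members) {
  k <- length(members)
  if (k < 2) return(1)
  sub <- igraph::induced_subgraph(g, members)
  igraph::ecount(sub) / choose(k, 2)
}

#' Plant densely wired motive modules in a network
#'
#' Selects \code{kMotives} disjoint connected node sets (breadth-first from
#' random roots) as effector sets, and adds intra-set edges (layer
#' \code{module}) until each set's internal edge density reaches
#' \code{minDensity}, so each motive is a genuinely proximal neighborhood.
#' Causal levels are assigned round-robin.  The general characterization
#' pseudo-motive is given the union of all module members.
#'
#' @param graph a [KnowledgeGraph-class]
#' @param kMotives number of modules.
#' @param sizeRange integer (lo, hi) module sizes, sampled uniformly.
#' @param minDensity internal edge density floor (default 0.3).
#' @param seed integer seed.
#' @return list with \code{graph} (edges added) and \code{map}
#'   (a [DiseaseMap-class] of planted motives).
#' @export
plantMotives <- function(graph, kMotives, sizeRange = c(8, 15),
                         minDensity = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  g <- graph@graph
  n <- igraph::vcount(g)
  if (kMotives * max(sizeRange) > n / 2)
    stop("modules would cover more than half the graph; reduce kMotives or sizes")
  used <- character(0)
  modules <- list()
  for (k in seq_len(kMotives)) {
    size <- .sampleFrom(seq(sizeRange[1], sizeRange[2]), 1)
    placed <- FALSE
    for (attempt in seq_len(200)) {
      root <- .sampleFrom(setdiff(nodeIds(graph), used), 1)
      ord <- igraph::bfs(g, root, unreachable = FALSE)$order
      ord <- igraph::V(g)$name[as.integer(ord[!is.na(ord)])]
      ord <- setdiff(ord, used)
      if (length(ord) >= size) {
        modules[[k]] <- ord[seq_len(size)]
        used <- c(used, modules[[k]])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place ", kMotives, " disjoint modules of size ",
           sizeRange[1], "-", sizeRange[2])
  }
  # densify each module
  extra <- list()
  for (k in seq_len(kMotives)) {
    mem <- modules[[k]]
    while (.setDensity(g, mem) < minDensity) {
      pair <- .sampleFrom(mem, 2)
      if (!igraph::are_adjacent(g, pair[1], pair[2])) {
        g <- igraph::add_edges(g, pair)
        extra[[length(extra) + 1L]] <- sort(pair)
      }
    }
  }
  edges <- graph@edgeTable
  if (length(extra)) {
    em <- do.call(rbind, extra)
    edges <- rbind(edges, data.frame(source = em[, 1], target = em[, 2],
                                     layer = "module",
                                     provenance = "planted",
                                     stringsAsFactors = FALSE))
  }
  newGraph <- KnowledgeGraph(edges, nodes = nodeIds(graph),
                             loadReport = graph@loadReport)
  levels <- rep(c("causative", "symptomatic", "both"),
                length.out = kMotives)
  motives <- lapply(seq_len(kMotives), function(k)
    list(id = sprintf("M%02d", k), name = sprintf("Planted module %d", k),
         level = levels[k], effectors = modules[[k]]))
  map <- DiseaseMap(motives, generalEffectors = unlist(modules))
  list(graph = newGraph, map = map)
}

#' Plant candidates at controlled proximity to the motive modules
#'
#' Related candidates are new nodes wired with \code{attachEdges} edges into
#' one module (hence at hop distance 1 from that motive); unrelated
#' candidates are existing non-module nodes at distance at least
#' \code{unrelatedMinDistance} from every module.  Ground-truth labels are
#' recorded in the \code{true_motive} column (\code{NA} for unrelated).
#'
#' @param graph a [KnowledgeGraph-class] (as returned by [plantMotives()]).
#' @param map the planted [DiseaseMap-class]
#' @param nRelatedPerMotive related candidates planted per motive.
#' @param nUnrelated unrelated candidates drawn from existing nodes (their
#'   degrees stay realistic for degree-matched nulls).
#' @param attachEdges edges wiring each related candidate into its module.
#' @param unrelatedMinDistance minimum hop distance of an unrelated candidate
#'   from every module (default 2; see [buildTruthTable()] for why larger
#'   floors are rarely satisfiable in small-world networks).
#' @param seed integer seed.
#' @return list with \code{graph} (new nodes and edges added) and
#'   \code{candidates} (a [CandidateList-class] with ground truth).
#' @export
plantCandidates <- function(graph, map, nRelatedPerMotive = 5,
                            nUnrelated = 20, attachEdges = 3,
                            unrelatedMinDistance = 2, seed = 1L) {
  set.seed(as.integer(seed))
  sets <- motiveSets(map, includeGeneral = FALSE)
  allModule <- unique(unlist(sets))
  ids <- character(0); motive <- character(0)
  edges <- graph@edgeTable
  cnt <- 0L
  for (m in names(sets)) {
    for (r in seq_len(nRelatedPerMotive)) {
      cnt <- cnt + 1L
      cid <- sprintf("CANDR%03d", cnt)
      anchors <- .sampleFrom(sets[[m]], min(attachEdges, length(sets[[m]])))
      edges <- rbind(edges, data.frame(
        source = pmin(cid, anchors), target = pmax(cid, anchors),
        layer = "synthetic", provenance = "planted_candidate",
        stringsAsFactors = FALSE))
      ids <- c(ids, cid); motive <- c(motive, m)
    }
  }
  newGraph <- KnowledgeGraph(edges, nodes = c(nodeIds(graph), ids),
                             loadReport = graph@loadReport)
  unrelIds <- character(0)
  if (nUnrelated > 0) {
    D <- igraph::distances(newGraph@graph,
                           v = setdiff(nodeIds(graph), allModule),
                           to = allModule)
    dmin <- apply(D, 1, min)
    pool <- names(dmin)[dmin >= unrelatedMinDistance]
    if (length(pool) < nUnrelated)
      stop("only ", length(pool), " nodes at distance >= ",
           unrelatedMinDistance,
           " from all modules; try a smaller unrelatedMinDistance")
    unrelIds <- sort(.sampleFrom(pool, nUnrelated))
  }
  entries <- data.frame(
    uniprot_id = c(ids, unrelIds),
    protein_name = c(sprintf("Planted related candidate %d", seq_along(ids)),
                     sprintf("Background protein %d", seq_along(unrelIds))),
    source_refs = rep("synthetic", length(ids) + length(unrelIds)),
    true_motive = c(motive, rep(NA_character_, length(unrelIds))),
    stringsAsFactors = FALSE)
  list(graph = newGraph, candidates = CandidateList(entries))
}

#' Simulate a complete synthetic study
#'
#' Composes [generateGraph()], [plantMotives()], [plantCandidates()] and
#' [buildTruthTable()] under per-stage seeds derived from \code{seed}.  The
#' defaults (500 proteins, 3 attachment edges, 4 planted modules of 8-15
#' effectors, 5 related candidates per module, 20 unrelated) give a
#' desk-scale study on which every pipeline stage is exercised end to end.
#'
#' @param nNodes,edgesPerNode network size and attachment density.
#' @param kMotives,sizeRange,minDensity module parameters.
#' @param nRelatedPerMotive,nUnrelated,attachEdges,unrelatedMinDistance
#'   candidate-planting parameters.
#' @param negPerPos,minNegDistance truth-table parameters.
#' @param seed master seed; stage seeds are fixed offsets of it.
#' @return a [SyntheticStudy-class]
#' @export
simulateStudy <- function(nNodes = 500, edgesPerNode = 3, kMotives = 4,
                          sizeRange = c(8, 15), minDensity = 0.3,
                          nRelatedPerMotive = 5, nUnrelated = 20,
                          attachEdges = 3, unrelatedMinDistance = 2,
                          negPerPos = 2, minNegDistance = 2, seed = 1L) {
  seed <- as.integer(seed)
  params <- list(nNodes = nNodes, edgesPerNode = edgesPerNode,
                 kMotives = kMotives, sizeRange = sizeRange,
                 minDensity = minDensity,
                 nRelatedPerMotive = nRelatedPerMotive,
                 nUnrelated = nUnrelated, attachEdges = attachEdges,
                 unrelatedMinDistance = unrelatedMinDistance,
                 negPerPos = negPerPos, minNegDistance = minNegDistance)
  g0 <- generateGraph(nNodes, edgesPerNode, seed = seed)
  pm <- plantMotives(g0, kMotives, sizeRange, minDensity, seed = seed + 1L)
  pc <- plantCandidates(pm$graph, pm$map, nRelatedPerMotive, nUnrelated,
                        attachEdges, unrelatedMinDistance, seed = seed + 2L)
  tt <- buildTruthTable(pm$map, pc$graph, negPerPos = negPerPos,
                        minNegDistance = minNegDistance, seed = seed + 3L)
  new("SyntheticStudy", graph = pc$graph, map = pm$map,
      candidates = pc$candidates, truth = tt, params = params, seed = seed)
}

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy (seed", object@seed, "):",
      nodeCount(object@graph), "nodes,",
      edgeCount(object@graph), "edges,",
      length(object@map@motives), "planted motives,",
      nrow(candidateTable(object@candidates)), "candidates\n")
})

#' Check the distance contracts of a synthetic study
#'
#' Verifies exhaustively that every planted related candidate is at hop
#' distance 1 of its motive's effector set and every unrelated candidate at
#' distance >= \code{unrelatedMinDistance} from all modules.
#'
#' @param study a [SyntheticStudy-class]
#' @return TRUE invisibly, or an error describing the violated contract.
#' @export
checkStudyInvariants <- function(study) {
  ct <- candidateTable(study@candidates)
  sets <- motiveSets(study@map, includeGeneral = FALSE)
  for (i in seq_len(nrow(ct))) {
    id <- ct$uniprot_id[i]
    if (!is.na(ct$true_motive[i])) {
      d <- min(igraph::distances(study@graph@graph, v = id,
                                 to = sets[[ct$true_motive[i]]]))
      if (d != 1)
        stop("related candidate ", id, " at distance ", d, " from its motive")
    } else {
      for (m in names(sets)) {
        d <- min(igraph::distances(study@graph@graph, v = id, to = sets[[m]]))
        if (d < study@params$unrelatedMinDistance)
          stop("unrelated candidate ", id, " at distance ", d,
               " from motive ", m)
      }
    }
  }
  invisible(TRUE)
}
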