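#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' KnowledgeGraph: a multi-layer protein interaction map
#'
#' Undirected protein interaction network assembled from one or more
#' knowledge-oriented connectivity layers (physical interactions, signaling,
#' metabolic relationships, regulation of gene expression).  Layer membership
#' is retained per edge record, but all proximity computations (shortest
#' paths, random walks, degrees) run on the collapsed simple graph: an
#' unordered protein pair supported by several layers counts once for
#' topology.
#'
#' @slot edgeTable data.frame with columns \code{source}, \code{target},
#'   \code{layer}, \code{provenance}; one row per layer-tagged edge record,
#'   deduplicated within layer, \code{source < target} lexicographically.
#' @slot graph the collapsed simple undirected \pkg{igraph} object; vertex
#'   names are normalized UniProt accessions.  May contain isolated nodes.
#' @slot loadReport named list of load diagnostics (line counts, dropped
#'   self-loops, dropped duplicates) accumulated by the readers.
#'
#' @seealso [readEdgeList()], [mergeGraphs()], [rwrProximity()]
#' @export
setClass("KnowledgeGraph",
  representation(
    edgeTable = "data.frame",
    graph = "ANY",
    loadReport = "list"
  )
)

setValidity("KnowledgeGraph", function(object) {
  msg <- character(0)
  et <- object@edgeTable
  need <- c("source", "target", "layer", "provenance")
  if (!all(need %in% names(et)))
    msg <- c(msg, paste("edgeTable must have columns:",
                        paste(need, collapse = ", ")))
  if (!igraph::is_igraph(object@graph))
    msg <- c(msg, "graph slot must be an igraph object")
  else {
    nodes <- igraph::V(object@graph)$name
    if (nrow(et) && !all(c(et$source, et$target) %in% nodes))
      msg <- c(msg, "edgeTable endpoints missing from the node set")
    if (any(et$source == et$target))
      msg <- c(msg, "self-loops are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' DiseaseMap: motives, causal levels, and effector protein sets
#'
#' The molecular characterization of a disease: a list of pathophysiological
#' processes ("motives"), each classified as \code{causative},
#' \code{symptomatic}, or \code{both}, with its curated effector protein set,
#' plus effectors of the disease in general.  The general characterization is
#' treated as a pseudo-motive (\code{das_general}) by scoring and counting so
#' that all processes are handled uniformly.
#'
#' @slot motives list; each element a list with fields \code{id},
#'   \code{name}, \code{level}, \code{effectors} (character vector of
#'   accessions).
#' @slot generalEffectors character vector of accessions: effectors of the
#'   disease in general.
#'
#' @seealso [loadDiseaseMap()], [motiveSets()]
#' @export
setClass("DiseaseMap",
  representation(
    motives = "list",
    generalEffectors = "character"
  )
)

.validLevels <- c("causative", "symptomatic", "both")

setValidity("DiseaseMap", function(object) {
  msg <- character(0)
  ids <- vapply(object@motives, function(m) m$id, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, paste("duplicate motive ids:",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lv <- vapply(object@motives, function(m) m$level, character(1))
  if (!all(lv %in% .validLevels))
    msg <- c(msg, paste("invalid motive level(s):",
                        paste(setdiff(lv, .validLevels), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' CandidateList: proteins submitted to prioritization
#'
#' @slot entries data.frame with at least \code{uniprot_id},
#'   \code{protein_name}, \code{source_refs}; synthetic studies append a
#'   \code{true_motive} ground-truth column.
#' @export
setClass("CandidateList",
  representation(entries = "data.frame")
)

setValidity("CandidateList", function(object) {
  e <- object@entries
  need <- c("uniprot_id", "protein_name", "source_refs")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$uniprot_id))
    return(paste("duplicate accessions:",
                 paste(unique(e$uniprot_id[duplicated(e$uniprot_id)]),
                       collapse = ", ")))
  TRUE
})

#' TruthTable: labelled protein-motive pairs for training
#'
#' Positives are (effector, its motive) assignments from a [DiseaseMap];
#' negatives are degree-matched proteins sampled away from the motive's
#' neighborhood.
#'
#' @slot pairs data.frame with columns \code{uniprot_id}, \code{motive_id},
#'   \code{label} (\code{"related"} or \code{"unrelated"}).
#' @slot seed integer seed the negatives were drawn under.
#' @export
setClass("TruthTable",
  representation(pairs = "data.frame", seed = "integer")
)

setValidity("TruthTable", function(object) {
  p <- object@pairs
  if (!all(c("uniprot_id", "motive_id", "label") %in% names(p)))
    return("pairs must have columns uniprot_id, motive_id, label")
  if (!all(p$label %in% c("related", "unrelated")))
    return("labels must be 'related' or 'unrelated'")
  key <- paste(p$uniprot_id, p$motive_id)
  if (any(tapply(p$label, key, function(x) length(unique(x))) > 1))
    return("a (protein, motive) pair carries both labels")
  TRUE
})

#' RelationshipModel: trained candidate-motive relationship predictor
#'
#' A single-hidden-layer feed-forward network (logistic activations) over the
#' five proximity features, trained by full-batch gradient descent under a
#' fixed seed.  Prediction is a deterministic function of the feature vector
#' given the stored weights; raw output lies in [0, 1].
#'
#' @slot weights list with matrices \code{W1} (hidden x features),
#'   \code{b1}, \code{W2} (1 x hidden), \code{b2}.
#' @slot center,scale numeric feature standardization parameters.
#' @slot featureNames character; feature ordering the weights assume.
#' @slot hyper list of hyperparameters used.
#' @slot seed integer training seed.
#' @slot metrics list of training diagnostics (held-out accuracy etc.).
#' @export
setClass("RelationshipModel",
  representation(
    weights = "list",
    center = "numeric",
    scale = "numeric",
    featureNames = "character",
    hyper = "list",
    seed = "integer",
    metrics = "list"
  )
)

#' NullDistribution: background raw scores of degree-matched proteins
#'
#' @slot scores numeric, sorted ascending raw model outputs of the sampled
#'   null proteins.
#' @slot seed integer sampling seed.
#' @slot bin integer log2-degree bin the nulls were drawn from.
#' @export
setClass("NullDistribution",
  representation(scores = "numeric", seed = "integer", bin = "integer")
)

setValidity("NullDistribution", function(object) {
  if (is.unsorted(object@scores))
    return("scores must be sorted ascending")
  TRUE
})

#' ScoreMatrix: candidate x motive relationship scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] with candidates as rows and
#' motives (including the \code{das_general} pseudo-motive) as columns.
#' Assays: \code{score} (0-100 relationship value), \code{p} (empirical
#' p-value; \code{NA} in fixture mode), \code{effector} (logical: is the
#' candidate a curated effector of that motive).  Unscored cells are
#' \code{NA}, which makes sparse fixture matrices (only strong-band rows
#' printed) first-class.  Categories are derived from \code{score} by
#' [scoreCategory()].
#'
#' @export
setClass("ScoreMatrix", contains = "SummarizedExperiment")

setValidity("ScoreMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("score", "effector") %in% an))
    return("ScoreMatrix needs 'score' and 'effector' assays")
  sc <- SummarizedExperiment::assay(object, "score")
  if (any(!is.na(sc) & (sc < 0 | sc > 100)))
    return("scores must lie in [0, 100]")
  TRUE
})

#' SyntheticStudy: a generated benchmark with known ground truth
#'
#' Bundle of a generated interaction network, planted motive modules, planted
#' candidates with ground-truth motive labels, and the truth table used for
#' training; fully reproducible from \code{params} and \code{seed}.
#'
#' @slot graph [KnowledgeGraph-class]
#' @slot map [DiseaseMap-class]
#' @slot candidates [CandidateList-class] (with \code{true_motive} column)
#' @slot truth [TruthTable-class]
#' @slot params list; the full generator parameter record.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticStudy",
  representation(
    graph = "KnowledgeGraph",
    map = "DiseaseMap",
    candidates = "CandidateList",
    truth = "TruthTable",
    params = "list",
    seed = "integer"
  )
)
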