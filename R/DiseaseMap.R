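#' Construct a DiseaseMap
#'
#' @param motives list of motive records; each a list with \code{id},
#'   \code{name}, \code{level} (\code{causative}, \code{symptomatic} or
#'   \code{both}) and a non-empty \code{effectors} accession vector.
#' @param generalEffectors accessions of effectors of the disease in general.
#' @return a [DiseaseMap-class]
#' @export
DiseaseMap <- function(motives = list(), generalEffectors = character(0)) {
  motives <- lapply(motives, function(m) {
    m$effectors <- unique(normalizeAccession(m$effectors))
    m
  })
  new("DiseaseMap", motives = motives,
      generalEffectors = unique(normalizeAccession(generalEffectors)))
}

#' Load a disease-map configuration
#'
#' Reads a YAML file with a top-level \code{motives} list (fields \code{id},
#' \code{name}, \code{level}, \code{effectors}) and a
#' \code{general_effectors} list.  Motive order is preserved.
#'
#' @param path YAML file path.
#' @return a [DiseaseMap-class]
#' @examples
#' map <- loadDiseaseMap(system.file("extdata", "as_disease_map.yaml",
#'                                   package = "motiveRank"))
#' motiveIds(map)
#' @export
loadDiseaseMap <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$motives) || !length(cfg$motives))
    stop("disease map '", path, "' declares no motives")
  motives <- lapply(cfg$motives, function(m) {
    for (f in c("id", "name", "level"))
      if (is.null(m[[f]])) stop("motive missing field '", f, "' in ", path)
    if (!m$level %in% .validLevels)
      stop("motive '", m$id, "': unknown level '", m$level, "' (expected ",
           paste(.validLevels, collapse = "/"), ")")
    if (is.null(m$effectors) || !length(m$effectors))
      stop("motive '", m$id, "' has an empty effector set")
    list(id = m$id, name = m$name, level = m$level,
         effectors = as.character(unlist(m$effectors)))
  })
  DiseaseMap(motives,
             generalEffectors = as.character(unlist(cfg$general_effectors)))
}

#' Serialize a DiseaseMap back to YAML
#'
#' Inverse of [loadDiseaseMap()]; load-serialize-load round-trips to an
#' identical object.
#'
#' @param map a [DiseaseMap-class]
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDiseaseMap <- function(map, path) {
  cfg <- list(
    motives = lapply(map@motives, function(m)
      list(id = m$id, name = m$name, level = m$level,
           effectors = as.list(m$effectors))),
    general_effectors = as.list(map@generalEffectors)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Accessors for DiseaseMap
#'
#' @param x a [DiseaseMap-class]
#' @param motive a motive id (use \code{"das_general"} for the general
#'   characterization pseudo-motive).
#' @param includeGeneral should \code{motiveSets} append the general
#'   characterization as pseudo-motive \code{das_general}?
#' @name DiseaseMap-accessors
#' @export
setMethod("motiveIds", "DiseaseMap", function(x)
  vapply(x@motives, function(m) m$id, character(1)))

#' @rdname DiseaseMap-accessors
#' @export
setMethod("motiveLevels", "DiseaseMap", function(x) {
  lv <- vapply(x@motives, function(m) m$level, character(1))
  names(lv) <- motiveIds(x)
  lv
})

#' @rdname DiseaseMap-accessors
#' @export
setMethod("effectors", "DiseaseMap", function(x, motive) {
  if (motive == "das_general") return(x@generalEffectors)
  i <- match(motive, motiveIds(x))
  if (is.na(i)) stop("unknown motive id: ", motive)
  x@motives[[i]]$effectors
})

#' @rdname DiseaseMap-accessors
#' @export
setMethod("generalEffectors", "DiseaseMap", function(x) x@generalEffectors)

#' @rdname DiseaseMap-accessors
#' @export
setMethod("motiveSets", "DiseaseMap", function(x, includeGeneral = TRUE) {
  sets <- lapply(x@motives, function(m) m$effectors)
  names(sets) <- motiveIds(x)
  if (includeGeneral && length(x@generalEffectors))
    sets$das_general <- x@generalEffectors
  sets
})

setMethod("show", "DiseaseMap", function(object) {
  lv <- motiveLevels(object)
  cat("DiseaseMap with", length(object@motives), "motives",
      sprintf("(causative=%d, symptomatic=%d, both=%d)",
              sum(lv == "causative"), sum(lv == "symptomatic"),
              sum(lv == "both")), "\n")
  for (m in object@motives)
    cat(sprintf("  %-26s %-11s %3d effectors\n", m$id, m$level,
                length(m$effectors)))
  cat("  general characterization:", length(object@generalEffectors),
      "effectors\n")
})

#' Construct / load a CandidateList
#'
#' \code{loadCandidates} reads a TSV with header
#' \code{uniprot_id, protein_name, source_refs} (extra columns such as the
#' synthetic generator's \code{true_motive} are kept); accessions are
#' normalized and must be unique.
#'
#' @param entries data.frame of candidate records.
#' @param path TSV path.
#' @return a [CandidateList-class]
#' @examples
#' cand <- loadCandidates(system.file("extdata", "as_candidates_table1.tsv",
#'                                    package = "motiveRank"))
#' length(candidateIds(cand))
#' @export
CandidateList <- function(entries) {
  entries$uniprot_id <- normalizeAccession(entries$uniprot_id)
  if (anyDuplicated(entries$uniprot_id))
    stop("duplicate candidate accessions: ",
         paste(unique(entries$uniprot_id[duplicated(entries$uniprot_id)]),
               collapse = ", "))
  rownames(entries) <- NULL
  new("CandidateList", entries = entries)
}

#' @rdname CandidateList
#' @export
loadCandidates <- function(path) {
  e <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("uniprot_id", "protein_name", "source_refs")
  if (!all(need %in% names(e)))
    stop("candidate TSV '", path, "' must have header columns: ",
         paste(need, collapse = ", "))
  CandidateList(e)
}

#' Accessors for CandidateList
#' @param x a [CandidateList-class]
#' @name CandidateList-accessors
#' @export
setMethod("candidateIds", "CandidateList", function(x) x@entries$uniprot_id)

#' @rdname CandidateList-accessors
#' @export
setMethod("candidateTable", "CandidateList", function(x) x@entries)

setMethod("show", "CandidateList", function(object) {
  cat("CandidateList with", nrow(object@entries), "proteins\n")
})

#' Cross-check map, candidates and graph
#'
#' Reports (without raising) effectors and candidates absent from the graph,
#' motives whose entire effector set is missing, and duplicated candidate
#' accessions.  The report is empty iff the inputs are consistent.
#'
#' @param map a [DiseaseMap-class]
#' @param candidates a [CandidateList-class]
#' @param graph a [KnowledgeGraph-class]
#' @return list with \code{missing_from_graph}, \code{empty_motives},
#'   \code{duplicate_candidates}.
#' @export
validateInputs <- function(map, candidates, graph) {
  nodes <- nodeIds(graph)
  sets <- motiveSets(map, includeGeneral = TRUE)
  allIds <- unique(c(unlist(sets), candidateIds(candidates)))
  report <- list(
    missing_from_graph = sort(setdiff(allIds, nodes)),
    empty_motives = names(sets)[vapply(sets, function(s)
      length(intersect(s, nodes)) == 0, logical(1))],
    duplicate_candidates = unique(candidateIds(candidates)[
      duplicated(candidateIds(candidates))])
  )
  report
}
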