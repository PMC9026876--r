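#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("layerTable", function(x) standardGeneric("layerTable"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))

#' @rdname degreeSequence
#' @export
setGeneric("degreeSequence", function(x) standardGeneric("degreeSequence"))

#' @rdname DiseaseMap-accessors
#' @export
setGeneric("motiveIds", function(x) standardGeneric("motiveIds"))

#' @rdname DiseaseMap-accessors
#' @export
setGeneric("motiveLevels", function(x) standardGeneric("motiveLevels"))

#' @rdname DiseaseMap-accessors
#' @export
setGeneric("effectors", function(x, motive) standardGeneric("effectors"))

#' @rdname DiseaseMap-accessors
#' @export
setGeneric("generalEffectors", function(x) standardGeneric("generalEffectors"))

#' @rdname DiseaseMap-accessors
#' @export
setGeneric("motiveSets",
  function(x, includeGeneral = TRUE) standardGeneric("motiveSets"))

#' @rdname CandidateList-accessors
#' @export
setGeneric("candidateIds", function(x) standardGeneric("candidateIds"))

#' @rdname CandidateList-accessors
#' @export
setGeneric("candidateTable", function(x) standardGeneric("candidateTable"))

#' @rdname TruthTable-accessors
#' @export
setGeneric("truthPairs", function(x) standardGeneric("truthPairs"))

#' @rdname predictRaw
#' @export
setGeneric("predictRaw", function(object, features) standardGeneric("predictRaw"))

#' @rdname NullDistribution-accessors
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))
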