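#' Packaged aortic-stenosis fixtures
#'
#' Convenience loaders for the fixtures shipped under \code{inst/extdata},
#' transcribed from the printed tables of the degenerative aortic stenosis
#' characterization:
#' \describe{
#'   \item{asDiseaseMap()}{the 8-motive disease map with causal levels.  The
#'     full published curation comprises 168 effectors in an unprinted
#'     appendix; the packaged effector sets are the partial subset
#'     recoverable from the printed multi-motive table.}
#'   \item{asCandidates()}{the 126-protein candidate list with source
#'     citations.}
#'   \item{asTable5Scores()}{the sparse score matrix of the 22 candidates
#'     strongly related to at least three processes (strong-band rows only,
#'     as printed).}
#'   \item{asTable4Summary()}{the printed per-motive strong-relationship
#'     count table, for consistency checks.}
#' }
#'
#' @return see the individual descriptions.
#' @name as-fixtures
#' @examples
#' map <- asDiseaseMap()
#' motiveLevels(map)
NULL

.extdata <- function(f) system.file("extdata", f, package = "motiveRank",
                                    mustWork = TRUE)

#' @rdname as-fixtures
#' @export
asDiseaseMap <- function() loadDiseaseMap(.extdata("as_disease_map.yaml"))

#' @rdname as-fixtures
#' @export
asCandidates <- function() loadCandidates(.extdata("as_candidates_table1.tsv"))

#' @rdname as-fixtures
#' @export
asTable5Scores <- function() readScoreMatrix(.extdata("as_table5_scores.tsv"))

#' @rdname as-fixtures
#' @export
asTable4Summary <- function() {
  utils::read.delim(.extdata("as_table4_summary.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}
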