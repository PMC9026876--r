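#' Per-protein score profiles
#'
#' Collapses a [ScoreMatrix-class] to one row per candidate: best score and
#' its motive, number of motives scored, number of motives in a strong band
#' (the general characterization pseudo-motive counts as one process), an
#' all-non-effector flag, and the three-tier priority class.
#'
#' @param x a [ScoreMatrix-class]
#' @param includeGeneral should \code{das_general} count towards
#'   \code{strong_motive_count}?  (It always contributes to
#'   \code{best_score}.)
#' @return data.frame with columns \code{uniprot_id}, \code{n_scored},
#'   \code{best_score}, \code{best_motive}, \code{strong_motive_count},
#'   \code{all_noneffector}, \code{priority_class}.
#' @export
proteinProfiles <- function(x, includeGeneral = TRUE) {
  sc <- annScores(x)
  ef <- effectorFlags(x)
  countCols <- colnames(sc)
  if (!includeGeneral) countCols <- setdiff(countCols, "das_general")
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    s <- sc[i, ]
    scored <- which(!is.na(s))
    if (!length(scored)) {
      return(data.frame(uniprot_id = rownames(sc)[i], n_scored = 0L,
                        best_score = NA_real_, best_motive = NA_character_,
                        strong_motive_count = 0L, all_noneffector = TRUE,
                        priority_class = "low", stringsAsFactors = FALSE))
    }
    best <- scored[which.max(s[scored])]
    data.frame(
      uniprot_id = rownames(sc)[i],
      n_scored = length(scored),
      best_score = unname(s[best]),
      best_motive = colnames(sc)[best],
      strong_motive_count = sum(isStrong(s[colnames(sc) %in% countCols])),
      all_noneffector = !any(ef[i, scored]),
      priority_class = classifyProtein(s[scored]),
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(uniprot_id = character(0), n_scored = integer(0),
                      best_score = numeric(0), best_motive = character(0),
                      strong_motive_count = integer(0),
                      all_noneffector = logical(0),
                      priority_class = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-tier priority class of a protein
#'
#' \code{strong} if any scored motive falls in a strong band (very_high,
#' high or medium_high, i.e. score >= 63); \code{medium} if the best band is
#' medium (38-63); \code{low} otherwise.
#'
#' @param scores numeric vector of the protein's per-motive scores (NAs for
#'   unscored motives are ignored; at least one score required).
#' @return \code{"strong"}, \code{"medium"} or \code{"low"}.
#' @examples
#' classifyProtein(c(86.48, 74.62, 70.58, 65.44))
#' @export
classifyProtein <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("profile has no scored motive")
  best <- max(scores)
  if (best >= 63) "strong" else if (best >= 38) "medium" else "low"
}

#' Per-motive summary of strong relationships
#'
#' Cross-tabulates, for every motive, the candidates in each strong band
#' (very_high, high, medium_high) by curated effector status, plus the row
#' total -- the layout of the published categorization table.
#'
#' @param x a [ScoreMatrix-class]
#' @return data.frame with one row per motive and columns
#'   \code{very_high_effector}, \code{very_high_noneffector},
#'   \code{high_effector}, \code{high_noneffector},
#'   \code{medium_high_effector}, \code{medium_high_noneffector},
#'   \code{total}.
#' @export
summarizeByMotive <- function(x) {
  sc <- annScores(x)
  ef <- effectorFlags(x)
  cat <- scoreCategories(x)
  out <- data.frame(motive_id = colnames(sc), stringsAsFactors = FALSE)
  for (band in c("very_high", "high", "medium_high")) {
    for (e in c(TRUE, FALSE)) {
      col <- paste0(band, if (e) "_effector" else "_noneffector")
      out[[col]] <- vapply(seq_len(ncol(sc)), function(j)
        sum(!is.na(cat[, j]) & cat[, j] == band & ef[, j] == e), integer(1))
    }
  }
  out$total <- rowSums(out[, -1])
  out
}

#' Select candidates strongly related to several processes
#'
#' Returns the profiles of candidates whose strong-band motive count reaches
#' \code{minMotives} (the general characterization counts as one process when
#' \code{includeGeneral}), sorted by best score descending; ties broken by
#' accession ascending.
#'
#' @param x a [ScoreMatrix-class]
#' @param minMotives minimum number of strongly related processes (default 3).
#' @param includeGeneral count the general pseudo-motive as a process.
#' @return ranked data.frame of profiles (see [proteinProfiles()]).
#' @export
selectMultimotive <- function(x, minMotives = 3L, includeGeneral = TRUE) {
  stopifnot(minMotives >= 1)
  prof <- proteinProfiles(x, includeGeneral = includeGeneral)
  sel <- prof[prof$strong_motive_count >= minMotives, , drop = FALSE]
  sel <- sel[order(-sel$best_score, sel$uniprot_id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Flag candidates absent from the molecular characterization
#'
#' Subsets profiles to those whose every scored motive has a FALSE effector
#' flag -- candidates the curation did not describe, hence potentially novel.
#'
#' @param profiles data.frame of profiles from [proteinProfiles()] or
#'   [selectMultimotive()].
#' @return the novel subset, order preserved.
#' @export
flagNovel <- function(profiles) {
  profiles[profiles$all_noneffector, , drop = FALSE]
}
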