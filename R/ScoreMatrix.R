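#' Construct a ScoreMatrix
#'
#' @param score numeric matrix (candidates x motives) of 0-100 scores; NA for
#'   unscored cells.
#' @param effector logical matrix of curated effector flags, same dims.
#' @param p optional numeric matrix of empirical p-values.
#' @param rowData optional data.frame of per-candidate annotation
#'   (\code{protein_name}, \code{gene_name}, \code{qc_flags}, ...).
#' @param metadata optional list stored in the object metadata.
#' @return a [ScoreMatrix-class]
#' @export
ScoreMatrix <- function(score, effector, p = NULL, rowData = NULL,
                        metadata = list()) {
  if (is.null(p)) p <- matrix(NA_real_, nrow(score), ncol(score),
                              dimnames = dimnames(score))
  assays <- list(score = score, p = p, effector = effector)
  if (is.null(rowData))
    rowData <- S4Vectors::DataFrame(row.names = rownames(score))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rowData, metadata = metadata)
  new("ScoreMatrix", se)
}

#' Assay accessors for ScoreMatrix
#'
#' @param x a [ScoreMatrix-class]
#' @return the corresponding candidate x motive matrix; \code{scoreCategories}
#'   derives the band labels from the scores.
#' @name ScoreMatrix-accessors
#' @export
annScores <- function(x) SummarizedExperiment::assay(x, "score")

#' @rdname ScoreMatrix-accessors
#' @export
empiricalPValues <- function(x) SummarizedExperiment::assay(x, "p")

#' @rdname ScoreMatrix-accessors
#' @export
effectorFlags <- function(x) SummarizedExperiment::assay(x, "effector")

#' @rdname ScoreMatrix-accessors
#' @export
scoreCategories <- function(x) {
  sc <- annScores(x)
  matrix(scoreCategory(sc), nrow(sc), ncol(sc), dimnames = dimnames(sc))
}

setMethod("show", "ScoreMatrix", function(object) {
  sc <- annScores(object)
  cat("ScoreMatrix:", nrow(sc), "candidates x", ncol(sc), "motives (",
      sum(!is.na(sc)), "scored cells )\n")
  cat("  motives:", paste(colnames(sc), collapse = ", "), "\n")
})

# deterministic per-(motive, bin) seed derived from the master seed,
# kept within 32-bit integer range
.deriveSeed <- function(master, motiveIndex, bin) {
  as.integer((as.numeric(master) * 1009 + motiveIndex * 101 + (bin + 2)) %%
               2147483647)
}

#' Score every candidate against every motive
#'
#' For each (candidate, motive) pair -- motives include the general
#' characterization pseudo-motive -- computes proximity features, the raw
#' model score, an empirical p-value against a degree-matched permutation
#' null, and the calibrated 0-100 score, plus the curated effector flag.
#' One null distribution is built per (motive, degree bin) pair and cached
#' within the call; all sampling seeds derive deterministically from
#' \code{seed}, so identical inputs give identical output.
#'
#' @param graph a [KnowledgeGraph-class]
#' @param model a trained [RelationshipModel-class]
#' @param map a [DiseaseMap-class]
#' @param candidates a [CandidateList-class]
#' @param nNull null draws per distribution (default 1000).
#' @param restart walk restart probability (default 0.3).
#' @param includeGeneral score against the general pseudo-motive too.
#' @param seed master seed for the null sampling.
#' @return a [ScoreMatrix-class]; per-candidate QC flags (e.g. candidates
#'   absent from the graph) are in \code{rowData(x)$qc_flags}.
#' @export
scoreAll <- function(graph, model, map, candidates, nNull = 1000L,
                     restart = 0.3, includeGeneral = TRUE, seed = 1L) {
  sets <- motiveSets(map, includeGeneral = includeGeneral)
  ids <- candidateIds(candidates)
  nm <- names(sets)
  score <- p <- matrix(NA_real_, length(ids), length(nm),
                       dimnames = list(ids, nm))
  eff <- matrix(FALSE, length(ids), length(nm), dimnames = list(ids, nm))
  qc <- rep("", length(ids))
  if (length(ids)) {
    cap <- distanceCap(graph)
    deg <- degreeSequence(graph)
    candDeg <- ifelse(ids %in% names(deg), deg[ids], 0L)
    candBin <- degreeBin(candDeg)
    nodes <- nodeIds(graph)
    for (j in seq_along(nm)) {
      M <- intersect(normalizeAccession(sets[[j]]), nodes)
      rwr <- if (length(M)) rwrProximity(graph, M, restart = restart) else NULL
      X <- featureMatrix(graph, ids, sets[[j]], restart = restart,
                         rwr = rwr, cap = cap)
      qcj <- attr(X, "qc")
      qc <- ifelse(nzchar(qcj) & !nzchar(qc), qcj, qc)
      raw <- predictRaw(model, X)
      nulls <- list()
      for (i in seq_along(ids)) {
        key <- as.character(candBin[i])
        if (is.null(nulls[[key]]))
          nulls[[key]] <- permutationNull(
            graph, model, sets[[j]], candDeg[i], N = nNull,
            seed = .deriveSeed(seed, j, candBin[i]), restart = restart,
            rwr = rwr, cap = cap)
        p[i, j] <- empiricalP(raw[i], nulls[[key]])
      }
      score[, j] <- calibrateToAnn(p[, j])
      eff[, j] <- ids %in% normalizeAccession(sets[[j]])
    }
  }
  ct <- candidateTable(candidates)
  rd <- S4Vectors::DataFrame(
    protein_name = ct$protein_name,
    qc_flags = qc,
    row.names = ids)
  if (!is.null(ct$gene_name)) rd$gene_name <- ct$gene_name
  if (!is.null(ct$true_motive)) rd$true_motive <- ct$true_motive
  ScoreMatrix(score, eff, p = p, rowData = rd,
              metadata = list(seed = as.integer(seed), nNull = nNull,
                              restart = restart,
                              includeGeneral = includeGeneral))
}

#' Read / write a ScoreMatrix as long-format TSV
#'
#' Columns: \code{uniprot_id, motive_id, ann_score, p_empirical, category,
#' is_effector, qc_flags} plus optional \code{gene_name, protein_name}.
#' Only scored (non-NA) cells are written; reading a sparse file yields NA
#' for absent cells, which is how the printed strong-band-only fixture
#' matrices are represented.
#'
#' @param path TSV path.
#' @param motiveOrder optional explicit column ordering.
#' @return \code{readScoreMatrix}: a [ScoreMatrix-class];
#'   \code{writeScoreMatrix}: \code{path} invisibly.
#' @examples
#' sm <- readScoreMatrix(system.file("extdata", "as_table5_scores.tsv",
#'                                   package = "motiveRank"))
#' dim(annScores(sm))
#' @export
readScoreMatrix <- function(path, motiveOrder = NULL) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("uniprot_id", "motive_id", "ann_score", "is_effector")
  if (!all(need %in% names(d)))
    stop("score TSV '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  d$uniprot_id <- normalizeAccession(d$uniprot_id)
  prot <- unique(d$uniprot_id)
  mot <- if (is.null(motiveOrder)) unique(d$motive_id) else motiveOrder
  idx <- cbind(match(d$uniprot_id, prot), match(d$motive_id, mot))
  score <- p <- matrix(NA_real_, length(prot), length(mot),
                       dimnames = list(prot, mot))
  eff <- matrix(FALSE, length(prot), length(mot),
                dimnames = list(prot, mot))
  score[idx] <- d$ann_score
  if (!is.null(d$p_empirical)) p[idx] <- d$p_empirical
  eff[idx] <- as.logical(d$is_effector)
  rd <- S4Vectors::DataFrame(row.names = prot)
  for (col in c("gene_name", "protein_name", "qc_flags")) {
    if (!is.null(d[[col]]))
      rd[[col]] <- d[[col]][match(prot, d$uniprot_id)]
  }
  ScoreMatrix(score, eff, p = p, rowData = rd,
              metadata = list(source = path))
}

#' @rdname readScoreMatrix
#' @param x a [ScoreMatrix-class]
#' @export
writeScoreMatrix <- function(x, path) {
  sc <- annScores(x); pv <- empiricalPValues(x); ef <- effectorFlags(x)
  rd <- SummarizedExperiment::rowData(x)
  rows <- which(!is.na(sc), arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  d <- data.frame(
    uniprot_id = as.character(rownames(sc)[rows[, 1]]),
    motive_id = colnames(sc)[rows[, 2]],
    ann_score = sc[rows],
    p_empirical = pv[rows],
    category = scoreCategory(sc[rows]),
    is_effector = ef[rows],
    qc_flags = if (!is.null(rd$qc_flags)) rd$qc_flags[rows[, 1]]
               else rep("", nrow(rows)),
    stringsAsFactors = FALSE)
  if (!is.null(rd$gene_name)) d$gene_name <- rd$gene_name[rows[, 1]]
  if (!is.null(rd$protein_name)) d$protein_name <- rd$protein_name[rows[, 1]]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
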