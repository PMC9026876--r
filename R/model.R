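.sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass of the 5 -> hidden -> 1 logistic network on standardized X.
.forward <- function(w, X) {
  H <- .sigmoid(sweep(X %*% t(w$W1), 2, w$b1, "+"))
  list(H = H, yhat = as.numeric(.sigmoid(H %*% t(w$W2) + w$b2)))
}

# Full-batch gradient descent with momentum on the cross-entropy loss.
.fitNet <- function(X, y, hidden, lr, epochs, momentum, l2, seed) {
  set.seed(seed)
  p <- ncol(X)
  w <- list(W1 = matrix(stats::runif(hidden * p, -0.5, 0.5), hidden, p),
            b1 = stats::runif(hidden, -0.5, 0.5),
            W2 = matrix(stats::runif(hidden, -0.5, 0.5), 1, hidden),
            b2 = stats::runif(1, -0.5, 0.5))
  v <- lapply(w, function(m) m * 0)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    fw <- .forward(w, X)
    err <- fw$yhat - y                       # dL/dz_out for logistic + CE
    gW2 <- (t(err) %*% fw$H) / n + l2 * w$W2
    gb2 <- mean(err)
    dH <- (err %*% w$W2) * fw$H * (1 - fw$H)
    gW1 <- (t(dH) %*% X) / n + l2 * w$W1
    gb1 <- colMeans(dH)
    g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (k in names(w)) {
      v[[k]] <- momentum * v[[k]] - lr * g[[k]]
      w[[k]] <- w[[k]] + v[[k]]
    }
  }
  w
}

# Feature matrix for arbitrary (protein, motive) pairs, batched per motive.
.pairFeatures <- function(graph, pairs, map, restart = 0.3, cap = NULL) {
  if (is.null(cap)) cap <- distanceCap(graph)
  sets <- motiveSets(map, includeGeneral = TRUE)
  X <- matrix(NA_real_, nrow(pairs), length(.featureNames),
              dimnames = list(NULL, .featureNames))
  for (m in unique(pairs$motive_id)) {
    idx <- which(pairs$motive_id == m)
    X[idx, ] <- featureMatrix(graph, pairs$uniprot_id[idx], sets[[m]],
                              restart = restart, cap = cap)
  }
  X
}

#' Train the candidate-motive relationship predictor
#'
#' Fits a single-hidden-layer feed-forward neural network (logistic hidden
#' and output units) to the proximity features of the truth-table pairs,
#' by full-batch gradient descent with momentum under a fixed seed.  Features
#' are standardized with training-set mean and standard deviation (stored in
#' the model).  A stratified 75/25 split provides the held-out accuracy
#' reported in the metrics; the returned weights are then refit on all rows.
#'
#' @param table a [TruthTable-class] with both labels present.
#' @param graph the [KnowledgeGraph-class] the features are computed on.
#' @param map the [DiseaseMap-class] supplying motive effector sets.
#' @param hidden hidden units (default 8).
#' @param lr learning rate (default 0.5).
#' @param epochs training epochs (default 600).
#' @param momentum momentum coefficient (default 0.9).
#' @param l2 L2 weight penalty (default 1e-4).
#' @param restart walk restart probability used for features.
#' @param seed integer training seed.
#' @return a [RelationshipModel-class]; \code{metrics} holds
#'   \code{holdout_accuracy}, \code{train_accuracy} and the split sizes.
#' @export
trainRelationshipModel <- function(table, graph, map, hidden = 8L, lr = 0.5,
                                   epochs = 600L, momentum = 0.9, l2 = 1e-4,
                                   restart = 0.3, seed = 1L) {
  pairs <- truthPairs(table)
  if (length(unique(pairs$label)) < 2)
    stop("truth table must contain both 'related' and 'unrelated' pairs")
  seed <- as.integer(seed)
  X <- .pairFeatures(graph, pairs, map, restart = restart)
  y <- as.numeric(pairs$label == "related")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  # stratified 75/25 holdout for the training report
  set.seed(seed)
  test <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1L, floor(length(ix) * 0.25)))))
  train <- setdiff(seq_along(y), test)
  wHold <- .fitNet(Xs[train, , drop = FALSE], y[train], hidden, lr, epochs,
                   momentum, l2, seed)
  accHold <- mean((.forward(wHold, Xs[test, , drop = FALSE])$yhat >= 0.5) ==
                    y[test])
  w <- .fitNet(Xs, y, hidden, lr, epochs, momentum, l2, seed)
  accTrain <- mean((.forward(w, Xs)$yhat >= 0.5) == y)
  new("RelationshipModel",
      weights = w, center = ctr, scale = scl, featureNames = .featureNames,
      hyper = list(hidden = hidden, lr = lr, epochs = epochs,
                   momentum = momentum, l2 = l2, restart = restart),
      seed = seed,
      metrics = list(holdout_accuracy = accHold, train_accuracy = accTrain,
                     n_train = length(train), n_test = length(test)))
}

#' Raw relationship score of feature vectors
#'
#' Deterministic forward pass of the trained network; output in [0, 1].
#'
#' @param object a [RelationshipModel-class]
#' @param features numeric feature matrix (or single named vector) with the
#'   model's feature columns.
#' @return numeric vector of raw scores in [0, 1].
#' @name predictRaw
#' @export
setMethod("predictRaw", "RelationshipModel", function(object, features) {
  if (is.null(dim(features))) features <- matrix(features, 1,
    dimnames = list(NULL, names(features)))
  features <- features[, object@featureNames, drop = FALSE]
  Xs <- scale(features, center = object@center, scale = object@scale)
  .forward(object@weights, Xs)$yhat
})

setMethod("show", "RelationshipModel", function(object) {
  cat(sprintf(
    "RelationshipModel: %d features -> %d hidden -> 1, seed %d\n",
    length(object@featureNames), object@hyper$hidden, object@seed))
  cat(sprintf("  held-out accuracy: %.3f (n=%d)\n",
              object@metrics$holdout_accuracy, object@metrics$n_test))
})

#' Serialize / restore a trained model as JSON
#'
#' The JSON document records weights, standardization parameters, feature
#' ordering, hyperparameters and seed; reading it back restores a model with
#' identical predictions.
#'
#' @param model a [RelationshipModel-class]
#' @param path JSON file path.
#' @return \code{writeRelationshipModel}: \code{path} invisibly;
#'   \code{readRelationshipModel}: the restored model.
#' @export
writeRelationshipModel <- function(model, path) {
  doc <- list(
    feature_names = model@featureNames,
    center = as.list(stats::setNames(model@center, model@featureNames)),
    scale = as.list(stats::setNames(model@scale, model@featureNames)),
    weights = list(W1 = as.numeric(t(model@weights$W1)),  # row-major flat
                   b1 = as.numeric(model@weights$b1),
                   W2 = as.numeric(model@weights$W2),
                   b2 = as.numeric(model@weights$b2)),
    hyper = model@hyper, seed = model@seed, metrics = model@metrics)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeRelationshipModel
#' @export
readRelationshipModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fn <- doc$feature_names
  h <- doc$hyper$hidden
  new("RelationshipModel",
      weights = list(W1 = matrix(as.numeric(doc$weights$W1), nrow = h,
                                 byrow = TRUE),
                     b1 = as.numeric(doc$weights$b1),
                     W2 = matrix(as.numeric(doc$weights$W2), nrow = 1),
                     b2 = as.numeric(doc$weights$b2)),
      center = unlist(doc$center[fn]), scale = unlist(doc$scale[fn]),
      featureNames = fn, hyper = as.list(doc$hyper),
      seed = as.integer(doc$seed), metrics = as.list(doc$metrics))
}
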