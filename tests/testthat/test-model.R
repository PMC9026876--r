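# A study in which relatedness is linearly separable in the proximity
# features: planted candidates sit at hop 1 of dense modules, unrelated
# background nodes at hop >= 2.
separableStudy <- function(seed) simulateStudy(nNodes = 300, kMotives = 3,
                                               sizeRange = c(6, 10),
                                               seed = seed)

test_that("the network separates proximal from distal pairs like a
           logistic-regression oracle", {
  st <- separableStudy(101)
  model <- trainRelationshipModel(st@truth, st@graph, st@map, seed = 7)
  expect_gte(model@metrics$holdout_accuracy, 0.95)

  # independent oracle: logistic regression on the same features must also
  # separate them -- confirming the signal is in the features, not the fit
  pairs <- truthPairs(st@truth)
  X <- motiveRank:::.pairFeatures(st@graph, pairs, st@map)
  y <- as.numeric(pairs$label == "related")
  glmFit <- suppressWarnings(
    stats::glm(y ~ ., data = data.frame(X, y = y), family = "binomial"))
  glmAcc <- mean((stats::predict(glmFit, type = "response") >= 0.5) == y)
  expect_gte(glmAcc, 0.95)
  netAcc <- mean((predictRaw(model, X) >= 0.5) == y)
  expect_gte(netAcc, 0.95)
})

test_that("training is deterministic and outputs stay in [0, 1]", {
  st <- separableStudy(102)
  m1 <- trainRelationshipModel(st@truth, st@graph, st@map, seed = 9)
  m2 <- trainRelationshipModel(st@truth, st@graph, st@map, seed = 9)
  expect_identical(m1@weights, m2@weights)

  set.seed(1)
  probe <- matrix(c(runif(100, 0, 6), runif(100, 0, 6), runif(100),
                    runif(100), runif(100, 0, 4)),
                  ncol = 5,
                  dimnames = list(NULL, m1@featureNames))
  probe[, "d_min"] <- pmin(probe[, "d_min"], probe[, "d_mean"])
  raw1 <- predictRaw(m1, probe)
  expect_true(all(raw1 >= 0 & raw1 <= 1))
  expect_identical(raw1, predictRaw(m2, probe))
})

test_that("a single-class truth table cannot be trained on", {
  st <- separableStudy(103)
  pairs <- truthPairs(st@truth)
  oneClass <- new("TruthTable",
                  pairs = pairs[pairs$label == "related", ], seed = 1L)
  expect_error(trainRelationshipModel(oneClass, st@graph, st@map),
               "both")
})

test_that("model state round-trips through the JSON serialization", {
  st <- separableStudy(104)
  model <- trainRelationshipModel(st@truth, st@graph, st@map, seed = 3)
  tf <- tempfile(fileext = ".json")
  writeRelationshipModel(model, tf)
  back <- readRelationshipModel(tf)
  set.seed(2)
  probe <- matrix(runif(50, 0, 3), 10, 5,
                  dimnames = list(NULL, model@featureNames))
  expect_equal(predictRaw(back, probe), predictRaw(model, probe),
               tolerance = 1e-12)
})

test_that("raw scores are invariant to node relabeling", {
  st <- simulateStudy(nNodes = 120, kMotives = 2, sizeRange = c(5, 7),
                      nRelatedPerMotive = 2, nUnrelated = 5, seed = 55)
  model <- trainRelationshipModel(st@truth, st@graph, st@map, seed = 4)
  # rename every node by a fixed permutation tag; features are label-free
  et <- layerTable(st@graph)
  tag <- function(x) paste0("X", x)
  kg2 <- KnowledgeGraph(data.frame(source = tag(et$source),
                                   target = tag(et$target),
                                   layer = et$layer,
                                   provenance = et$provenance),
                        nodes = tag(nodeIds(st@graph)))
  sets <- motiveSets(st@map, includeGeneral = FALSE)
  M <- sets[[1]]
  cands <- setdiff(nodeIds(st@graph), M)[1:10]
  X1 <- featureMatrix(st@graph, cands, M)
  X2 <- featureMatrix(kg2, tag(cands), tag(M))
  expect_equal(unname(predictRaw(model, X2)), unname(predictRaw(model, X1)),
               tolerance = 1e-10)
})
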