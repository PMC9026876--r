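test_that("three-tier classification follows the band definitions", {
  # endoplasmin's printed profile: best score 86.48 (inflammation) -> strong
  sm <- asTable5Scores()
  endo <- annScores(sm)["P14625", ]
  expect_equal(max(endo, na.rm = TRUE), 86.48)
  expect_equal(classifyProtein(endo), "strong")
  expect_equal(classifyProtein(c(50.0, 40)), "medium")
  expect_equal(classifyProtein(c(37.9, 12, NA)), "low")
  expect_error(classifyProtein(c(NA_real_, NA_real_)), "no scored")
})

test_that("per-motive summaries cross-tab strong bands by effector status", {
  # the printed summary satisfies total = sum of the six cells on every row
  printed <- asTable4Summary()
  cells <- printed[, c("very_high_effector", "very_high_noneffector",
                       "high_effector", "high_noneffector",
                       "medium_high_effector", "medium_high_noneffector")]
  expect_equal(unname(rowSums(cells)), printed$total)
  das <- printed[printed$motive_id == "das_general", ]
  expect_equal(das$high_effector + das$medium_high_effector +
                 das$medium_high_noneffector, 35)
  expect_equal(das$total, 35)

  # computed summaries obey the same identity on the fixture matrix
  sm <- asTable5Scores()
  s <- summarizeByMotive(sm)
  cols <- setdiff(names(s), c("motive_id", "total"))
  expect_equal(unname(rowSums(s[, cols])), s$total)

  # hand-built matrix: one strong effector in one motive
  one <- ScoreMatrix(
    score = matrix(c(85, 20), 1, 2,
                   dimnames = list("P1", c("m1", "m2"))),
    effector = matrix(c(TRUE, FALSE), 1, 2,
                      dimnames = list("P1", c("m1", "m2"))))
  s1 <- summarizeByMotive(one)
  expect_equal(s1$total, c(1, 0))
  expect_equal(s1$high_effector, c(1, 0))

  empty <- ScoreMatrix(score = matrix(NA_real_, 0, 2,
                                      dimnames = list(NULL, c("a", "b"))),
                       effector = matrix(FALSE, 0, 2,
                                         dimnames = list(NULL, c("a", "b"))))
  expect_true(all(summarizeByMotive(empty)$total == 0))
})

test_that("multi-motive selection reproduces the printed candidate list", {
  sm <- asTable5Scores()
  sel <- selectMultimotive(sm, minMotives = 3, includeGeneral = TRUE)
  expect_equal(nrow(sel), 22)
  expect_equal(sel$uniprot_id[1], "P08123")
  expect_equal(sel$best_score[1], 92.52)
  # ranked by best score descending
  expect_true(all(diff(sel$best_score) <= 0))
  # every printed profile is strong (minimum printed score is 63.40)
  expect_true(all(sel$priority_class == "strong"))
  expect_gte(min(annScores(sm), na.rm = TRUE), 63.40)
  # transthyretin qualifies only through the general characterization
  ttr <- proteinProfiles(sm, includeGeneral = FALSE)
  expect_lt(ttr$strong_motive_count[ttr$uniprot_id == "P02766"], 3)

  # degenerate cases
  one <- ScoreMatrix(
    score = matrix(80, 1, 1, dimnames = list("P1", "m1")),
    effector = matrix(FALSE, 1, 1, dimnames = list("P1", "m1")))
  expect_equal(nrow(selectMultimotive(one, minMotives = 1)), 1)
  empty <- ScoreMatrix(score = matrix(NA_real_, 0, 1,
                                      dimnames = list(NULL, "m1")),
                       effector = matrix(FALSE, 0, 1,
                                         dimnames = list(NULL, "m1")))
  expect_equal(nrow(selectMultimotive(empty)), 0)
})

test_that("selection order is total and reruns are identical", {
  sm <- asTable5Scores()
  expect_identical(selectMultimotive(sm), selectMultimotive(sm))
  # ties break by accession ascending
  tied <- ScoreMatrix(
    score = matrix(c(70, 70), 2, 1, dimnames = list(c("P2", "P1"), "m1")),
    effector = matrix(FALSE, 2, 1, dimnames = list(c("P2", "P1"), "m1")))
  expect_equal(selectMultimotive(tied, minMotives = 1)$uniprot_id,
               c("P1", "P2"))
})

test_that("novel flagging isolates candidates outside the characterization", {
  sm <- asTable5Scores()
  nov <- flagNovel(selectMultimotive(sm))
  expect_equal(nrow(nov), 8)
  expect_true(all(c("P14625", "P07996") %in% nov$uniprot_id))
  expect_setequal(nov$uniprot_id,
                  c("P14625", "P02766", "P10909", "P07996", "P02768",
                    "P07585", "Q92743", "P01023"))
  # an all-effector input yields nothing
  allEff <- ScoreMatrix(
    score = matrix(90, 1, 1, dimnames = list("P1", "m1")),
    effector = matrix(TRUE, 1, 1, dimnames = list("P1", "m1")))
  expect_equal(nrow(flagNovel(proteinProfiles(allEff))), 0)
})

test_that("strong classification coincides with a positive strong count", {
  sm <- asTable5Scores()
  prof <- proteinProfiles(sm)
  expect_equal(prof$priority_class == "strong", prof$strong_motive_count >= 1)
})
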