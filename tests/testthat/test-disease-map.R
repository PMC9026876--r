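test_that("the packaged disease map matches the published characterization", {
  map <- asDiseaseMap()
  expect_length(motiveIds(map), 8)
  lv <- motiveLevels(map)
  expect_equal(unname(lv["calcification"]), "both")
  expect_equal(sum(lv == "causative"), 5)
  expect_equal(sum(lv == "symptomatic"), 2)
  expect_setequal(names(lv)[lv == "causative"],
                  c("lipoprotein_accumulation", "inflammation",
                    "oxidative_stress", "endothelial_dysfunction",
                    "raa_system"))
  expect_setequal(names(lv)[lv == "symptomatic"],
                  c("hypertrophy", "myocardial_fibrosis"))
  expect_true(length(generalEffectors(map)) > 0)
  # the general characterization joins the motive sets as a pseudo-motive
  sets <- motiveSets(map)
  expect_equal(names(sets)[length(sets)], "das_general")
  expect_length(motiveSets(map, includeGeneral = FALSE), 8)
})

test_that("disease-map schema violations are rejected", {
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(motives = list(
    list(id = "m1", name = "M1", level = "causal",
         effectors = list("P00001"))), general_effectors = list()), tf)
  expect_error(loadDiseaseMap(tf), "causal")
  yaml::write_yaml(list(motives = list(
    list(id = "m1", name = "M1", level = "causative",
         effectors = list()))), tf)
  expect_error(loadDiseaseMap(tf), "m1")
})

test_that("disease maps round-trip through serialization", {
  map <- asDiseaseMap()
  tf <- tempfile(fileext = ".yaml")
  writeDiseaseMap(map, tf)
  again <- loadDiseaseMap(tf)
  expect_equal(again@motives, map@motives)
  expect_equal(generalEffectors(again), generalEffectors(map))
})

test_that("the packaged candidate list carries the 126 published proteins", {
  cand <- asCandidates()
  ids <- candidateIds(cand)
  expect_length(ids, 126)
  expect_false(anyDuplicated(ids) > 0)
  tab <- candidateTable(cand)
  expect_equal(tab$protein_name[tab$uniprot_id == "P14625"], "Endoplasmin")
  expect_equal(tab$protein_name[tab$uniprot_id == "P07996"],
               "Thrombospondin-1")
})

test_that("candidate loader normalizes, deduplicates, handles empty files", {
  tf <- tempfile(fileext = ".tsv")
  writeLines("uniprot_id\tprotein_name\tsource_refs", tf)
  expect_length(candidateIds(loadCandidates(tf)), 0)
  writeLines(c("uniprot_id\tprotein_name\tsource_refs",
               "P07996-2\tThbs1\tx", "p07996\tThbs1\ty"), tf)
  expect_error(loadCandidates(tf), "P07996")
  writeLines(c("uniprot_id\tprotein_name", "P07996\tThbs1"), tf)
  expect_error(loadCandidates(tf), "source_refs")
})

test_that("validation reports missing nodes and empty motives, never raises", {
  kg <- pathGraph(3)  # nodes A, B, C
  map <- DiseaseMap(list(
    list(id = "m1", name = "M1", level = "causative", effectors = c("A")),
    list(id = "m2", name = "M2", level = "symptomatic", effectors = c("X"))))
  cand <- CandidateList(data.frame(uniprot_id = c("B", "XXXXX"),
                                   protein_name = "", source_refs = ""))
  rep <- validateInputs(map, cand, kg)
  expect_setequal(rep$missing_from_graph, c("X", "XXXXX"))
  expect_equal(rep$empty_motives, "m2")
  expect_length(rep$duplicate_candidates, 0)

  allGood <- validateInputs(
    DiseaseMap(list(list(id = "m1", name = "M1", level = "both",
                         effectors = "A"))),
    CandidateList(data.frame(uniprot_id = "C", protein_name = "",
                             source_refs = "")), kg)
  expect_length(allGood$missing_from_graph, 0)
  expect_length(allGood$empty_motives, 0)
})
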