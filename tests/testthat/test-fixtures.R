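# The fixture corpus is itself tested code: coverage guarantees and
# self-validation against the pipeline.

test_that("the corpus covers every discard reason at least twice", {
  corpus <- fixtureCorpus()
  expect_gte(nrow(corpus), 40)
  expect_true(all(corpus$expected %in% c("pass", REASON_TAGS)))
  cover <- table(corpus$expected[corpus$expected != "pass"])
  for (tag in REASON_TAGS) {
    expect_gte(unname(cover[tag]), 2)
  }
  # every tautomer/mesomer family contributes at least one pair
  expect_gte(sum(corpus$family == "tautomer" & corpus$expected == "duplicate"), 4)
  expect_gte(sum(corpus$family %in% c("mesomer", "valence") &
                   corpus$expected == "duplicate"), 2)
  expect_false(anyDuplicated(corpus$name) > 0)
})

test_that("the corpus is self-validating against the pipeline", {
  rep <- corpus_report()
  corpus <- fixtureCorpus()
  got <- merge(corpus, rep$table, by.x = "name", by.y = "ID")
  got$observed <- ifelse(got$status == "pass", "pass", got$reason)
  expect_identical(nrow(got), nrow(corpus))
  mismatch <- got[got$expected != got$observed, c("name", "expected", "observed")]
  expect_identical(nrow(mismatch), 0L, info = paste(capture.output(mismatch),
                                                    collapse = "\n"))
  # frozen canonical outputs for passing cases
  smap <- vapply(rep$results, qsarSmiles, "")
  names(smap) <- vapply(rep$results, identifier, "")
  exp <- corpus[!is.na(corpus$expected_smiles), ]
  expect_identical(unname(smap[exp$name]), exp$expected_smiles)
})

test_that("corpus generation is deterministic and exportable", {
  expect_identical(fixtureCorpus(), fixtureCorpus())
  d <- withr::local_tempdir()
  paths <- writeFixtureFiles(d)
  expect_true(all(file.exists(paths)))
  smi <- readLines(paths[["smi"]])
  expect_identical(length(smi), sum(nzchar(fixtureCorpus()$smiles)))
  back <- read.csv(paths[["expected"]], stringsAsFactors = FALSE)
  expect_identical(back$name, fixtureCorpus()$name)
})

test_that("ruleOrderProbe exhibits genuine order dependence", {
  probe <- ruleOrderProbe()
  expect_false(identical(probe$result_AB, probe$result_BA))
  # single-rule application is trivially order-free
  lib <- defaultRuleLibrary()
  k <- match(probe$ruleA, lib@rules$rule_id)
  rule <- c(as.list(lib@rules[k, ]), list(parsed = lib@parsed[[k]]))
  g <- smi2graph(probe$structure)
  once <- applyRule(g, rule)$graph
  expect_identical(canonicalSmiles(applyRule(once, rule)$graph),
                   canonicalSmiles(once))
})
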