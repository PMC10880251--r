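# Input readers and the five-output-file contract.

test_that("detectFormat decides by extension, then by content sniffing", {
  d <- withr::local_tempdir()
  for (ext in c("smi", "csv", "mol", "sdf")) {
    f <- file.path(d, paste0("input.", ext))
    writeLines("x", f)
    expect_identical(detectFormat(f), ext)
  }
  noext <- file.path(d, "structures")
  writeLines(strsplit(TWO_RECORD_SDF, "\n")[[1]], noext)
  expect_identical(detectFormat(noext), "sdf")
  molfile <- file.path(d, "single")
  writeLines(strsplit(MARKUSH_MOL, "\n")[[1]], molfile)
  expect_identical(detectFormat(molfile), "mol")
  mystery <- file.path(d, "mystery")
  writeLines("who knows", mystery)
  expect_identical(detectFormat(mystery), "unknown")
  expect_error(detectFormat(file.path(d, "absent.smi")), "absent")
})

test_that("readStructures parses .smi files and keeps failures", {
  d <- withr::local_tempdir()
  f <- file.path(d, "in.smi")
  writeLines(c("CCO eth1", "c1ccccc1 bz1", "C1CC broken"), f)
  recs <- readStructures(f)
  expect_length(recs, 3)
  expect_identical(vapply(recs, identifier, ""), c("eth1", "bz1", "broken"))
  expect_identical(vapply(recs, function(r) r@parseStatus, ""),
                   c("ok", "ok", "failed"))
  expect_match(recs[[3]]@parseMessages, "ring closure")
})

test_that("readStructures handles CSV input with blank cells and id collisions", {
  d <- withr::local_tempdir()
  f <- file.path(d, "in.csv")
  write.csv(data.frame(ID = c("a", "a", "c"), SMILES = c("CCO", "", "CCN")),
            f, row.names = FALSE)
  recs <- readStructures(f, smilesColumn = "SMILES", idColumn = "ID")
  expect_length(recs, 3)
  expect_identical(vapply(recs, identifier, ""), c("a", "a_2", "c"))
  expect_identical(recs[[2]]@parseStatus, "failed")
  expect_error(readStructures(f, smilesColumn = "Smiles"), "available columns")
  # empty file: empty list, not an error
  empty <- file.path(d, "empty.smi")
  file.create(empty)
  expect_length(readStructures(empty), 0)
})

test_that("readStructures extracts SDF records, titles and data fields", {
  d <- withr::local_tempdir()
  f <- file.path(d, "in.sdf")
  writeLines(strsplit(TWO_RECORD_SDF, "\n")[[1]], f)
  recs <- readStructures(f)
  expect_length(recs, 2)
  expect_identical(vapply(recs, identifier, ""), c("ethanol", "benzene"))
  expect_identical(recs[[1]]@meta$CASRN, "64-17-5")
  expect_true(all(vapply(recs, function(r) r@parseStatus, "") == "ok"))
})

test_that("SDF writer round-trips graphs (InChI as isomorphism oracle)", {
  smis <- c("CCO", "c1ccccc1", "CC(=O)O", "C[N+](C)(C)C", "O=C1CCCCC1")
  results <- lapply(seq_along(smis), function(k) {
    g <- sanitizeCoordinates(smi2graph(smis[k]))
    new("QsarReadyResult", identifier = paste0("m", k), graph = g,
        smiles = canonicalSmiles(g), inchi = computeInchi(g)$inchi,
        inchikey = computeInchi(g)$inchikey, saltSolvent = character(0),
        saltId = character(0), originalSmiles = smis[k],
        log = character(0), stereoPayload = list())
  })
  f <- withr::local_tempfile(fileext = ".sdf")
  writeSdf(results, f)
  txt <- readLines(f)
  expect_identical(sum(txt == "M  END"), 5L)
  expect_identical(sum(txt == "$$$$"), 5L)
  back <- readStructures(f)
  expect_length(back, 5)
  for (k in seq_along(back)) {
    expect_identical(computeInchi(back[[k]]@graph)$inchi, results[[k]]@inchi)
  }
  # empty result list: empty file is still created
  f2 <- withr::local_tempfile(fileext = ".sdf")
  writeSdf(list(), f2)
  expect_true(file.exists(f2))
  expect_length(readLines(f2), 0)
})

test_that("SMILES writer emits one tab-separated line per result, in order", {
  g <- smi2graph("c1ccccc1")
  mk <- function(id) new("QsarReadyResult", identifier = id, graph = g,
    smiles = "c1ccccc1", inchi = computeInchi(g)$inchi,
    inchikey = computeInchi(g)$inchikey, saltSolvent = character(0),
    saltId = character(0), originalSmiles = "c1ccccc1", log = character(0),
    stereoPayload = list())
  f <- withr::local_tempfile(fileext = ".smi")
  writeSmiles(list(mk("bz1"), mk("bz2")), f)
  expect_identical(readLines(f), c("c1ccccc1\tbz1", "c1ccccc1\tbz2"))
  writeSmiles(list(), f)
  expect_length(readLines(f), 0)
})

test_that("summary, discarded and salt-map CSVs honour the field contract", {
  rep <- corpus_report()
  s <- read.csv(rep$files[["summary"]], stringsAsFactors = FALSE)
  expect_identical(names(s), c("ID", "Original_SMILES", "Canonical_QSARr",
                               "InChI", "InChIKey", "Salt_Solvent",
                               "Salt_Solvent_ID"))
  na_row <- s[s$ID == "sodium-acetate", ]
  expect_identical(na_row$Canonical_QSARr, "CC(=O)O")
  expect_identical(na_row$Salt_Solvent, "[Na+]")
  expect_identical(na_row$Salt_Solvent_ID, "SS-0001")
  expect_identical(s[s$ID == "toluene", ]$Salt_Solvent, "")

  d <- read.csv(rep$files[["discarded"]], stringsAsFactors = FALSE)
  expect_identical(names(d), c("ID", "Original_Structure", "Reason"))
  expect_identical(d[d$ID == "ethanol-ethylamine", ]$Reason, "mixture")
  expect_identical(d[d$ID == "sodium-chloride", ]$Reason, "inorganic")
  expect_identical(d[d$ID == "unclosed-ring", ]$Reason, "failed_parsing")

  sm <- read.csv(rep$files[["salts"]], stringsAsFactors = FALSE)
  expect_identical(names(sm), c("ID", "Salt_Solvent_SMILES", "Salt_Solvent_ID"))
  hyd <- sm[sm$ID == "ethanol-dihydrate", ]
  expect_identical(hyd$Salt_Solvent_SMILES, c("O", "O"))
  # records without stripped fragments never appear
  expect_false("toluene" %in% sm$ID)
})

test_that("header rows are written even for an empty run", {
  d <- withr::local_tempdir()
  input <- file.path(d, "none.smi")
  file.create(input)
  rep <- runPipeline(stdConfig(input = input, outputDir = d))
  s <- read.csv(rep$files[["summary"]], stringsAsFactors = FALSE)
  expect_identical(nrow(s), 0L)
  expect_identical(names(s)[1:2], c("ID", "Original_SMILES"))
  expect_length(readLines(rep$files[["sdf"]]), 0)
  expect_identical(unname(rep$counts), c(0L, 0L, 0L))
})
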