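# The reaction-format rule engine and the non-library standardization stages.

test_that("loadRuleFile parses the shipped library and enforces invariants", {
  lib <- defaultRuleLibrary()
  expect_gte(ruleCount(lib), 100)
  expect_gt(ruleCount(lib, enabledOnly = TRUE), 0)
  expect_lt(ruleCount(lib, enabledOnly = TRUE), ruleCount(lib))
  expect_true(all(lib@rules$family %in%
                    c("mesomer", "tautomer", "neutralization", "other")))

  d <- withr::local_tempdir()
  dup <- file.path(d, "dup.tsv")
  writeLines(c("A\t1\t1\ttautomer\t[OX2H:1][C:2]=[C:3]>>[O:1]=[C:2][C:3]\ta",
               "B\t1\t1\ttautomer\t[SX2H:1][C:2]=[C:3]>>[S:1]=[C:2][C:3]\tb"),
             dup)
  expect_error(loadRuleFile(dup), "order_index")

  bad <- file.path(d, "bad.tsv")
  writeLines("A\t1\t1\ttautomer\t[OX2H:1][C:2]=[C:3]\ta", bad)
  expect_error(loadRuleFile(bad), "A")

  empty <- file.path(d, "empty.tsv")
  writeLines("# nothing here", empty)
  expect_identical(ruleCount(loadRuleFile(empty)), 0L)
})

test_that("applyRule transforms all matches to a fixed point", {
  keto <- "[OX2H:1][C:2]=[C:3]>>[O:1]=[C:2][C:3]"
  r <- applyRule(smi2graph("CC(O)=C"), keto)
  expect_identical(canonicalSmiles(r$graph), "CC(=O)C")
  expect_identical(r$applications, 1L)

  # no-op on non-matching input
  r <- applyRule(smi2graph("c1ccccc1"), keto)
  expect_identical(canonicalSmiles(r$graph), "c1ccccc1")
  expect_identical(r$applications, 0L)

  # 1,3-cyclohexanedione dienol: fixed point within two passes
  r <- applyRule(smi2graph("OC1=CC(O)=CCC1"), keto)
  expect_lte(r$applications, 2L)
  r2 <- applyRule(r$graph, keto)
  expect_identical(r2$applications, 0L)
  expect_identical(canonicalSmiles(r2$graph), canonicalSmiles(r$graph))
})

test_that("rule applications preserve heavy atoms and net charge", {
  lib <- defaultRuleLibrary()
  probes <- c("CC(O)=C", "C[N-][N+]#N", "Oc1ccccn1", "OC#C", "NC=C",
              "C[S+](C)[O-]", "CC(C)N=O", "OC(=CC=C)")
  for (s in probes) {
    g <- smi2graph(s)
    out <- standardizeMesomersTautomers(g, lib)$graph
    expect_identical(heavy_multiset(out), heavy_multiset(g), info = s)
    expect_identical(netCharge(out), netCharge(g), info = s)
  }
})

test_that("tautomer and mesomer pairs collapse to one canonical form", {
  lib <- defaultRuleLibrary()
  std <- function(s) canonicalSmiles(
    standardizeMesomersTautomers(smi2graph(s), lib)$graph)
  pairs <- list(
    azide = c("CN=[N+]=[N-]", "C[N-][N+]#N"),
    ketoenol = c("CC(C)=O", "CC(O)=C"),
    enamine = c("CC=N", "NC=C"),
    pyridone = c("O=C1C=CC=CN1", "Oc1ccccn1"),
    ynol = c("C=C=O", "OC#C"),
    nitroso = c("CC(C)=NO", "CC(C)N=O"))
  for (nm in names(pairs)) {
    expect_identical(std(pairs[[nm]][1]), std(pairs[[nm]][2]), info = nm)
  }
  # already-canonical input is untouched (idempotence per structure)
  for (s in c("CC(=O)C", "O=c1cccc[nH]1", "[N-]=[N+]=NC", "CCO")) {
    expect_identical(std(s), canonicalSmiles(smi2graph(s)), info = s)
  }
})

test_that("disabling a rule changes the outcome", {
  lib <- defaultRuleLibrary()
  off <- setRuleEnabled(lib, grep("^TAU-ENOL", lib@rules$rule_id, value = TRUE),
                        FALSE)
  g <- smi2graph("CC(O)=C")
  with_rule <- canonicalSmiles(standardizeMesomersTautomers(g, lib)$graph)
  without <- canonicalSmiles(standardizeMesomersTautomers(g, off)$graph)
  expect_identical(with_rule, "CC(=O)C")
  expect_false(identical(without, with_rule))
  expect_error(setRuleEnabled(lib, "NO-SUCH-RULE"), "unknown rule")
})

test_that("neutralize removes removable charges and keeps permanent ones", {
  out <- function(s) canonicalSmiles(neutralize(smi2graph(s))$graph)
  expect_identical(out("C[NH3+]"), "CN")
  expect_identical(out("CC(=O)[O-]"), "CC(=O)O")
  expect_identical(out("[NH3+]CC([O-])=O"), "NCC(=O)O")      # paired transfer
  expect_identical(out("C[N+](C)(C)C"), "C[N+](C)(C)C")      # quaternary N
  expect_identical(out("C[N+](=O)[O-]"), "[O-][N+](=O)C")    # nitro protected
  # net |charge| never increases
  for (s in c("C[NH3+]", "CC(=O)[O-]", "[NH3+]CC([O-])=O", "C[N+](C)(C)C")) {
    g <- smi2graph(s)
    expect_lte(abs(netCharge(neutralize(g)$graph)), abs(netCharge(g)))
  }
})

test_that("flattenStereo strips descriptors and reports them in the payload", {
  fs <- flattenStereo(smi2graph("C[C@H](N)C(=O)O"))
  expect_identical(fs$payload$tetrahedral, 1L)
  expect_identical(fs$payload$doubleBond, 0L)
  expect_false(grepl("@", canonicalSmiles(fs$graph)))

  fb <- flattenStereo(smi2graph("C/C=C/C"))
  expect_identical(fb$payload$doubleBond, 1L)
  expect_identical(canonicalSmiles(fb$graph), "CC=CC")

  fa <- flattenStereo(smi2graph("CCO"))
  expect_identical(fa$payload$tetrahedral + fa$payload$doubleBond, 0L)
})

test_that("virtualizeHydrogens folds explicit H but keeps isotopic hydrogens", {
  g <- parseStructure("[H]OC([H])([H])[H]", "smi")$graph   # folded at parse
  expect_identical(sum(g@atoms$elem == "H"), 0L)
  expect_identical(sum(g@atoms$hcount), 4L)
  expect_identical(canonicalSmiles(g), "CO")

  gd <- smi2graph("[2H]OC")
  expect_identical(sum(gd@atoms$elem == "H" & gd@atoms$isotope == 2L), 1L)

  before <- smi2graph("CCO")
  expect_identical(virtualizeHydrogens(before)@atoms, before@atoms)
})

test_that("setRingMode follows Huckel's rule and preserves the InChI", {
  g <- setRingMode(smi2graph("C1=CC=CC=C1"), "aromatic")
  expect_true(all(g@atoms$arom))
  expect_identical(canonicalSmiles(g), "c1ccccc1")

  anti <- setRingMode(smi2graph("C1=CC=C1"), "aromatic")   # 4 pi electrons
  expect_false(any(anti@atoms$arom))

  ar <- setRingMode(smi2graph("c1ccccc1"), "aromatic")
  kek <- setRingMode(smi2graph("c1ccccc1"), "kekule")
  expect_match(canonicalSmiles(kek), "C1")
  expect_identical(computeInchi(ar)$inchi, computeInchi(kek)$inchi)
})

test_that("crossed flags mark only stereogenic-capable acyclic double bonds", {
  g <- fixCrossedDoubleBonds(flattenStereo(smi2graph("C/C=C/C"))$graph)
  expect_identical(sum(g@bonds$crossed), 1L)
  expect_true(g@bonds$crossed[g@bonds$order == 2L])
  sdf <- writeMolBlock(g)
  expect_match(sdf, "  2  3  2  3", fixed = TRUE)   # stereo code 3 in the ctab

  expect_identical(sum(fixCrossedDoubleBonds(smi2graph("C=CC"))@bonds$crossed), 0L)
  bz <- fixCrossedDoubleBonds(perceiveAromaticity(smi2graph("c1ccccc1")))
  expect_identical(sum(bz@bonds$crossed), 0L)
})

test_that("sanitizeCoordinates generates layouts only when needed", {
  g <- smi2graph("CCO")                       # SMILES-born: no coordinates
  expect_identical(g@dim, 0L)
  s <- sanitizeCoordinates(g)
  expect_identical(s@dim, 2L)
  expect_gt(min(dist(cbind(s@atoms$x, s@atoms$y))), 1e-4)
  expect_identical(s@atoms$elem, g@atoms$elem)
  # valid coordinates pass through untouched
  expect_identical(sanitizeCoordinates(s)@atoms, s@atoms)
})
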