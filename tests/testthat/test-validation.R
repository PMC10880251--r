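# Parsing, valence remediation and the composition / ambiguity / size filters.

test_that("parseStructure returns structured failures, never raises", {
  ok <- parseStructure("CCO", "smi")
  expect_identical(ok$status, "ok")
  expect_identical(heavyAtomCount(ok$graph), 3L)
  expect_identical(netCharge(ok$graph), 0L)

  bad <- parseStructure("C1CC", "smi")
  expect_identical(bad$status, "failed")
  expect_match(bad$messages, "ring closure")

  corrupt <- parseStructure(CORRUPT_MOL, "mol")
  expect_identical(corrupt$status, "failed")

  expect_identical(parseStructure("", "smi")$status, "failed")
})

test_that("correctValence remediates hypervalent nitrogen drawings", {
  cases <- list(
    c("CN(=O)=O", "[O-][N+](=O)C"),         # pentavalent nitro
    c("O=n1ccccc1", "[O-][n+]1ccccc1"),     # hypervalent aromatic N-oxide
    c("CN(C)(C)=O", "[O-][N+](C)(C)C"),     # trimethylamine N-oxide
    c("CN=N#N", "[N-]=[N+]=NC")             # pentavalent azide
  )
  for (cs in cases) {
    cv <- correctValence(smi2graph(cs[1]))
    expect_true(cv$ok)
    expect_identical(canonicalSmiles(cv$graph), cs[2])
    expect_gt(length(cv$log), 0)
    # net charge unchanged by charge separation
    expect_identical(netCharge(cv$graph), netCharge(smi2graph(cs[1])))
  }
  # valid input: identity with empty log
  cv <- correctValence(smi2graph("CCO"))
  expect_true(cv$ok)
  expect_length(cv$log, 0)
  expect_identical(canonicalSmiles(cv$graph), "CCO")
})

test_that("correctValence is idempotent and conserves heavy atoms", {
  for (s in c("CN(=O)=O", "O=n1ccccc1", "CC(=O)O", "c1ccccc1", "CN=N#N")) {
    g <- smi2graph(s)
    once <- correctValence(g)
    twice <- correctValence(once$graph)
    expect_true(twice$ok)
    expect_identical(canonicalSmiles(twice$graph), canonicalSmiles(once$graph))
    expect_length(twice$log, 0)
    expect_identical(heavy_multiset(once$graph), heavy_multiset(g))
  }
})

test_that("irreparable valence errors fail as failed_parsing", {
  cv <- correctValence(smi2graph("CC(C)(C)(C)C"))   # five-coordinate carbon
  expect_false(cv$ok)
  expect_identical(cv$reason, "failed_parsing")
  expect_match(cv$messages, "valence")
})

test_that("classifyComposition partitions organic / inorganic / organometallic", {
  expect_identical(classifyComposition(smi2graph("CCO")), "organic")
  expect_identical(classifyComposition(smi2graph("CC[Pb](CC)(CC)CC")),
                   "organometallic")
  expect_identical(classifyComposition(smi2graph("O=[Si]=O")), "inorganic")
  # boron and silicon organics are accepted as organic
  expect_identical(classifyComposition(smi2graph("B(O)(O)c1ccccc1")), "organic")
  expect_identical(classifyComposition(smi2graph("C[Si](C)(C)C")), "organic")
})

test_that("detectAmbiguous flags wildcards and Markush query atoms", {
  expect_true(detectAmbiguous(smi2graph("*CC"), "*CC"))
  p <- parseStructure(MARKUSH_MOL, "mol")   # R# survives as a wildcard atom
  expect_identical(p$status, "ok")
  expect_true(detectAmbiguous(p$graph, MARKUSH_MOL))
  expect_false(detectAmbiguous(smi2graph("CCO"), "CCO"))
})

test_that("sizeShapeCheck applies MW / heavy-atom / nano-ratio bounds", {
  lim <- sizeLimits(enabled = TRUE, heavyMin = 2, nanoRatioMax = 1.3)
  hexane <- smi2graph("CCCCCC")
  expect_identical(heavyBondCount(hexane), 5L)
  expect_identical(sizeShapeCheck(hexane, lim), "pass")
  expect_identical(sizeShapeCheck(smi2graph("C"), lim), "size")
  cubane <- smi2graph("C12C3C4C1C5C4C3C25")
  expect_identical(heavyBondCount(cubane) / heavyAtomCount(cubane), 1.5)
  expect_identical(sizeShapeCheck(cubane, lim), "nano_shape")
  mw <- sizeLimits(enabled = TRUE, mwMin = 100)
  expect_identical(sizeShapeCheck(smi2graph("CCO"), mw), "size")
  # disabled limits never discard
  expect_identical(sizeShapeCheck(smi2graph("C"), sizeLimits()), "pass")
  expect_identical(sizeShapeCheck(cubane, sizeLimits()), "pass")
})

test_that("acyclic fragments always pass any nano ratio threshold >= 1", {
  # bonds/heavy = 1 + (rings - fragments)/heavy; trees have rings = 0
  set.seed(7)
  lim <- sizeLimits(enabled = TRUE, heavyMin = 1, nanoRatioMax = 1)
  for (rep in 1:20) {
    n <- sample(2:14, 1)
    parents <- vapply(2:n, function(k) sample(k - 1L, 1), integer(1))
    atoms <- data.frame(elem = rep("C", n), charge = 0L, isotope = 0L,
                        hcount = 0L, arom = FALSE, x = 0, y = 0, z = 0)
    bonds <- data.frame(a1 = parents, a2 = 2:n, order = 1L, arom = FALSE,
                        crossed = FALSE)
    g <- fillImplicitH(MolGraph(atoms, bonds))
    expect_identical(sizeShapeCheck(g, lim), "pass")
    expect_identical(heavyBondCount(g), n - 1L)
  }
})

test_that("molecular weight accounts for implicit hydrogens and isotopes", {
  expect_equal(molWeight(smi2graph("C")), 16.043, tolerance = 1e-3)
  expect_equal(molWeight(smi2graph("CCO")), 46.069, tolerance = 1e-3)
  # deuterated methanol heavier than methanol by ~1
  d <- molWeight(smi2graph("[2H]OC")) - molWeight(smi2graph("OC"))
  expect_equal(d, 2 - 1.008, tolerance = 0.01)
})
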