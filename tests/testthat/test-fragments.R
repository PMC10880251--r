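# Fragment splitting, blocklist lookup, salt/solvent stripping and the
# mixture rule.

test_that("splitFragments returns components in deterministic order", {
  expect_length(splitFragments(smi2graph("CC(=O)[O-].[Na+]")), 2)
  expect_length(splitFragments(smi2graph("CCO")), 1)
  expect_length(splitFragments(smi2graph("CCO.O.O")), 3)
  frags <- splitFragments(smi2graph("O.CC(=O)[O-].[Na+]"))
  expect_identical(vapply(frags, canonicalSmiles, ""),
                   c("[O-]C(=O)C", "O", "[Na+]"))
})

test_that("lookupBlocklist matches by skeleton InChIKey, charge-insensitively", {
  bl <- defaultBlocklist()
  na_id <- lookupBlocklist(smi2graph("[Na+]"), bl)
  expect_false(is.na(na_id))
  expect_identical(bl$name[bl$salt_id == na_id], "sodium")
  water <- lookupBlocklist(smi2graph("O"), bl)
  expect_identical(bl$class[bl$salt_id == water], "solvent")
  # acetate and acetic acid hit the same entry
  expect_identical(lookupBlocklist(smi2graph("CC(=O)[O-]"), bl),
                   lookupBlocklist(smi2graph("CC(=O)O"), bl))
  expect_true(is.na(lookupBlocklist(smi2graph("c1ccccc1CCN"), bl)))
})

test_that("stripAndRebalance handles salts, mixtures and inorganics", {
  sr <- stripAndRebalance(smi2graph("CC(=O)[O-].[Na+]"))
  expect_identical(sr$status, "ok")
  expect_identical(canonicalSmiles(sr$parent), "CC(=O)O")
  expect_identical(netCharge(sr$parent), 0L)
  expect_identical(sr$stripped$smiles, "[Na+]")
  expect_match(sr$chargeOps, "protonated", all = FALSE)

  expect_identical(stripAndRebalance(smi2graph("CCO.CCN"))$status, "mixture")
  expect_identical(stripAndRebalance(smi2graph("[Na+].[Cl-]"))$status,
                   "inorganic")

  # quaternary N: charge +1 must be retained (no H to remove)
  sr <- stripAndRebalance(smi2graph("C[N+](C)(C)C.[Cl-]"))
  expect_identical(sr$status, "ok")
  expect_identical(netCharge(sr$parent), 1L)
  expect_identical(canonicalSmiles(sr$parent), "C[N+](C)(C)C")
})

test_that("mixtureDecision passes at most one organic fragment", {
  expect_identical(mixtureDecision(list(smi2graph("CCO"))), "pass")
  expect_identical(mixtureDecision(list(smi2graph("CCO"), smi2graph("Nc1ccccc1"))),
                   "mixture")
  expect_identical(mixtureDecision(list()), "pass")
})

test_that("heavy atoms are conserved through stripping, and stripping is idempotent", {
  salts <- c("CC(=O)[O-].[Na+]", "CCO.O.O", "c1ccccc1CCN.Cl",
             "C[N+](C)(C)C.[Cl-]", "CCCCN.Cc1ccc(cc1)S(O)(=O)=O",
             "NCCCCC(N)C(O)=O.OC(=O)C(F)(F)F", "CCO.CCO", "CCO.[Fe]")
  for (s in salts) {
    g <- smi2graph(s)
    sr <- stripAndRebalance(g)
    expect_identical(sr$status, "ok")
    stripped_atoms <- unlist(lapply(sr$stripped$smiles, function(x)
      heavy_multiset(smi2graph(x))))
    expect_identical(sort(c(heavy_multiset(sr$parent), stripped_atoms)),
                     heavy_multiset(g), info = s)
    # idempotence: the parent has nothing left to strip
    again <- stripAndRebalance(sr$parent)
    expect_identical(again$status, "ok")
    expect_identical(nrow(again$stripped), 0L, info = s)
  }
})

test_that("fragment order in the input SMILES does not change the result", {
  a <- stripAndRebalance(smi2graph("CC(=O)[O-].[Na+]"))
  b <- stripAndRebalance(smi2graph("[Na+].CC(=O)[O-]"))
  expect_identical(canonicalSmiles(a$parent), canonicalSmiles(b$parent))
  expect_identical(a$stripped, b$stripped)
  c1 <- stripAndRebalance(smi2graph("O.CCO.O"))
  c2 <- stripAndRebalance(smi2graph("CCO.O.O"))
  expect_identical(canonicalSmiles(c1$parent), canonicalSmiles(c2$parent))
  expect_identical(sort(c1$stripped$smiles), sort(c2$stripped$smiles))
})

test_that("records made only of blocklisted fragments are never QSAR-ready", {
  rep <- corpus_report()
  discarded <- vapply(rep$outcomes, identifier, "")
  expect_true("sodium-chloride" %in% discarded)
  expect_identical(
    reasonTag(rep$outcomes[[match("sodium-chloride", discarded)]]),
    "inorganic")
})

test_that("a custom blocklist file can replace the shipped one", {
  d <- withr::local_tempdir()
  f <- file.path(d, "tiny.csv")
  write.csv(data.frame(salt_id = "X-1", smiles = "[K+]", class = "counterion",
                       name = "potassium"), f, row.names = FALSE)
  bl <- loadBlocklist(f)
  expect_identical(nrow(bl), 1L)
  expect_false(is.na(lookupBlocklist(smi2graph("[K+]"), bl)))
  expect_true(is.na(lookupBlocklist(smi2graph("[Na+]"), bl)))
})
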