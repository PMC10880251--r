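## Deterministic toy-structure corpus exercising every pipeline branch, every
## discard reason and every transform family. Expected outputs were derived
## by hand per case (charge bookkeeping, proton moves, fragment counting) and
## frozen as the Open Babel canonical form of the hand-derived structure, so
## the expectations are independent of the pipeline implementation.

#' The configuration the fixture corpus is defined against
#'
#' Aromatic ring mode, deduplication on, and the size/shape filter enabled
#' with heavy atoms in 2..80 and nano ratio threshold 1.3 (so that the
#' undersized, oversized and cage-shaped corpus members exercise the size and
#' nano-shape branches).
#' @param input,outputDir passed through to [stdConfig()].
#' @return a StdConfig
#' @export
fixtureConfig <- function(input = "", outputDir = NA_character_) {
  stdConfig(input = input, outputDir = outputDir, ringMode = "aromatic",
            dedup = TRUE,
            sizeFilter = sizeLimits(enabled = TRUE, heavyMin = 2,
                                    heavyMax = 80, nanoRatioMax = 1.3))
}

.C60_SMILES <- paste0(
  "C12=C3C4=C5C6=C1C7=C8C9=C1C%10=C%11C(=C29)C3=C2C3=C4C4=C5C5=C9C6=C7C6=",
  "C7C8=C1C1=C8C%10=C%10C%11=C2C2=C3C3=C4C4=C5C5=C%11C%12=C(C6=C95)C7=C1C",
  "1=C%12C5=C%11C4=C3C3=C5C(=C81)C%10=C23")

#' The fixture corpus
#'
#' At least forty deterministic cases spanning parse failures, hypervalent
#' N remediation, nitro/azide mesomer pairs, keto-enol / enamine-imine /
#' ynol-ketene / nitroso-oxime / lactam tautomer pairs, zwitterions, salts
#' and hydrates, mixtures, inorganics, organometallics, Markush wildcards,
#' stereo-bearing structures, and cage structures for the nano-shape filter.
#' `expected` is the branch under [fixtureConfig()] ("pass" or a reason tag);
#' `expected_smiles` is the frozen canonical output for passing cases
#' (NA where the case is order-dependent only, e.g. duplicates).
#'
#' @return data.frame(name, smiles, expected, expected_smiles, family)
#' @export
fixtureCorpus <- function() {
  M <- function(name, smiles, expected, expected_smiles = NA_character_,
                family = "misc") {
    data.frame(name = name, smiles = smiles, expected = expected,
               expected_smiles = expected_smiles, family = family,
               stringsAsFactors = FALSE)
  }
  rbind(
    ## parse failures
    M("unclosed-ring", "C1CC", "failed_parsing", family = "parse"),
    M("pentavalent-carbon", "CC(C)(C)(C)C", "failed_parsing", family = "parse"),
    M("blank-input", "", "failed_parsing", family = "parse"),
    ## valence remediation
    M("nitro-pentavalent", "CN(=O)=O", "pass", "[O-][N+](=O)C", "valence"),
    M("nitro-charge-separated", "C[N+](=O)[O-]", "duplicate", family = "valence"),
    M("pyridine-oxide-hypervalent", "O=n1ccccc1", "pass", "[O-][n+]1ccccc1", "valence"),
    M("trimethylamine-oxide", "CN(C)(C)=O", "pass", "[O-][N+](C)(C)C", "valence"),
    ## mesomers
    M("azide-cumulated", "CN=[N+]=[N-]", "pass", "[N-]=[N+]=NC", "mesomer"),
    M("azide-inner-anion", "C[N-][N+]#N", "duplicate", family = "mesomer"),
    M("dmso", "CS(C)=O", "pass", "CS(=O)C", "mesomer"),
    M("dmso-charge-separated", "C[S+](C)[O-]", "duplicate", family = "mesomer"),
    ## tautomers (first member passes, partner collapses as duplicate)
    M("acetone", "CC(C)=O", "pass", "CC(=O)C", "tautomer"),
    M("propen-2-ol", "CC(O)=C", "duplicate", family = "tautomer"),
    M("ethanimine", "CC=N", "pass", "CC=N", "tautomer"),
    M("vinylamine", "NC=C", "duplicate", family = "tautomer"),
    M("2-pyridone", "O=C1C=CC=CN1", "pass", "O=c1cccc[nH]1", "tautomer"),
    M("2-hydroxypyridine", "Oc1ccccn1", "duplicate", family = "tautomer"),
    M("ketene", "C=C=O", "pass", "C=C=O", "tautomer"),
    M("ynol", "OC#C", "duplicate", family = "tautomer"),
    M("acetoxime", "CC(C)=NO", "pass", "ON=C(C)C", "tautomer"),
    M("2-nitrosopropane", "CC(C)N=O", "duplicate", family = "tautomer"),
    ## zwitterions / neutralization
    M("glycine-zwitterion", "[NH3+]CC([O-])=O", "pass", "NCC(=O)O", "neutralization"),
    M("glycine-neutral", "NCC(O)=O", "duplicate", family = "neutralization"),
    M("betaine-permanent", "C[N+](C)(C)CC([O-])=O", "pass",
      "[O-]C(=O)C[N+](C)(C)C", "neutralization"),
    M("methylammonium", "C[NH3+]", "pass", "CN", "neutralization"),
    ## salts, counterions, hydrates
    M("sodium-acetate", "CC(=O)[O-].[Na+]", "pass", "CC(=O)O", "salt"),
    M("acetic-acid", "CC(=O)O", "duplicate", family = "salt"),
    M("ethanol-dihydrate", "CCO.O.O", "pass", "CCO", "salt"),
    M("phenethylamine-hcl", "c1ccccc1CCN.Cl", "pass", "NCCc1ccccc1", "salt"),
    M("tetramethylammonium-chloride", "C[N+](C)(C)C.[Cl-]", "pass",
      "C[N+](C)(C)C", "salt"),
    M("butylamine-tosylate", "CCCCN.Cc1ccc(cc1)S(O)(=O)=O", "pass",
      "CCCCN", "salt"),
    M("lysine-tfa", "NCCCCC(N)C(O)=O.OC(=O)C(F)(F)F", "pass",
      "NCCCCC(C(=O)O)N", "salt"),
    ## mixtures
    M("ethanol-ethylamine", "CCO.CCN", "mixture", family = "mixture"),
    M("aniline-butanol", "Nc1ccccc1.OCCCC", "mixture", family = "mixture"),
    ## inorganics
    M("sodium-chloride", "[Na+].[Cl-]", "inorganic", family = "inorganic"),
    M("silica", "O=[Si]=O", "inorganic", family = "inorganic"),
    M("water-only", "O", "inorganic", family = "inorganic"),
    ## organometallics
    M("tetraethyllead", "CC[Pb](CC)(CC)CC", "organometallic", family = "organometallic"),
    M("ethylmagnesium-bromide", "CC[Mg]Br", "organometallic", family = "organometallic"),
    ## ambiguous / Markush
    M("wildcard-attachment", "*CC", "ambiguous_structure", family = "ambiguous"),
    M("wildcard-ring", "C1CC1*", "ambiguous_structure", family = "ambiguous"),
    ## size and shape
    M("methane-undersized", "C", "size", family = "size"),
    M("nonacontane-oversized", strrep("C", 90), "size", family = "size"),
    M("fullerene-c60", .C60_SMILES, "nano_shape", family = "size"),
    M("cubane-cage", "C12C3C4C1C5C4C3C25", "nano_shape", family = "size"),
    ## stereochemistry
    M("l-alanine", "C[C@H](N)C(=O)O", "pass", "CC(C(=O)O)N", "stereo"),
    M("trans-2-butene", "C/C=C/C", "pass", "CC=CC", "stereo"),
    M("cis-2-butene", "C/C=C\\C", "duplicate", family = "stereo"),
    ## unchanged aromatic / drug-like structures
    M("aspirin", "CC(=O)Oc1ccccc1C(O)=O", "pass",
      "CC(=O)Oc1ccccc1C(=O)O", "aromatic"),
    M("caffeine", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", "pass",
      "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "aromatic"),
    M("toluene", "Cc1ccccc1", "pass", "Cc1ccccc1", "aromatic"),
    M("phenol", "Oc1ccccc1", "pass", "Oc1ccccc1", "aromatic")
  )
}

#' Order-sensitivity probe
#'
#' A concrete structure and rule pair whose outcome depends on application
#' order: 1-aminoprop-1-en-2-ol carries both an enol and an enamine motif
#' sharing the same C=C. The keto-enol rule first yields aminoacetone; the
#' enamine-imine rule first yields the amino alcohol imine. The engine's
#' documented library order applies the keto-enol family first, so the
#' pipeline must reproduce `result_AB`.
#'
#' @param library a RuleLibrary.
#' @return list(structure=, ruleA=, ruleB=, result_AB=, result_BA=)
#' @export
ruleOrderProbe <- function(library = defaultRuleLibrary()) {
  structure_smiles <- "CC(O)=CN"
  idA <- "TAU-ENOL-O-H1"        # keto-enol, =CH- terminus
  idB <- "TAU-ENAMINE-H2-H0"    # primary enamine, fully substituted terminus
  r <- library@rules
  ruleA <- c(as.list(r[r$rule_id == idA, ]),
             list(parsed = library@parsed[[which(r$rule_id == idA)]]))
  ruleB <- c(as.list(r[r$rule_id == idB, ]),
             list(parsed = library@parsed[[which(r$rule_id == idB)]]))
  g <- parseStructure(structure_smiles, "smi")$graph
  ab <- applyRule(applyRule(g, ruleA)$graph, ruleB)$graph
  ba <- applyRule(applyRule(g, ruleB)$graph, ruleA)$graph
  list(structure = structure_smiles, ruleA = idA, ruleB = idB,
       result_AB = canonicalSmiles(ab), result_BA = canonicalSmiles(ba))
}

#' Write the fixture corpus to disk for external validation
#'
#' Emits `fixtures.smi` (SMILES + name) and `fixtures_expected.csv` (the full
#' corpus table) into `dir`.
#' @param dir output directory (created if needed).
#' @return (invisibly) the paths written
#' @export
writeFixtureFiles <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- fixtureCorpus()
  smi <- file.path(dir, "fixtures.smi")
  keep <- nzchar(corpus$smiles)
  writeLines(paste0(corpus$smiles[keep], "\t", corpus$name[keep]), smi)
  csv <- file.path(dir, "fixtures_expected.csv")
  utils::write.csv(corpus, csv, row.names = FALSE)
  invisible(c(smi = smi, expected = csv))
}

#' Run the pipeline over the fixture corpus
#'
#' Convenience wrapper used by the test suite and the acceptance script:
#' writes the corpus to a temporary .smi file and runs the full workflow on
#' it under [fixtureConfig()] (or a caller-supplied configuration).
#'
#' @param config optional StdConfig; input/outputDir are filled in.
#' @param dir working directory for input and outputs.
#' @return the run report from [runPipeline()]
#' @export
runFixtureCorpus <- function(config = NULL, dir = tempfile("qsarstd_fix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- fixtureCorpus()
  input <- file.path(dir, "corpus.smi")
  ## blank-input is representable in CSV but not in a .smi line; the corpus
  ## is therefore shipped as a one-column CSV so even empty entries survive
  input <- file.path(dir, "corpus.csv")
  utils::write.csv(data.frame(ID = corpus$name, SMILES = corpus$smiles,
                              stringsAsFactors = FALSE),
                   input, row.names = FALSE)
  if (is.null(config)) config <- fixtureConfig()
  config@input <- input
  config@outputDir <- dir
  config@format <- "csv"
  config@smilesColumn <- "SMILES"
  config@idColumn <- "ID"
  runPipeline(config)
}
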