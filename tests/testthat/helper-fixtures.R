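# Shared helpers: parse a SMILES into a MolGraph, build records, and cache
# full corpus pipeline runs (they are reused by several test files).

smi2graph <- function(smiles) {
  p <- parseStructure(smiles, "smi")
  stopifnot(p$status == "ok")
  p$graph
}

make_record <- function(smiles, id = "r1") {
  p <- parseStructure(smiles, "smi")
  new("ChemicalRecord", identifier = id, rawInput = smiles,
      sourceFormat = "smi", graph = p$graph, parseStatus = p$status,
      parseMessages = p$messages, meta = list())
}

# full pipeline run over the fixture corpus, memoized per configuration
.corpus_cache <- new.env(parent = emptyenv())
corpus_report <- function(ring = "aromatic", dedup = TRUE) {
  key <- paste(ring, dedup)
  if (is.null(.corpus_cache[[key]])) {
    cfg <- fixtureConfig()
    cfg@ringMode <- ring
    cfg@dedup <- dedup
    .corpus_cache[[key]] <- runFixtureCorpus(config = cfg)
  }
  .corpus_cache[[key]]
}

# multiset of heavy-atom element symbols of a structure
heavy_multiset <- function(graph) {
  a <- graph@atoms
  sort(a$elem[!(a$elem %in% c("H", "D", "T"))])
}

# a handwritten two-record SDF (ethanol + benzene) used by the io tests
TWO_RECORD_SDF <- paste(c(
  "ethanol", "  test", "",
  "  3  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    2.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0",
  "  2  3  1  0  0  0  0",
  "M  END",
  "> <CASRN>", "64-17-5", "", "$$$$",
  "benzene", "  test", "",
  "  6  6  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.5000    0.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    1.7320    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    0.0000    1.7320    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.5000    0.8660    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  2  0  0  0  0",
  "  2  3  1  0  0  0  0",
  "  3  4  2  0  0  0  0",
  "  4  5  1  0  0  0  0",
  "  5  6  2  0  0  0  0",
  "  6  1  1  0  0  0  0",
  "M  END", "$$$$"), collapse = "\n")

# a MOL block with a Markush R# atom
MARKUSH_MOL <- paste(c(
  "markush", "  test", "",
  "  3  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    2.0000    0.0000    0.0000 R#  0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0",
  "  2  3  1  0  0  0  0",
  "M  END"), collapse = "\n")

# a MOL block with a corrupt atom-count line
CORRUPT_MOL <- paste(c(
  "bad", "  test", "",
  "  X  2  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0",
  "M  END"), collapse = "\n")
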