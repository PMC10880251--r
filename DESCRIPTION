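Package: qsarstd
Title: QSAR-Ready Chemical Structure Standardization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts heterogeneous chemical structure inputs (SMILES, CSV,
    MOL, SDF) into a deduplicated set of canonical, model-ready ("QSAR-ready")
    structures suitable for molecular descriptor calculation. The pipeline
    performs valence remediation, filtering of inorganics, organometallics and
    Markush/ambiguous structures, salt and solvent stripping against an
    editable blocklist with charge rebalancing of the parent, mixture
    rejection, an ordered library of reaction-format (SMIRKS-style)
    mesomer/tautomer standardization rules, neutralization, stereochemistry
    flattening, hydrogen virtualization, aromatic/Kekule ring handling,
    InChI/InChIKey-based duplicate collapsing, optional size/shape filtering
    and optional deterministic 3D embedding. Every rejected input is tagged
    with a machine-readable reason and reported alongside the standardized
    output files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    utils,
    stats,
    tools,
    igraph,
    yaml,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: Open Babel command line tools (obabel, obminimize,
    obenergy) for Kekule SMILES output and 3D embedding
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'obabel.R'
    'molgraph.R'
    'smirks.R'
    'transform.R'
    'validation.R'
    'fragments.R'
    'transform-stage.R'
    'chem-io.R'
    'config.R'
    'pipeline.R'
    'fixtures.R'
    'qsarstd-package.R'
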