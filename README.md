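# qsarstd — QSAR-ready chemical structure standardization

`qsarstd` turns heterogeneous chemical structure inputs — SMILES line files,
CSV spreadsheets, MOL and SDF files — into a deduplicated set of canonical,
model-ready ("QSAR-ready") structures suitable for molecular descriptor
calculation, and tags every input it cannot standardize with a
machine-readable reason. It is written for QSAR/QSPR modelers and
cheminformatics data curators who need the *same* substance to always reach
the descriptor calculator in the *same* form, whether it arrived as a
sodium salt, a hydrate, a charge-separated mesomer or a minor tautomer.

## What it does

Every record passes through a fixed stage order; the first failing stage
short-circuits with one reason tag from a closed vocabulary
(`failed_parsing`, `mixture`, `inorganic`, `organometallic`,
`ambiguous_structure`, `size`, `nano_shape`, `duplicate`):

```
parse → valence remediation → Markush/ambiguity filter
     → fragment split / salt+solvent strip / mixture rule
     → composition filter (organic only)
     → ordered mesomer/tautomer rules → neutralization
     → stereo flattening → H virtualization → ring mode (aromatic/Kekulé)
     → crossed double bonds → coordinate sanitization
     → size/shape filter (opt-in) → InChI/InChIKey + canonical SMILES
     → duplicate collapsing by InChI (opt-in) → output files
```

The core is an ordered library of reaction-format transformation rules,
`pattern>>product` with mapped atoms (e.g. keto–enol
`[OX2H:1][C:2]=[C:3]>>[O:1]=[C:2][C:3]`, nitro
`[#7v5X3+0:1](=[OX1:2])=[OX1:3]>>[#7+:1](=[O:2])[O-:3]`). The shipped
library holds 104 individually toggleable rules; each rule is applied to
fixed point, in library order — order is semantic, since some rules do not
commute — with rollback of any edit that would create an illegal valence.
Salt/solvent stripping matches fragments against an editable blocklist of
~60 counterions and solvents by the skeleton block of the standard
InChIKey (charge-state-insensitive), then rebalances the parent's charge
by protonation/deprotonation at charged heteroatoms. Duplicates are
collapsed on the standard InChI, which also guarantees that aromatic and
Kekulé runs of the same input agree.

## Worked example

```r
library(qsarstd)

f <- tempfile(fileext = ".smi")
writeLines(c("CC(=O)[O-].[Na+] na-acetate", "CCO.CCN mix"), f)
rec <- readStructures(f)

res <- standardizeRecord(rec[[1]])
res
#> QsarReadyResult na-acetate: CC(=O)O
#>   InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4) / QTBSBXVTEAMEQO-UHFFFAOYSA-N
qsarSmiles(res)        # "CC(=O)O"      — acetate kept, protonated to the acid
res@saltSolvent        # "[Na+]"        — the stripped counterion
reasonTag(standardizeRecord(rec[[2]]))
#> "mixture"            — two distinct organic fragments do not pass
```

Or from the shell, via the bundled CLI:

```sh
Rscript inst/scripts/qsar-ready-std.R run demo.csv \
    --smiles-col SMILES --id-col ID --dedup --out out/
# processed 4 record(s): 2 QSAR-ready, 2 discarded
#   mixture              1
#   inorganic            1
# wrote out/demo_QSAR-ready.sdf
# wrote out/demo_QSAR-ready_smi.smi
# wrote out/demo_Summary_file.csv
# wrote out/demo_DiscardedStructures.csv
# wrote out/demo_StrippedSalts.csv
```

The summary CSV carries `ID, Original_SMILES, Canonical_QSARr, InChI,
InChIKey, Salt_Solvent, Salt_Solvent_ID`; discarded records land in
`*_DiscardedStructures.csv` with their reason; stripped fragments are
mapped in `*_StrippedSalts.csv`. Outputs are byte-identical across reruns.

A deterministic fixture corpus of 52 structures exercising every pipeline
branch ships with the package (`fixtureCorpus()`,
`qsar-ready-std fixtures --out DIR`), and `ruleOrderProbe()` returns a
concrete structure/rule pair proving that rule order changes the outcome.

## Documentation

The methods vignette (`vignettes/standardization.Rmd`) describes the
model: the rule language and engine guarantees, canonical tautomer
directions, blocklist stripping semantics, the neutralization model,
Hückel aromaticity handling, the deterministic 3D embedding design, all
tunable parameters with their defaults, and known limitations.
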