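---
title: "QSAR-ready structure standardization: model and design"
author: "qsarstd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSAR-ready structure standardization: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarstd)
```

## Why standardize

QSAR/QSPR models learn from molecular descriptors, and descriptors are
computed from a concrete drawing of a molecular graph. The same substance can
be encoded in many equivalent ways — a nitro group as a pentavalent neutral
nitrogen or as a charge-separated pair, a lactam as its lactim tautomer, an
acid as its sodium salt, benzene as alternating bonds or an aromatic ring —
and each drawing yields different descriptor values. Training a model on one
convention and predicting on another silently corrupts the
structure–activity relationship. `qsarstd` converts heterogeneous structure
inputs (SMILES, CSV, MOL, SDF) into one canonical, desalted, neutralized,
tautomer-normalized, stereo-flattened form per substance — a "QSAR-ready"
structure — and tags every record it cannot standardize with a
machine-readable reason instead of dropping it.

## The pipeline

`standardizeRecord()` runs each record through a fixed stage order:

1. **parse** — Open Babel reads the input; MOL/SDF text is first normalized
   (validating the connection table and kekulizing aromatic bonds) and then
   loaded into the package's `MolGraph` container (atoms with element,
   formal charge, isotope and implicit-H count; bonds with Kekulé order,
   an aromaticity flag and the crossed-bond display flag);
2. **valence remediation** (`correctValence`) — hypervalent neutral nitrogen
   drawings (nitro, N-oxides, azides, diazo, isocyanides) become their
   charge-separated equivalents; a four-coordinate neutral N becomes an
   ammonium cation; anything still violating the legal valence set for its
   element and charge (a five-coordinate carbon, say) is irreparable and
   discarded as `failed_parsing`;
3. **ambiguity filter** — query atoms, R-groups and wildcard attachments
   (Markush structures) cannot describe one substance and are discarded;
4. **fragments** (`stripAndRebalance`) — connected components are separated,
   blocklisted salts/solvents stripped, true mixtures rejected, and the
   parent's net charge rebalanced toward zero;
5. **composition filter** — the parent must be organic: at least one carbon
   and no covalent carbon–metal bond;
6. **mesomer/tautomer rules** — the ordered reaction-format rule library;
7. **neutralization** — removable charges are discharged;
8. **stereo flattening**, **hydrogen virtualization**, **ring mode**,
   **crossed double bonds**, **coordinate sanitization**;
9. **size/shape filter** (opt-in), then **InChI/InChIKey and canonical
   SMILES generation**.

The first failing stage short-circuits with a single reason tag from the
closed vocabulary `r paste(REASON_TAGS, collapse = ", ")`. After all records
are processed, `deduplicate()` optionally collapses records with identical
standard InChI (first occurrence wins; duplicates are reported with the
surviving identifier), and `runPipeline()` writes five artifacts named from
the input stem: the QSAR-ready SDF and SMILES files, a summary CSV, the
discarded-structures CSV and the stripped-salt map.

Every input record ends up in exactly one of summary or discarded, so
`n_input = n_summary + n_discarded` holds for every run; the test suite
asserts this, together with full byte-level determinism of the output files.

## The transformation rule engine

The scientific core is an ordered library of reaction-format rules. A rule
is a two-step sequence — a substructure pattern that detects a feature, and
a mapped product template that prescribes the remedy — written as
`pattern>>product` in a SMARTS-subset language (elements, `#n`, aromatic
lowercase symbols, charge, `H`/`X`/`D`/`v`/`R` counts, negation, OR;
bonds `- = # : ~` plus the default single-or-aromatic bond). The engine
finds all embeddings by backtracking subgraph matching, edits charges,
hydrogen counts and bond orders at the matched sites, and re-applies the
rule until no match remains, with a 10-pass iteration cap as a guard
against oscillating rule pairs (cap hits are logged, never silent).

Three safety properties are enforced on every application: mapped
connectivity cannot change (rules move protons, charges and bond orders,
never heavy atoms — checked at parse time), an edit that would produce an
illegal valence is rolled back for that site, and the net formal charge is
preserved exactly (tautomer/mesomer families) or may only shrink in
magnitude (neutralization family).

The shipped library (`defaultRuleLibrary()`, a plain TSV users can edit)
holds `r ruleCount(defaultRuleLibrary())` individually toggleable rules:
mesomer normalizations (nitro, azide, diazo, N-oxide, sulfoxide/sulfone,
phosphine oxide and relatives are standardized to their charge-separated or
hypervalent conventions), 1,3-/1,5-/1,7-shift tautomer rules enumerated by
donor (O, S, Se, NH~2~, NH) and acceptor (C=C, C=N, C#C, C#N, N=O, N=N)
with substitution-specific variants ahead of the generic forms,
neutralization rules, and a set of expert rules shipped disabled (direction-
ambiguous amidine/guanidine shifts, dearomatizing variants). The canonical
directions follow the common conventions: carbonyl over enol, amide over
imidic acid (which also maps 2-hydroxy azines onto their oxo forms), imine
over enamine, cumulated ketene over ynol, oxime over nitroso,
charge-separated nitro/azide.

**Order matters and is controlled.** Some rules compete for the same atoms:
1-aminoprop-1-en-2-ol (`CC(O)=CN`) carries an enol and an enamine sharing
one C=C, and applying keto–enol before enamine–imine gives aminoacetone
while the reverse order gives an imino alcohol. `ruleOrderProbe()` returns
this triple, and the acceptance suite asserts both that the two orders
really differ and that the engine reproduces the documented library order
(keto–enol family first). Because order is semantic, `order_index` values
must be unique and the library is applied in exactly one ordered sweep,
each rule to its own fixed point — no global fixed-point iteration, which
also guarantees termination.

Aromatic atoms are deliberately excluded from the plain C=C tautomer rules
(phenol and aniline are canonical as drawn); rules that are *meant* to act
across aromatic systems (lactim to lactam) use element-number primitives to
match the Kekulé form regardless of aromatic flags.

## Fragments, blocklist and the mixture rule

The blocklist ships as an editable CSV of about sixty common counterions,
salt formers and solvents. At load it is compiled to the skeleton (first)
block of each entry's standard InChIKey, which makes matching insensitive
to charge state — acetate and acetic acid, chloride and hydrogen chloride,
hit the same entry. (Hydroxide is deliberately absent: standard InChI
represents it as the water skeleton with a proton layer, so the water entry
already covers it.)

Stripping semantics, chosen where the obvious rule is self-contradictory:

* single-fragment substances are never stripped — a lone ethanol record is
  a structure, not a solvent;
* inorganic blocklist entries (metal cations, halides, water) always strip;
* an *organic* counterion-class entry (acetate, tosylate, TFA) strips
  whenever any other organic fragment is present, so sodium acetate keeps
  acetate as its parent while butylammonium tosylate keeps the amine;
* an *organic* solvent-class entry (ethanol, DMSO, toluene) strips only
  next to a strictly larger organic fragment, so a drug–ethanol solvate
  loses the ethanol but an ethanol/ethylamine pair is a mixture rather
  than silently becoming ethylamine;
* identical copies of the remaining organic fragment collapse onto one
  parent, and non-blocklisted leftover inorganic fragments are stripped
  with an empty salt id — both recorded in the stripped list, so the
  heavy-atom multiset of parent plus stripped fragments always equals the
  input's.

Anything with two or more distinct organic fragments after stripping is a
mixture and does not pass. After stripping, the parent's net charge is
brought as close to zero as protonation/deprotonation at charged
heteroatoms allows; atoms participating in an adjacent +/− pair (nitro,
N-oxide, azide interiors) are protected, as are cations without hydrogens
(quaternary ammonium keeps its permanent +1).

## Neutralization

Charged structures are neutralized "when possible" by two mechanisms: the
library's neutralization rules (each application guarded so the net-charge
magnitude never grows — protonating one oxyanion of a doubly charged
sulfate is fine, protonating the oxygen of a neutral nitro group is rolled
back), then paired proton transfer for zwitterions (glycine's ammonium
hands its proton to the carboxylate; betaine, with no proton to give,
stays zwitterionic) and a residual nearest-to-zero adjustment.

## Stereochemistry, rings, coordinates

2D QSAR descriptors are stereo-blind, so defined tetrahedral and
double-bond configurations are flattened. The removed information is kept
as a payload — the count of defined centres/configured double bonds (read
from the /t and /b layers of the stereo-bearing InChI) plus the stereo
canonical SMILES — and reinstated for 3D embedding when the standardized
skeleton still matches. After flattening, acyclic non-aromatic C=C/C=N
bonds whose both ends carry another heavy substituent get the
crossed-bond flag (V2000 stereo code 3) in SDF output, marking their
configuration as explicitly unknown. This is a conservative approximation:
it does not detect ends with two *identical* substituents, so a
2-methyl-2-butene is flagged although it has no stereoisomers.

Ring handling perceives aromaticity by Hückel's rule on 5–7-membered rings
(endocyclic double bond contributes one π electron per atom, exocyclic
double bonds zero, heteroatom lone pairs two, 4n+2 test per ring).
Macrocyclic aromaticity (azulene's 10-ring, annulenes) is out of model.
Aromatic mode writes aromatic SMILES; Kekulé mode writes alternating bond
orders; both describe the same molecule, which the pipeline verifies by
requiring identical InChI columns between the two modes over the whole
fixture corpus. Missing, all-zero or overlapping 2D coordinates (closer
than 10^-4^) are replaced with a fresh deterministic layout; valid
coordinates pass through.

## Deterministic 3D embedding

Stock 3D builders are seeded from the clock and unsuitable for a pipeline
whose outputs must be reproducible. `embed3d()` therefore builds its
starting geometry deterministically: explicit hydrogens plus a
deterministic 2D layout, then an out-of-plane perturbation of the z
coordinates drawn from R's RNG under the embedding seed (default 42),
followed by MMFF94 minimization (UFF fallback when MMFF94 lacks
parameters). The same input and seed give bit-identical coordinates; a
different seed gives a different, still-minimized conformation. The
optimized energy is never above the starting energy, and methane relaxes
to C–H bonds of about 1.09 Å. The price of determinism is that the result
is a plausible local minimum, not a conformer-search global minimum —
acceptable for descriptor calculation, and documented rather than hidden.
Embedding failures fall back to 2D output with a warning row in the log,
not a discard.

## Size and shape filter

Off by default; when enabled it discards parents outside the configured
molecular weight or heavy-atom bounds (`size`) and cage-like structures
whose bonds-per-heavy-atom ratio exceeds `nanoRatioMax` (`nano_shape`).
For a connected graph the ratio equals 1 + (rings − 1)/heavy-atoms: trees
sit below 1, ordinary polycyclics slightly above, fused cages well above.
The default threshold 1.3 is an explicit package choice (no literature
value exists): C~60~ (ratio 1.5) and cubane (1.5) are flagged, while
naphthalene (1.1) and steroids pass. The default `heavyMin = 2` merely
keeps single atoms out when the filter is on; MW bounds are unset.

## The fixture corpus

`fixtureCorpus()` generates `r nrow(fixtureCorpus())` deterministic cases —
parse failures, hypervalent drawings, mesomer/tautomer pairs, zwitterions,
salts and hydrates, mixtures, inorganics, organometallics, Markush
wildcards, stereo-bearing inputs, and cage structures — with every discard
reason covered at least twice. Expected outcomes were derived by hand per
case (charge bookkeeping, proton moves, fragment counting) and frozen as
the Open Babel canonical form of the hand-derived structure, so the
expectations do not depend on the pipeline they test. The corpus expects
its branches under `fixtureConfig()`: aromatic mode, deduplication on, and
the size filter enabled at heavy atoms 2–80, nano ratio 1.3, chosen so the
size branches are exercised.

What passing this corpus shows: the stage order, every filter branch, the
rule families, charge handling and the output contract behave as specified
on unambiguous, small-molecule inputs. What it does not show: behaviour on
the long tail of real registry data — polymers, radicals, complex
organometallics drawn with dative bonds, macrocyclic aromatics, isotope
mixtures, or tautomer families outside the shipped rules. Records of that
kind fail *safely* (they end in the discarded file with a reason) but the
corpus makes no claim that their standardized forms would be chemically
ideal.

## Numerical and degenerate-input choices

* Implicit hydrogens fill to the smallest legal valence ≥ the bond-order
  sum; elements without a valence model (metals, query atoms) imply none.
* Fragment ordering is by descending heavy-atom count with canonical-SMILES
  ties, so results are independent of input atom numbering.
* Duplicate resolution keeps the first occurrence in input order.
* Empty inputs produce all five output files with headers and a zero-count
  report, not an error; a blank SMILES cell becomes a `failed_parsing` row.
* Output files contain no timestamps and are byte-identical across reruns.
* In-process Open Babel string conversions are validated byte-wise and
  recomputed through the command-line converter on any anomaly.

## Known limitations

* Tautomer canonicalization is rule-based, not energy-based: only motifs in
  the library are normalized, and the canonical form is the conventional
  one, not necessarily the dominant solution-phase species.
* The consistency ranking of structures against external identifiers
  (names, registry numbers) is out of scope.
* Aromaticity perception is limited to 5–7-membered rings.
* The crossed-bond flag over-marks symmetric double bonds (see above).
* MMFF94/UFF geometries are local minima from a deterministic start, not
  global conformer searches.
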