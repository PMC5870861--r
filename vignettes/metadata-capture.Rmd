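---
title: "Capturing instrument metadata from mzML, imzML and nmrML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capturing instrument metadata from mzML, imzML and nmrML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spec2isa)
```

## What the package computes

Open mass-spectrometry and NMR data formats carry their acquisition
metadata as *controlled-vocabulary parameters*: XML elements that point at a
term in the PSI-MS, imagingMS or NMR ontology by accession, optionally with
a value and a unit. spec2isa turns a directory of such files into (a) a
per-file metadata record, (b) a merged study-level dataset and (c) an
ISA-Tab tree whose assay columns are pre-populated — the parts of a
repository submission that a machine can fill reliably. Everything the XML
cannot know (study design, sample characteristics, chromatography) is left
as empty, declared cells for manual completion, or supplied through the
user's study descriptor.

## The extraction model

Extraction is rule-driven. A rule is one row of a tibble and states:

* **where** a match counts: `xml_scope`, a slash-joined element-path
  fragment such as `instrumentConfiguration` or
  `fileDescription/fileContent`. A vocabulary term planted outside its
  rule's scope is never extracted — decoy-planting tests pin this.
* **what** to match: either one exact accession, or any term whose `is_a`
  chain reaches a subtree root (`descendant` mode). Descendance is
  *reflexive* — a root matches its own rule — so "anything under mass
  analyzer type" uniformly includes the root itself. Traversal keeps a
  visited set, so a (malformed) cyclic vocabulary terminates and is flagged
  at load time rather than looping.
* **how many** values to keep: `single`/`first` rules take the first match
  in document order and warn about extras; `multi`/`all` rules keep
  document order (two mass analyzers in one configuration are both kept,
  serialized as a JSON array and as a `;`-joined ISA cell).

Three rule sources beyond plain cvParams exist because the formats store
some facts structurally:

* **attribute** rules read XML attributes (software `version`,
  nmrML's `numberOfScans`, a source file's `name`);
* **value-element** rules read nmrML's value-bearing elements
  (`<fieldStrength value="9.4" unitName="tesla" .../>`), keeping the unit
  term verbatim — no tesla↔MHz conversion is attempted, since that would
  need nucleus-specific constants the file does not state;
* **summary** rules aggregate per-spectrum facts of MS files (below).

The default rulesets pin **23** terms for mzML, **42** for imzML and **46**
for nmrML. The counts are fixed contract; the membership was chosen from the
descriptors the formats reliably carry — generic instrument descriptors
(model, manufacturer, serial number, software), data-transformation
descriptors (conversion, processing actions, compression), file-level
descriptors (formats, checksums, contacts) and platform-specific blocks
(component list and scan summaries for MS; imaging geometry for imzML;
acquisition and processing parameter sets for NMR). The sets are plain
tibbles, so a deployment can extend or replace them per call.

### Dereferencing and precedence

mzML declares reusable parameter bundles (`referenceableParamGroup`) that
instrument configurations reference. Before matching, every reference is
expanded in place: group parameters are inserted ahead of locally declared
ones, and a local parameter with the same accession overrides the group
value (the local value is the more specific statement). A reference to an
undeclared group is an error naming the group id. The fixture generator
always routes the instrument model through a parameter group so this path
is exercised by every round-trip test.

### Derived and summary terms

The instrument *manufacturer* is rarely a cvParam. The PSI-MS vocabulary
organizes instrument models into vendor subtrees, so the manufacturer is
derived as the ancestor of the model term that is a direct child of the
instrument-model root. A breadth-first-search oracle over the raw `is_a`
edges confirms the derivation for every bundled model.

Per-spectrum facts are folded into four file-level keys: `scan_count`
(element count wins over a mismatching declared count, with a warning),
`scan_polarity` (uniform polarity keeps its term; files mixing positive and
negative scans get the literal `alternating scan`, since one assay cell
must summarize the file), `mz_range` (minimum over scan-window lower limits
to maximum over upper limits, rendered `L-U` with trailing zeros stripped)
and `spectrum_representation` (profile/centroid; both kept when mixed).
A missing spectrum list degrades to a warning, never an error.

### Technology detection

Detection uses document content, not file names: an `nmrML` root is NMR;
an `mzML` root (optionally wrapped in `indexedmzML`, which is unwrapped and
whose index is ignored) is imaging MS when any `IMS:` accession occurs,
plain MS otherwise. imzML shares the mzML root element, so root-only
detection cannot separate the two — the accession scan is the discriminator.
The dedicated extractors guard the boundary: feeding an mzML file to the
NMR extractor raises an error naming the detected format, never a silent
partial result. Accessions that do not resolve in the loaded vocabularies
produce a warning and keep the file-supplied name; obsolete terms resolve
but are flagged, because real files reference them. Namespace-mismatched
lookups (imzML mixes `MS:` and `IMS:` accessions in one file) return
not-found with a logged warning rather than aborting extraction.

## The metadata model and JSON export

Missing metadata is represented by *key absence*, never empty strings —
"not present in the file" is distinct from "present but empty". The
canonical JSON export is written by a purpose-built serializer because
byte-level determinism is part of its contract (two exports of the same
record are identical byte sequences, which makes diffs and caching
meaningful); an independent JSON parser is used in tests to confirm
structural round-tripping. The shape is documented by a JSON Schema under
`inst/schema/`. Dates in the study descriptor are accepted only as
ISO-8601 and copied verbatim.

## ISA-Tab assembly, serialization and validation

One study row and one assay row per input file; sample names default to
the file basename without extension, with one source per sample (the
minimal valid linkage). Vocabulary-resolved single values emit the
annotation triple; a multi-valued cell stays a `;`-joined value without a
triple, since ISA-Tab's triple pattern carries exactly one accession per
cell. Values with units render as `value unit-label` in the cell — the
unit's accession is preserved in the JSON export; the Unit column
quadruple of full ISA-Tab was deliberately left out to keep the assay
dialect minimal. Extracted columns attach to the instrument-analysis
protocol (Mass spectrometry / NMR spectroscopy) or the Data transformation
protocol; a default protocol chain (including Chromatography for MS and
NMR sample handling for NMR) is declared so the stub is completable in
standard ISA editors, because chromatography and wet-lab metadata are not
available in the XML and must come from the user. User-supplied extra
parameters become additional study-wide columns.

Serialization is pinned: UTF-8 without BOM, LF line endings, cells
containing tab, quote or newline wrapped in double quotes with internal
quotes doubled. The writer/reader pair is hand-rolled because ISA-Tab
headers repeat column names (`Term Source REF` appears once per annotated
column), which column-unique table readers mangle. Write–read–write is a
fixpoint and identical datasets yield byte-identical trees; both are
asserted in tests.

The validator is self-contained and structural: the three file types exist
and parse; every used Term Source REF is declared; every assay sample name
resolves in a study file; annotation triples are complete; every
`Parameter Value[...]` column is declared by a protocol; every row is
rectangular. Findings carry machine-readable codes (e.g.
`unresolved-sample-name`), and a catalog of deliberate corruptions in the
test suite checks that each class of damage is detected. Output is designed
to also satisfy the external reference validator, but no external tool is
invoked.

## The synthetic fixture generator

The generator emulates batches of converted instrument output: files with
a realistic spread of optional metadata (each injectable key present with
probability 0.7 by default), 1–4 spectra per MS file with random scan
windows, occasional mixed-polarity files (20% of multi-spectrum files),
and both plain and `indexedmzML` framing. Every generated value is recorded
in a manifest, and the repository's central oracle is exactness: extraction
over a corpus must recover the manifest with no extras and no omissions.
A fixture spec fully determines the output bytes, so corpora are
reproducible from a single seed.

What the fixtures do *not* emulate: vendor-specific quirks, XSD-level
schema validity, real spectral payloads (binary arrays are dummy base64 and
are never decoded, matching the extractor's contract), userParam usage, and
the long tail of unusual cvParam placements found in the wild. Passing the
round-trip suite therefore demonstrates that the extraction machinery is
correct against the formats' documented structure, not that every
historical file will yield every term; on real data, absent or
unconventional parameters simply leave their columns empty.

nmrML has no referenceable parameter groups (they are an mzML-lineage
feature), so NMR fixtures exercise every rule source except group
dereferencing; the acquisition/processing layout used is a plausible
rendering of the nmrML lineage, shared by generator and extractor and
checked end-to-end by the round-trip oracle.

## Numerical and policy choices

* Scan-range endpoints are printed in fixed notation with up to six
  decimals and trailing zeros stripped, so `50` not `50.0`, `50.25`
  unchanged.
* Multiple `instrumentConfiguration` elements: the first is used and the
  ignored ids are listed in a warning — assay rows are single-instrument
  and the formats do not say which configuration produced a file.
* Corrupt files in a batch are skipped with a warning; a run fails only
  when every file fails. Batch submissions should not abort on one bad
  conversion.
* A directory mixing mzML and imzML is refused: one assay cannot span two
  technologies, and silently splitting would surprise the submitter.
* Valueless class-style cvParams (e.g. a detector type) use their label as
  the value, following mzML convention.
* Problem sizes in the test suite: hierarchy queries are cross-checked on
  a 50-term random DAG (all 2500 ordered pairs) against a brute-force BFS
  oracle; round-trip corpora use 20 files per technology; end-to-end
  validation corpora use 50 files per technology, a realistic batch size
  for one study.

## Known limitations

* The bundled OBO files are reduced subsets sized for testing; production
  use should point `ontology_paths` at the full vocabularies. The NMR
  subset uses synthetic placeholder accessions in the vocabulary's id
  style.
* Only `is_a` hierarchy is honored; other OBO relationships, synonyms and
  xrefs are ignored (no rule needs them).
* One assay per technology run: no splitting by polarity or fraction.
* No ISA-JSON, no repository submission transport, no GUI — the package
  ends at a validated ISA-Tab tree and JSON exports.
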