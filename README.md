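# spec2isa

Automated instrument-metadata capture from mzML, imzML and nmrML files into
ISA-Tab metadata stubs and canonical JSON.

## The problem

Metabolomics repositories such as MetaboLights require submissions in
ISA-Tab — three linked tab-delimited file types (**I**nvestigation,
**S**tudy, **A**ssay) describing a project, its samples and its
measurements. Filling the assay-level instrument fields by hand (instrument
model, ion source, mass analyzer, detector, conversion software, scan
ranges, acquisition nuclei, pulse sequences, ...) is slow and error-prone,
yet almost all of that information is already present in the open XML data
formats as controlled-vocabulary parameters:

```xml
<cvParam cvRef="MS" accession="MS:1000449" name="LTQ Orbitrap" value=""/>
```

spec2isa reads directories of mzML / imzML (mass spectrometry) or nmrML
(NMR) files, resolves each `cvParam` accession against the PSI-MS, imagingMS
or NMR controlled vocabulary (OBO format), and assembles a structurally
validated ISA-Tab tree with the instrument fields pre-populated — an "assay
stub" that only needs the experimental-design fields completed. Per-file
metadata can also be exported as canonical JSON for other pipelines.

## The method

* **Vocabulary registry** — an OBO loader plus hierarchy queries. A rule
  can match a term *exactly* (e.g. `MS:1000529`, instrument serial number)
  or any *descendant* of a subtree root via `is_a` edges (e.g. anything
  under `MS:1000443`, mass analyzer type). The descendant relation is
  reflexive and cycle-safe.
* **Extraction rulesets** — fixed tables of rules pinning **23** terms for
  mzML, **42** for imzML (the 23 mzML terms plus 19 imaging terms in the
  IMS namespace) and **46** for nmrML. Each rule says where in the document
  a match counts (scope), what to match, and which Assay column it fills.
  `referenceableParamGroup` indirection is expanded before matching, with
  local parameters overriding group ones.
* **Derived and summary terms** — the instrument manufacturer is derived as
  the vendor-family ancestor of the instrument-model term; per-spectrum
  facts are aggregated into file-level scan count, polarity (the literal
  `alternating scan` for mixed files), m/z range and spectrum
  representation.
* **ISA-Tab assembly and validation** — one study and assay row per file,
  ontology-annotation triples (value / Term Source REF / Term Accession
  Number) for vocabulary-resolved values, a default protocol chain, and a
  self-contained structural validator (sample-name linkage, declared term
  sources, declared parameter columns, rectangular tables).
* **Synthetic fixtures** — a deterministic generator writes
  schema-plausible files of all three formats with a ground-truth manifest
  of every injected value; extraction must recover the manifest exactly.

## Worked example

```r
library(spec2isa)

# three synthetic mzML files stand in for instrument output
corpus <- generate_corpus(3, "mzML", seed = 42, out_dir = "demo_in")

run <- run_ms("demo_in", "demo_out", study_identifier = "MTBLS9001",
              verbose = TRUE)
#> INFO: fixture_001.mzML: 13 term(s) captured
#> INFO: fixture_002.mzML: 15 term(s) captured
#> INFO: fixture_003.mzML: 19 term(s) captured
#> INFO: wrote 6 output file(s) to demo_out

glance(run$dataset)
#> # A tibble: 1 × 5
#>   study_identifier technology n_files n_columns n_warnings
#>   <chr>            <chr>        <int>     <int>      <int>
#> 1 MTBLS9001        mzML             3        22          0

validate_isatab("demo_out")
#> <isatab_validation> PASSED: 0 finding(s)

tidy(run$dataset$files[[1]])[, c("term_key", "value", "term_accession")]
#> # A tibble: 13 × 3
#>    term_key                  value                  term_accession
#>  1 customization             modified ion funnel    "MS:1000032"
#>  2 mass_analyzer             quadrupole             "MS:1000081"
#>  3 detector                  inductive detector     "MS:1000624"
#>  ...
#> 11 scan_polarity             positive scan          "MS:1000130"
#> 12 mz_range                  50.6-1715              ""
#> 13 scan_count                4                      ""
```

`demo_out/` now holds `i_Investigation.txt`, `s_MTBLS9001.txt`,
`a_MTBLS9001_metabolite_profiling_mass_spectrometry.txt` and one canonical
JSON document per input file: each captured term lists its value, resolved
accession, unit and XML provenance. The numbers above mean: 22 distinct
metadata columns were captured across the corpus, each file contributed the
subset actually present in its XML, and the resulting tree passes every
structural check of the built-in validator.

NMR batches work identically through `run_nmr()`. Thin command-line
wrappers ship under `inst/cli/` (`ms2isatab.R`, `nmr2isatab.R`).

## Package layout

* `R/` — vocabulary registry, rulesets, extractors, metadata model,
  ISA-Tab builder/writer/validator, fixture generator, pipeline runners.
* `inst/extdata/` — bundled OBO subsets of the PSI-MS, imagingMS and NMR
  vocabularies (test-sized; full vocabularies can be supplied via
  `ontology_paths` / `--ontology`).
* `inst/schema/` — JSON Schema for the canonical per-file export.
* `vignettes/metadata-capture.Rmd` — the methods vignette: model,
  parameters, design decisions, limitations.
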