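test_that("the default nmrML ruleset pins 46 distinct terms and resolves", {
  rs <- default_nmrml_ruleset()
  expect_equal(nrow(rs), 46)
  expect_equal(length(unique(rs$term_key)), 46)
  regs <- default_registries("nmrML")
  for (acc in stats::na.omit(rs$cv_target)) {
    expect_false(is.null(spec2isa:::registries_resolve(regs, acc)),
                 label = paste("cv_target resolves:", acc))
  }
})

test_that("numeric acquisition parameters carry their units", {
  spec <- fixture_spec("nmrML", injected = c(
    magnetic_field_strength = "9.4", acquisition_nucleus = "1H"),
    n_spectra = 0, seed = 2)
  fm <- extract_file_metadata(generate_file(spec, tempfile())$path)
  b <- fm$entries[fm$entries$term_key == "magnetic_field_strength", ]
  expect_identical(b$value, "9.4")
  expect_identical(b$unit_label, "tesla")
  expect_identical(b$unit_accession, "UO:0000228")
  nuc <- fm$entries[fm$entries$term_key == "acquisition_nucleus", ]
  expect_identical(nuc$term_accession, "NMR:1400152")
})

test_that("a minimal acquisition-only fixture yields only acquisition keys", {
  spec <- fixture_spec("nmrML", injected = c(
    number_of_scans = "64", sweep_width = "12019.23", solvent = "deuterium oxide"),
    n_spectra = 0, seed = 3)
  fm <- extract_file_metadata(generate_file(spec, tempfile())$path)
  expect_setequal(unique(fm$entries$term_key),
                  c("number_of_scans", "sweep_width", "solvent"))
  expect_identical(fm$technology, "nmrML")
})

test_that("randomized nmrML fixtures round-trip exactly", {
  cm <- generate_corpus(20, "nmrML", seed = 23, decoys = TRUE)
  files <- lapply(cm$files, extract_file_metadata)
  expect_manifest_equal(cm$manifest, files)
})

test_that("the technology guard distinguishes mzML from unknown XML", {
  ms <- generate_file(fixture_spec("mzML", seed = 4), tempfile())$path
  expect_error(extract_nmrml_metadata(ms), "looks like mzML",
               class = "spec2isa_extraction_error")
  nmr <- generate_file(fixture_spec("nmrML", seed = 4), tempfile())$path
  expect_error(extract_mzml_metadata(nmr), "nmrML root",
               class = "spec2isa_extraction_error")
})
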