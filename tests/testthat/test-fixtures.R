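test_that("a fixture spec fully determines the output bytes", {
  for (tech in c("mzML", "imzML", "nmrML")) {
    s <- fixture_spec(tech, seed = 6)
    p1 <- generate_file(s, tempfile())$path
    p2 <- generate_file(s, tempfile())$path
    expect_identical(readLines(p1), readLines(p2), label = tech)
  }
})

test_that("corpora are deterministic under a fixed seed", {
  c1 <- generate_corpus(6, "mzML", seed = 99)
  c2 <- generate_corpus(6, "mzML", seed = 99)
  expect_identical(c1$manifest, c2$manifest)
  for (i in seq_along(c1$files)) {
    expect_identical(readLines(c1$files[i]), readLines(c2$files[i]))
  }
  c3 <- generate_corpus(6, "mzML", seed = 100)
  expect_false(identical(c1$manifest, c3$manifest))
})

test_that("the instrument model travels through a referenceable param group", {
  s <- fixture_spec("mzML", injected = c(instrument_model = "micrOTOF-Q"),
                    n_spectra = 1, seed = 2)
  r <- generate_file(s, tempfile())
  txt <- paste(readLines(r$path), collapse = "\n")
  expect_match(txt, "referenceableParamGroupRef")
  fm <- extract_file_metadata(r$path)
  expect_identical(fm$entries$value[fm$entries$term_key == "instrument_model"],
                   "micrOTOF-Q")
})

test_that("uninjectable keys and unknown labels are spec errors", {
  expect_error(fixture_spec("mzML", injected = c(pixel_size_x = "25")),
               "not injectable", class = "spec2isa_spec_error")
  expect_error(fixture_spec("mzML", injected = c(instrument_model = "Tricorder")),
               class = "spec2isa_spec_error")
})

test_that("generated files parse as XML and declare the right technology", {
  for (tech in c("mzML", "imzML", "nmrML")) {
    r <- generate_file(fixture_spec(tech, seed = 8), tempfile())
    v <- read_xml_view(r$path)
    expect_identical(v$technology, tech)
  }
})

test_that("manifest covers exactly the generated files", {
  cm <- generate_corpus(5, "nmrML", seed = 3)
  expect_setequal(unique(cm$manifest$file), basename(cm$files))
  expect_true(all(file.exists(cm$files)))
})
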