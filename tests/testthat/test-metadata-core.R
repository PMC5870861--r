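make_fm <- function(keys_values, source_file = "f.mzML", technology = "mzML",
                    term_keys = default_mzml_ruleset()$term_key) {
  entries <- dplyr::bind_rows(lapply(names(keys_values), function(k) {
    spec2isa:::param_value(k, value = keys_values[[k]],
                           source_file = source_file, xml_path = "x")
  }))
  if (length(keys_values) == 0) entries <- spec2isa:::empty_params()
  spec2isa:::new_file_metadata(source_file, technology, entries, term_keys)
}

test_that("canonical JSON has the full top-level shape even with zero entries", {
  fm <- make_fm(list())
  j <- to_canonical_json(fm)
  p <- jsonlite::fromJSON(j, simplifyVector = FALSE)
  expect_named(p, c("source_file", "technology", "entries", "warnings"))
  expect_length(p$entries, 0)
})

test_that("canonical JSON is byte-deterministic and round-trips structurally", {
  set.seed(3)
  for (i in 1:5) {
    spec <- fixture_spec("mzML", seed = 100 + i)
    r <- generate_file(spec, tempfile())
    fm <- extract_file_metadata(r$path)
    j1 <- to_canonical_json(fm)
    j2 <- to_canonical_json(fm)
    expect_identical(j1, j2)
    p <- jsonlite::fromJSON(j1, simplifyVector = FALSE)   # independent parser
    expect_identical(p$source_file, fm$source_file)
    expect_identical(p$technology, fm$technology)
    # entries keyed in ruleset order, values in document order
    present <- intersect(fm$term_keys, unique(fm$entries$term_key))
    expect_identical(names(p$entries), present)
    for (k in present) {
      rows <- fm$entries[fm$entries$term_key == k, ]
      expect_length(p$entries[[k]], nrow(rows))
      for (j in seq_len(nrow(rows))) {
        o <- p$entries[[k]][[j]]
        expect_identical(o$value, rows$value[j])
        expect_identical(o$term_accession, rows$term_accession[j])
        expect_identical(o$unit_label, rows$unit_label[j])
      }
    }
  }
})

test_that("JSON string escaping survives an independent parse", {
  fm <- make_fm(list(customization = "tab\there \"quoted\" back\\slash\nnewline"))
  p <- jsonlite::fromJSON(to_canonical_json(fm), simplifyVector = FALSE)
  expect_identical(p$entries$customization[[1]]$value,
                   "tab\there \"quoted\" back\\slash\nnewline")
})

test_that("merging a singleton corpus keeps exactly its keys", {
  fm <- make_fm(list(instrument_model = "LTQ Orbitrap", scan_count = "3"))
  ds <- merge_corpus(list(fm), study_descriptor("MTBLS1"))
  expect_length(ds$files, 1)
  expect_identical(ds$column_union, c("instrument_model", "scan_count"))
})

test_that("column union is ruleset-ordered and independent of file order", {
  f1 <- make_fm(list(detector = "electron multiplier"), source_file = "a.mzML")
  f2 <- make_fm(list(instrument_model = "Q Exactive"), source_file = "b.mzML")
  d1 <- merge_corpus(list(f1, f2), study_descriptor("S"))
  d2 <- merge_corpus(list(f2, f1), study_descriptor("S"))
  # ruleset order: instrument_model precedes detector regardless of input order
  expect_identical(d1$column_union, c("instrument_model", "detector"))
  expect_identical(d1$column_union, d2$column_union)
  expect_identical(vapply(d2$files, `[[`, "", "source_file"), c("b.mzML", "a.mzML"))
})

test_that("merge preserves file cardinality and order over a generated corpus", {
  cm <- generate_corpus(12, "mzML", seed = 5)
  files <- lapply(cm$files, extract_file_metadata)
  ds <- merge_corpus(files, study_descriptor("S"))
  expect_length(ds$files, 12)
  expect_identical(vapply(ds$files, `[[`, "", "source_file"), basename(cm$files))
  # populated iff injected, per file and key
  for (i in seq_along(files)) {
    injected <- cm$manifest$term_key[cm$manifest$file == basename(cm$files[i])]
    expect_setequal(unique(files[[i]]$entries$term_key), injected)
  }
})

test_that("merge refuses empty and mixed-technology corpora", {
  expect_error(merge_corpus(list(), study_descriptor("S")), "no input files",
               class = "spec2isa_merge_error")
  f1 <- make_fm(list(scan_count = "1"), technology = "mzML")
  f2 <- make_fm(list(scan_count = "1"), technology = "imzML",
                term_keys = default_imzml_ruleset()$term_key)
  expect_error(merge_corpus(list(f1, f2), study_descriptor("S")),
               "mzML.*imzML|imzML.*mzML", class = "spec2isa_merge_error")
})

test_that("descriptor extras add columns absent from all files", {
  fm <- make_fm(list(instrument_model = "LTQ Orbitrap"))
  ds <- merge_corpus(list(fm), study_descriptor(
    "S", extra_parameters = c(chromatography_column = "HSS T3 2.1x100 mm")))
  expect_identical(ds$column_union, c("instrument_model", "chromatography_column"))
})

test_that("study descriptors enforce identifier and ISO-8601 dates", {
  expect_error(study_descriptor(""), class = "spec2isa_descriptor_error")
  expect_error(study_descriptor("S", submission_date = "01/02/2020"),
               class = "spec2isa_descriptor_error")
  d <- study_descriptor("S", submission_date = "2020-02-01")
  expect_identical(d$submission_date, "2020-02-01")
})

test_that("study descriptors round-trip through the JSON user-metadata document", {
  path <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    study_identifier = "MTBLS42", title = "demo study",
    contacts = data.frame(last_name = "Doe", first_name = "J",
                          email = "d@e.org", affiliation = "Uni", role = "PI"),
    extra_parameters = list(chromatography_column = "C18")
  ), auto_unbox = TRUE), path)
  d <- read_study_descriptor(path)
  expect_identical(d$study_identifier, "MTBLS42")
  expect_equal(nrow(d$contacts), 1)
  expect_identical(d$extra_parameters$chromatography_column, "C18")
})
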