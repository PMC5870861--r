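build_demo <- function(n = 3, tech = "mzML", seed = 31, id = "MTBLSDEMO") {
  cm <- generate_corpus(n, tech, seed = seed)
  files <- lapply(cm$files, extract_file_metadata)
  ds <- merge_corpus(files, study_descriptor(id, title = "demo"))
  list(cm = cm, files = files, ds = ds, doc = build_isatab(ds))
}

test_that("a minimal dataset builds one study row and one assay row", {
  spec <- fixture_spec("mzML", injected = c(instrument_model = "LTQ Orbitrap"),
                       n_spectra = 1, seed = 1)
  fm <- extract_file_metadata(generate_file(spec, tempfile())$path)
  ds <- merge_corpus(list(fm), study_descriptor("MTBLS1"))
  doc <- build_isatab(ds)
  expect_length(doc$study_table$rows, 1)
  expect_length(doc$assay_table$rows, 1)
  inv <- spec2isa:::inv_row(spec2isa:::inv_section(doc$investigation, "STUDY"),
                            "Study Identifier")
  expect_identical(inv, "MTBLS1")
})

test_that("assay header has one Parameter Value column per captured key", {
  d <- build_demo(n = 4, seed = 8)
  pv <- grepl("^Parameter Value\\[", d$doc$assay_table$header)
  expect_equal(sum(pv), length(d$ds$column_union))
})

test_that("assay cells equal the injected values, empty elsewhere", {
  d <- build_demo(n = 10, seed = 12)
  hdr <- d$doc$assay_table$header
  rules <- default_mzml_ruleset()
  catalog <- spec2isa:::fixture_catalog("mzML")
  sample_col <- which(hdr == "Sample Name")[1]
  for (i in seq_along(d$files)) {
    row <- d$doc$assay_table$rows[[i]]
    fname <- d$files[[i]]$source_file
    man <- d$cm$manifest[d$cm$manifest$file == fname, ]
    for (k in d$ds$column_union) {
      lab <- rules$isa_field[rules$term_key == k]
      col <- which(hdr == paste0("Parameter Value[", lab, "]"))
      vals <- man$value[man$term_key == k]
      cell <- row[col]
      if (length(vals) == 0) {
        expect_identical(cell, "", label = paste(fname, k, "is empty"))
      } else {
        # units render appended to the value in the cell
        entry <- d$files[[i]]$entries[d$files[[i]]$entries$term_key == k, ]
        shown <- ifelse(nzchar(entry$unit_label),
                        paste(entry$value, entry$unit_label), entry$value)
        expect_identical(cell, paste(shown, collapse = ";"),
                         label = paste(fname, k, "cell"))
      }
    }
  }
})

test_that("writing produces exactly the three named files", {
  d <- build_demo(n = 2, seed = 21, id = "MTBLSW")
  out <- tempfile()
  paths <- write_isatab(d$doc, out)
  expect_setequal(basename(unname(paths)),
                  c("i_Investigation.txt", "s_MTBLSW.txt",
                    "a_MTBLSW_metabolite_profiling_mass_spectrometry.txt"))
  expect_true(all(file.exists(paths)))
})

test_that("cells containing tabs, quotes and newlines round-trip the dialect", {
  tbl <- list(header = c("Sample Name", "Note"),
              rows = list(c("s1", "a\tb \"quoted\"\nmultiline")))
  path <- tempfile()
  spec2isa:::write_isatab_table(tbl, path)
  back <- spec2isa:::read_isatab_table(path)
  expect_identical(back$rows[[1]][2], "a\tb \"quoted\"\nmultiline")
})

test_that("serialization is a fixpoint and byte-deterministic", {
  d <- build_demo(n = 5, seed = 33)
  out1 <- tempfile(); write_isatab(d$doc, out1)
  out2 <- tempfile(); spec2isa:::isatab_rewrite(out1, out2)
  for (f in list.files(out1)) {
    expect_identical(readBin(file.path(out1, f), "raw", file.size(file.path(out1, f))),
                     readBin(file.path(out2, f), "raw", file.size(file.path(out2, f))),
                     label = paste("fixpoint:", f))
  }
  # identical dataset -> byte-identical tree
  d2 <- build_demo(n = 5, seed = 33)
  out3 <- tempfile(); write_isatab(d2$doc, out3)
  for (f in list.files(out1)) {
    expect_identical(readBin(file.path(out1, f), "raw", file.size(file.path(out1, f))),
                     readBin(file.path(out3, f), "raw", file.size(file.path(out3, f))),
                     label = paste("determinism:", f))
  }
  # LF endings, no BOM
  raw <- readBin(file.path(out1, "i_Investigation.txt"), "raw", 3)
  expect_false(identical(raw, as.raw(c(0xef, 0xbb, 0xbf))))
  txt <- readChar(file.path(out1, "i_Investigation.txt"),
                  file.size(file.path(out1, "i_Investigation.txt")))
  expect_false(grepl("\r", txt))
})

test_that("the pipeline output validates cleanly for both technologies", {
  for (tech in c("mzML", "nmrML")) {
    d <- build_demo(n = 5, tech = tech, seed = 44, id = paste0("MTBLS", tech))
    out <- tempfile()
    write_isatab(d$doc, out)
    v <- validate_isatab(out)
    expect_true(v$passed, label = paste(tech, "validation"))
    expect_equal(nrow(tidy(v)), 0)
  }
})

mutate_file <- function(dir, fname, fn) {
  p <- file.path(dir, fname)
  lines <- readLines(p, warn = FALSE)
  writeLines(fn(lines), p, sep = "\n")
}

test_that("every structural corruption in the mutation catalog is detected", {
  d <- build_demo(n = 4, seed = 55, id = "MTBLSMUT")
  assay <- "a_MTBLSMUT_metabolite_profiling_mass_spectrometry.txt"
  fresh <- function() { out <- tempfile(); write_isatab(d$doc, out); out }

  # 1. mangled assay sample name orphans the row
  out <- fresh()
  mutate_file(out, assay, function(l) { l[2] <- sub("^[^\t]*", "GHOST", l[2]); l })
  v <- validate_isatab(out)
  expect_false(v$passed)
  expect_true("unresolved-sample-name" %in% v$findings$code)

  # 2. stripping the declared ontology sources leaves used Term Source REFs dangling
  out <- fresh()
  mutate_file(out, "i_Investigation.txt", function(l) {
    ifelse(grepl("^Term Source Name", l), "Term Source Name\t", l)
  })
  v <- validate_isatab(out)
  expect_false(v$passed)
  expect_true("undeclared-term-source" %in% v$findings$code)

  # 3. dropping the protocol parameter declarations orphans the columns
  out <- fresh()
  mutate_file(out, "i_Investigation.txt", function(l) {
    l[!grepl("^Study Protocol Parameters Name", l)]
  })
  v <- validate_isatab(out)
  expect_false(v$passed)
  expect_true("undeclared-parameter" %in% v$findings$code)

  # 4. dropping a trailing cell makes the row ragged
  out <- fresh()
  mutate_file(out, assay, function(l) { l[2] <- sub("\t[^\t]*$", "", l[2]); l })
  v <- validate_isatab(out)
  expect_false(v$passed)
  expect_true("ragged-row" %in% v$findings$code)

  # 5. a missing study file is reported, not crashed on
  out <- fresh()
  file.remove(file.path(out, "s_MTBLSMUT.txt"))
  v <- validate_isatab(out)
  expect_false(v$passed)
  expect_true(all(c("missing-study-file", "missing-declared-file") %in% v$findings$code))
})

test_that("validating a dataset with zero files is refused at build time", {
  fm <- extract_file_metadata(
    generate_file(fixture_spec("mzML", seed = 1), tempfile())$path)
  ds <- merge_corpus(list(fm), study_descriptor("S"))
  ds$files <- list()
  expect_error(build_isatab(ds), class = "spec2isa_isatab_error")
})
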