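test_that("default MS rulesets pin the term counts and resolve their targets", {
  ms <- default_mzml_ruleset()
  im <- default_imzml_ruleset()
  expect_equal(length(unique(ms$term_key)), 23)
  expect_equal(length(unique(im$term_key)), 42)
  expect_true(all(ms$term_key %in% im$term_key))
  regs <- default_registries("imzML")
  for (acc in stats::na.omit(im$cv_target)) {
    expect_false(is.null(spec2isa:::registries_resolve(regs, acc)),
                 label = paste("cv_target resolves:", acc))
  }
})

mini_mzml <- function(body, wrap = TRUE) {
  path <- tempfile(fileext = ".mzML")
  txt <- if (wrap) c('<?xml version="1.0"?>',
                     '<mzML xmlns="http://psi.hupo.org/ms/mzml">',
                     body, '</mzML>') else body
  writeLines(txt, path)
  path
}

test_that("param-group dereferencing expands references with local precedence", {
  # no references: identity
  v0 <- read_xml_view(mini_mzml(
    '<instrumentConfigurationList><instrumentConfiguration id="IC1">
       <cvParam cvRef="MS" accession="MS:1000449" name="LTQ Orbitrap" value=""/>
     </instrumentConfiguration></instrumentConfigurationList>'))
  d0 <- dereference_param_groups(v0)
  expect_identical(d0$params, v0$params)

  # group expansion reaches the referencing configuration
  v1 <- read_xml_view(mini_mzml('
    <referenceableParamGroupList>
      <referenceableParamGroup id="G">
        <cvParam cvRef="MS" accession="MS:1000449" name="LTQ Orbitrap" value=""/>
      </referenceableParamGroup>
    </referenceableParamGroupList>
    <instrumentConfigurationList><instrumentConfiguration id="IC1">
      <referenceableParamGroupRef ref="G"/>
    </instrumentConfiguration></instrumentConfigurationList>'))
  d1 <- dereference_param_groups(v1)
  hit <- d1$params[d1$params$accession == "MS:1000449", ]
  expect_equal(nrow(hit), 1)
  expect_match(hit$parent_norm, "instrumentConfiguration$")

  # local param with the same accession overrides the group value
  v2 <- read_xml_view(mini_mzml('
    <referenceableParamGroupList>
      <referenceableParamGroup id="G">
        <cvParam cvRef="MS" accession="MS:1000529" name="instrument serial number" value="group"/>
      </referenceableParamGroup>
    </referenceableParamGroupList>
    <instrumentConfigurationList><instrumentConfiguration id="IC1">
      <referenceableParamGroupRef ref="G"/>
      <cvParam cvRef="MS" accession="MS:1000529" name="instrument serial number" value="local"/>
    </instrumentConfiguration></instrumentConfigurationList>'))
  d2 <- dereference_param_groups(v2)
  hit2 <- d2$params[d2$params$accession == "MS:1000529", ]
  expect_equal(nrow(hit2), 1)
  expect_identical(hit2$value, "local")

  # undeclared group id is an extraction error naming the id
  v3 <- read_xml_view(mini_mzml(
    '<instrumentConfigurationList><instrumentConfiguration id="IC1">
       <referenceableParamGroupRef ref="NOPE"/>
     </instrumentConfiguration></instrumentConfigurationList>'))
  expect_error(dereference_param_groups(v3), "NOPE",
               class = "spec2isa_extraction_error")
})

test_that("fixture round-trip recovers exactly the injected values", {
  spec <- fixture_spec("mzML", injected = c(
    instrument_model = "LTQ Orbitrap", detector = "inductive detector",
    data_file_checksum = "abc123"), n_spectra = 2, seed = 3)
  r <- generate_file(spec, tempfile())
  fm <- extract_file_metadata(r$path)
  im <- fm$entries[fm$entries$term_key == "instrument_model", ]
  expect_identical(im$value, "LTQ Orbitrap")
  expect_identical(im$term_accession, "MS:1000449")
  man <- fm$entries[fm$entries$term_key == "instrument_manufacturer", ]
  expect_identical(man$value, "Thermo Fisher Scientific instrument model")
  expect_identical(
    fm$entries$value[fm$entries$term_key == "data_file_checksum"], "abc123")
  expect_manifest_equal(r$manifest, list(fm))
})

test_that("a minimal file yields only spectra summaries, without error", {
  spec <- fixture_spec("mzML", injected = character(), n_spectra = 1, seed = 1)
  r <- generate_file(spec, tempfile())
  fm <- extract_file_metadata(r$path)
  expect_setequal(unique(fm$entries$term_key),
                  c("scan_count", "scan_polarity", "mz_range",
                    "spectrum_representation"))
})

test_that("randomized fixtures round-trip exactly, including decoy-hardened ones", {
  for (tech in c("mzML", "imzML")) {
    cm <- generate_corpus(20, tech, seed = 17, decoys = TRUE)
    files <- lapply(cm$files, extract_file_metadata)
    expect_manifest_equal(cm$manifest, files)
    expect_true(all(vapply(files, function(f) f$technology, "") == tech))
  }
})

test_that("spectra summaries match hand-computed and brute-force values", {
  spec <- fixture_spec("mzML", injected = character(), n_spectra = 3,
                       polarities = "positive",
                       windows = list(c(100, 1000), c(50, 2000), c(100, 1500)),
                       seed = 2)
  fm <- extract_file_metadata(generate_file(spec, tempfile())$path)
  g <- function(k) fm$entries$value[fm$entries$term_key == k]
  expect_identical(g("scan_polarity"), "positive scan")
  expect_identical(g("mz_range"), "50-2000")
  expect_identical(g("scan_count"), "3")

  spec2 <- fixture_spec("mzML", injected = character(), n_spectra = 2,
                        polarities = c("positive", "negative"), seed = 2)
  fm2 <- extract_file_metadata(generate_file(spec2, tempfile())$path)
  expect_identical(fm2$entries$value[fm2$entries$term_key == "scan_polarity"],
                   "alternating scan")

  # 200 random windows against an in-test brute-force min/max
  set.seed(9)
  wins <- lapply(1:200, function(i) {
    lo <- round(stats::runif(1, 40, 300), 2)
    c(lo, lo + round(stats::runif(1, 100, 1900), 2))
  })
  spec3 <- fixture_spec("mzML", injected = character(), n_spectra = 200,
                        windows = wins, seed = 4)
  fm3 <- extract_file_metadata(generate_file(spec3, tempfile())$path)
  lo <- min(vapply(wins, `[`, 0, 1)); hi <- max(vapply(wins, `[`, 0, 2))
  brute <- paste0(sub("\\.?0+$", "", sprintf("%.6f", lo)), "-",
                  sub("\\.?0+$", "", sprintf("%.6f", hi)))
  expect_identical(fm3$entries$value[fm3$entries$term_key == "mz_range"], brute)
  expect_identical(fm3$entries$value[fm3$entries$term_key == "scan_count"], "200")
})

test_that("manufacturer derivation agrees with a BFS oracle for every model", {
  reg <- default_registries("mzML")[[1]]
  models <- spec2isa:::ms_catalog()$instrument_model$terms
  # oracle: ancestors via BFS; the vendor family is the one that is a direct
  # child of the instrument model root
  parents <- reg$parents
  root_children <- reg$terms$accession[vapply(reg$terms$parent_accessions,
                                              function(p) "MS:1000031" %in% p, FALSE)]
  for (lab in names(models)) {
    anc <- bfs_reach(parents, models[[lab]])
    oracle <- intersect(anc, root_children)
    fam <- spec2isa:::vendor_family(reg, models[[lab]], "MS:1000031")
    expect_identical(fam$accession, oracle)
    spec <- fixture_spec("mzML", injected = c(instrument_model = lab), n_spectra = 1)
    fm <- extract_file_metadata(generate_file(spec, tempfile())$path)
    expect_identical(
      fm$entries$term_accession[fm$entries$term_key == "instrument_manufacturer"],
      oracle)
  }
})

test_that("only the first instrumentConfiguration is used, with a warning", {
  path <- mini_mzml('
    <instrumentConfigurationList>
      <instrumentConfiguration id="IC1">
        <cvParam cvRef="MS" accession="MS:1000449" name="LTQ Orbitrap" value=""/>
      </instrumentConfiguration>
      <instrumentConfiguration id="IC2">
        <cvParam cvRef="MS" accession="MS:1001911" name="Q Exactive" value=""/>
      </instrumentConfiguration>
    </instrumentConfigurationList>')
  fm <- extract_file_metadata(path)
  expect_identical(fm$entries$value[fm$entries$term_key == "instrument_model"],
                   "LTQ Orbitrap")
  expect_match(paste(fm$warnings, collapse = " "), "IC2")
})

test_that("unresolvable accessions warn and keep the file-supplied name", {
  path <- mini_mzml(
    '<instrumentConfigurationList><instrumentConfiguration id="IC1">
       <cvParam cvRef="MS" accession="MS:7777777" name="mystery device" value=""/>
     </instrumentConfiguration></instrumentConfigurationList>')
  rules <- default_mzml_ruleset()
  rules$match_mode[rules$term_key == "instrument_serial_number"] <- "exact"
  rules$cv_target[rules$term_key == "instrument_serial_number"] <- "MS:7777777"
  fm <- extract_file_metadata(path, rules = rules)
  hit <- fm$entries[fm$entries$term_key == "instrument_serial_number", ]
  expect_identical(hit$term_label, "mystery device")
  expect_match(paste(fm$warnings, collapse = " "), "MS:7777777")
})

test_that("non-XML input and unknown roots raise extraction errors", {
  junk <- tempfile(fileext = ".mzML")
  writeLines("this is not xml at all <", junk)
  expect_error(extract_file_metadata(junk), class = "spec2isa_extraction_error")
  other <- tempfile(fileext = ".xml")
  writeLines("<html><body/></html>", other)
  expect_error(extract_file_metadata(other), "unknown XML root",
               class = "spec2isa_extraction_error")
  expect_error(extract_file_metadata(tempfile()), class = "spec2isa_io_error")
})

test_that("indexedmzML wrappers are transparently unwrapped", {
  spec <- fixture_spec("mzML", injected = c(instrument_model = "Q Exactive"),
                       n_spectra = 1, indexed = TRUE, seed = 5)
  fm <- extract_file_metadata(generate_file(spec, tempfile())$path)
  expect_identical(fm$entries$value[fm$entries$term_key == "instrument_model"],
                   "Q Exactive")
})
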