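#' Synthetic data-file fixtures
#'
#' Generates schema-plausible mzML, imzML and nmrML files together with a
#' ground-truth manifest of every metadata value injected, standing in for
#' instrument output so the whole pipeline is testable without downloads.
#' Files aim for structural plausibility (correct root and namespaces,
#' cvParam syntax, a referenceable parameter group exercised for the
#' instrument model) rather than formal XSD validity; binary data arrays
#' hold dummy base64 payloads that are never decoded. A fixture spec fully
#' determines the output bytes.
#'
#' @name fixtures
NULL

# ---- injection catalogs ----------------------------------------------------
# kind "class": valueless cvParam, injected value = a term label
# kind "value": cvParam whose value attribute carries the datum
# kind "attr" / "velem": structural attribute / value element (nmrML, plus
#   the software version and source-file name of the mzML family)

ms_catalog <- function() list(
  instrument_model = list(kind = "class", terms = c(
    "LTQ Orbitrap" = "MS:1000449", "Q Exactive" = "MS:1001911",
    "SYNAPT G2-S" = "MS:1001790", "micrOTOF-Q" = "MS:1001547",
    "TripleTOF 5600" = "MS:1000932")),
  instrument_serial_number = list(kind = "value", acc = "MS:1000529",
    name = "instrument serial number", default = "SN04211A"),
  customization = list(kind = "value", acc = "MS:1000032",
    name = "customization", default = "modified ion funnel"),
  ion_source = list(kind = "class", terms = c(
    "electrospray ionization" = "MS:1000073", "nanoelectrospray" = "MS:1000398",
    "matrix-assisted laser desorption ionization" = "MS:1000075",
    "chemical ionization" = "MS:1000071")),
  mass_analyzer = list(kind = "class", terms = c(
    "orbitrap" = "MS:1000484", "quadrupole" = "MS:1000081",
    "time-of-flight" = "MS:1000084", "ion trap" = "MS:1000264")),
  detector = list(kind = "class", terms = c(
    "electron multiplier" = "MS:1000253", "inductive detector" = "MS:1000624",
    "photomultiplier" = "MS:1000116")),
  software_name = list(kind = "class", terms = c(
    "Xcalibur" = "MS:1000532", "ProteoWizard msconvert" = "MS:1002205",
    "CompassXport" = "MS:1000717")),
  software_version = list(kind = "attr", default = "2.8-202101"),
  file_conversion = list(kind = "class", terms = c(
    "Conversion to mzML" = "MS:1000544", "Conversion to mzXML" = "MS:1000545")),
  data_processing_action = list(kind = "class", terms = c(
    "smoothing" = "MS:1000592", "baseline reduction" = "MS:1000593",
    "deisotoping" = "MS:1000033", "charge deconvolution" = "MS:1000034",
    "low intensity data point removal" = "MS:1000594")),
  binary_compression = list(kind = "class", terms = c(
    "zlib compression" = "MS:1000574", "no compression" = "MS:1000576")),
  raw_data_file_format = list(kind = "class", terms = c(
    "Thermo RAW format" = "MS:1000563", "ABI WIFF format" = "MS:1000562")),
  raw_data_file = list(kind = "attr", default = "sample01.raw"),
  native_spectrum_id_format = list(kind = "class", terms = c(
    "Thermo nativeID format" = "MS:1000768",
    "multiple peak list nativeID format" = "MS:1000774")),
  data_file_checksum = list(kind = "value", acc = "MS:1000568", name = "MD5",
    default = "9a0364b9e99bb480dd25e1f0284c8555"),
  data_file_content = list(kind = "class", terms = c(
    "MS1 spectrum" = "MS:1000579", "MSn spectrum" = "MS:1000580",
    "mass spectrum" = "MS:1000294")),
  contact_name = list(kind = "value", acc = "MS:1000586", name = "contact name",
    default = "Jane Doe"),
  contact_organization = list(kind = "value", acc = "MS:1000590",
    name = "contact affiliation", default = "Example University")
)

ims_catalog <- function() list(
  ibd_identifier = list(kind = "value", acc = "IMS:1000080",
    name = "universally unique identifier",
    default = "{9D3BDE1C-55E9-4B34-8E0C-2E4F6A3B0D11}"),
  ibd_checksum = list(kind = "value", acc = "IMS:1000090", name = "ibd MD5",
    default = "f5dc6df2a96b0bd8a5e1a7fd7c6f8e31"),
  ibd_binary_type = list(kind = "class", terms = c(
    "continuous" = "IMS:1000030", "processed" = "IMS:1000031")),
  scan_direction = list(kind = "class", terms = c(
    "top down" = "IMS:1000401", "bottom up" = "IMS:1000402",
    "left right" = "IMS:1000403", "right left" = "IMS:1000404")),
  scan_pattern = list(kind = "class", terms = c(
    "meandering" = "IMS:1000410", "flyback" = "IMS:1000413")),
  scan_type = list(kind = "class", terms = c(
    "horizontal line scan" = "IMS:1000480", "vertical line scan" = "IMS:1000481")),
  line_scan_direction = list(kind = "class", terms = c(
    "linescan left right" = "IMS:1000491", "linescan right left" = "IMS:1000490",
    "linescan bottom up" = "IMS:1000492", "linescan top down" = "IMS:1000493")),
  max_count_pixels_x = list(kind = "value", acc = "IMS:1000042",
    name = "max count of pixels x", default = "200"),
  max_count_pixels_y = list(kind = "value", acc = "IMS:1000043",
    name = "max count of pixels y", default = "120"),
  max_dimension_x = list(kind = "value", acc = "IMS:1000044",
    name = "max dimension x", default = "5000",
    unit = c("UO:0000017", "micrometer")),
  max_dimension_y = list(kind = "value", acc = "IMS:1000045",
    name = "max dimension y", default = "3000",
    unit = c("UO:0000017", "micrometer")),
  pixel_size_x = list(kind = "value", acc = "IMS:1000046",
    name = "pixel size x", default = "25", unit = c("UO:0000017", "micrometer")),
  pixel_size_y = list(kind = "value", acc = "IMS:1000047",
    name = "pixel size y", default = "25", unit = c("UO:0000017", "micrometer")),
  absolute_position_offset_x = list(kind = "value", acc = "IMS:1000053",
    name = "absolute position offset x", default = "0",
    unit = c("UO:0000017", "micrometer")),
  absolute_position_offset_y = list(kind = "value", acc = "IMS:1000054",
    name = "absolute position offset y", default = "0",
    unit = c("UO:0000017", "micrometer")),
  target_material = list(kind = "value", acc = "IMS:1000202",
    name = "target material", default = "ITO coated glass"),
  spatial_resolution = list(kind = "value", acc = "IMS:1000802",
    name = "spatial resolution", default = "50",
    unit = c("UO:0000017", "micrometer")),
  position_accuracy = list(kind = "value", acc = "IMS:1000806",
    name = "position accuracy", default = "1",
    unit = c("UO:0000017", "micrometer")),
  matrix_solution = list(kind = "value", acc = "IMS:1000835",
    name = "matrix solution", default = "10 mg/mL DHB in 50% ACN")
)

nmr_catalog <- function() list(
  instrument_model = list(kind = "class", terms = c(
    "Bruker Avance III 600" = "NMR:1400018", "Bruker Avance II 500" = "NMR:1400019",
    "Varian INOVA 600" = "NMR:1400020", "JEOL ECA 600" = "NMR:1400021")),
  instrument_probe = list(kind = "class", terms = c(
    "cryoprobe" = "NMR:1400122", "inverse triple resonance probe" = "NMR:1400123")),
  instrument_serial_number = list(kind = "value", acc = "NMR:1400034",
    name = "instrument serial number", default = "NMR-600-017"),
  software_name = list(kind = "class", terms = c(
    "TopSpin" = "NMR:1400225", "VnmrJ" = "NMR:1400226", "Delta" = "NMR:1400227")),
  software_version = list(kind = "attr", default = "3.6.2"),
  contact_name = list(kind = "value", acc = "NMR:1400301", name = "contact name",
    default = "John Smith"),
  contact_organization = list(kind = "value", acc = "NMR:1400302",
    name = "contact affiliation", default = "Example Institute"),
  raw_data_file_format = list(kind = "class", terms = c(
    "Bruker FID format" = "NMR:1400286", "nmrML format" = "NMR:1400287")),
  raw_data_file = list(kind = "attr", default = "fid"),
  data_file_checksum = list(kind = "value", acc = "NMR:1400292", name = "MD5",
    default = "6f1ed002ab5595859014ebf0951522d9"),
  data_file_content = list(kind = "class", terms = c(
    "free induction decay" = "NMR:1400296",
    "processed NMR spectrum" = "NMR:1400297")),
  magnetic_field_strength = list(kind = "velem", default = "9.4",
    unit = c("UO:0000228", "tesla")),
  irradiation_frequency = list(kind = "velem", default = "600.13",
    unit = c("UO:0000325", "megahertz")),
  effective_excitation_field = list(kind = "velem", default = "25000",
    unit = c("UO:0000106", "hertz")),
  number_of_scans = list(kind = "attr", default = "128"),
  number_of_steady_state_scans = list(kind = "attr", default = "4"),
  number_of_data_points = list(kind = "attr", default = "65536"),
  sweep_width = list(kind = "velem", default = "12019.23",
    unit = c("UO:0000106", "hertz")),
  relaxation_delay = list(kind = "velem", default = "4.0",
    unit = c("UO:0000010", "second")),
  pulse_width = list(kind = "velem", default = "10.5",
    unit = c("UO:0000029", "microsecond")),
  spinning_rate = list(kind = "velem", default = "20",
    unit = c("UO:0000106", "hertz")),
  sample_acquisition_temperature = list(kind = "velem", default = "298.0",
    unit = c("UO:0000012", "kelvin")),
  acquisition_nucleus = list(kind = "class", terms = c(
    "1H" = "NMR:1400152", "13C" = "NMR:1400153", "31P" = "NMR:1400155")),
  decoupling_nucleus = list(kind = "class", terms = c(
    "13C" = "NMR:1400153", "15N" = "NMR:1400154")),
  decoupling_method = list(kind = "class", terms = c(
    "WALTZ-16" = "NMR:1400342", "GARP" = "NMR:1400343")),
  pulse_sequence_name = list(kind = "attr", default = "noesypr1d"),
  solvent = list(kind = "class", terms = c(
    "deuterium oxide" = "NMR:1400312", "deuterated chloroform" = "NMR:1400313",
    "DMSO-d6" = "NMR:1400314")),
  solvent_suppression_method = list(kind = "class", terms = c(
    "presaturation" = "NMR:1400322", "WATERGATE" = "NMR:1400323",
    "excitation sculpting" = "NMR:1400324")),
  sample_container = list(kind = "class", terms = c(
    "5 mm NMR tube" = "NMR:1400332", "3 mm NMR tube" = "NMR:1400333")),
  sample_ph = list(kind = "attr", default = "7.4"),
  sample_volume = list(kind = "velem", default = "600",
    unit = c("UO:0000101", "microliter")),
  receiver_gain = list(kind = "velem", default = "90.5"),
  flip_angle = list(kind = "velem", default = "90",
    unit = c("UO:0000185", "degree")),
  shim_method = list(kind = "class", terms = c("gradient shimming" = "NMR:1400392")),
  detection_method = list(kind = "class", terms = c(
    "quadrature detection" = "NMR:1400402")),
  data_transformation = list(kind = "class", terms = c(
    "Fourier transform" = "NMR:1400352", "magnitude calculation" = "NMR:1400353")),
  window_function = list(kind = "class", terms = c(
    "exponential window function" = "NMR:1400362",
    "Gaussian window function" = "NMR:1400363",
    "sine bell window function" = "NMR:1400364")),
  window_function_parameter = list(kind = "velem", default = "0.3",
    unit = c("UO:0000106", "hertz")),
  zero_order_phase_correction = list(kind = "velem", default = "12.3",
    unit = c("UO:0000185", "degree")),
  first_order_phase_correction = list(kind = "velem", default = "-5.2",
    unit = c("UO:0000185", "degree")),
  zero_fill_size = list(kind = "attr", default = "131072"),
  baseline_correction_method = list(kind = "class", terms = c(
    "polynomial baseline correction" = "NMR:1400372")),
  calibration_compound = list(kind = "class", terms = c(
    "TSP" = "NMR:1400382", "DSS" = "NMR:1400383", "TMS" = "NMR:1400384")),
  processing_software = list(kind = "class", terms = c(
    "TopSpin" = "NMR:1400225", "Delta" = "NMR:1400227")),
  processing_software_version = list(kind = "attr", default = "4.0.7")
)

# vendor family implied by each injectable instrument model label
MODEL_FAMILY <- c(
  "LTQ Orbitrap" = "Thermo Fisher Scientific instrument model",
  "Q Exactive" = "Thermo Fisher Scientific instrument model",
  "SYNAPT G2-S" = "Waters instrument model",
  "micrOTOF-Q" = "Bruker Daltonics instrument model",
  "TripleTOF 5600" = "SCIEX instrument model",
  "Bruker Avance III 600" = "Bruker NMR instrument",
  "Bruker Avance II 500" = "Bruker NMR instrument",
  "Varian INOVA 600" = "Varian NMR instrument",
  "JEOL ECA 600" = "JEOL NMR instrument"
)

fixture_catalog <- function(technology) {
  switch(technology,
    mzML  = ms_catalog(),
    imzML = c(ms_catalog(), ims_catalog()),
    nmrML = nmr_catalog(),
    stopf("unknown technology '%s'", technology)
  )
}

#' Keys the fixture generator can inject for a technology
#' @param technology `"mzML"`, `"imzML"` or `"nmrML"`.
#' @return Character vector of injectable term keys.
#' @export
injectable_keys <- function(technology) names(fixture_catalog(technology))

#' Specify one synthetic data file
#'
#' @param technology `"mzML"`, `"imzML"` or `"nmrML"`.
#' @param injected Named character vector mapping injectable term keys to
#'   values (a term label for vocabulary-class keys, a literal otherwise),
#'   or the string `"all"` to inject every injectable key at its default
#'   value. Empty string values fall back to the key's default.
#' @param n_spectra Number of spectrum elements (MS technologies).
#' @param polarities Per-spectrum polarities, recycled: `"positive"` /
#'   `"negative"`.
#' @param windows List of `c(lower, upper)` scan windows, recycled over
#'   spectra.
#' @param representation `"profile"` or `"centroid"`; may be per-spectrum.
#' @param indexed Wrap the mzML document in an `indexedmzML` element.
#' @param decoys Plant vocabulary-matching cvParams outside every rule's
#'   scope, to exercise scope safety; decoys never enter the manifest.
#' @param seed Integer recorded in the spec; with all other fields it fully
#'   determines the output bytes.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(technology = c("mzML", "imzML", "nmrML"),
                         injected = "all", n_spectra = 3,
                         polarities = "positive",
                         windows = list(c(100, 1000)),
                         representation = "profile",
                         indexed = FALSE, decoys = FALSE, seed = 1L) {
  technology <- match.arg(technology)
  cat_keys <- injectable_keys(technology)
  if (identical(injected, "all")) {
    injected <- stats::setNames(rep("", length(cat_keys)), cat_keys)
  }
  bad <- setdiff(names(injected), cat_keys)
  if (length(bad)) {
    stopf("spec error: key(s) not injectable for %s: %s", technology,
          paste(bad, collapse = ", "), class = "spec2isa_spec_error")
  }
  catalog <- fixture_catalog(technology)
  injected <- vapply(names(injected), function(k) {
    v <- injected[[k]]
    e <- catalog[[k]]
    if (!nzchar(v)) {
      v <- if (e$kind == "class") names(e$terms)[1] else e$default
    }
    if (e$kind == "class" && !v %in% names(e$terms)) {
      stopf("spec error: '%s' is not an injectable label for %s", v, k,
            class = "spec2isa_spec_error")
    }
    v
  }, "")
  structure(
    list(technology = technology, injected = injected, n_spectra = n_spectra,
         polarities = rep_len(polarities, max(1, n_spectra)),
         windows = rep_len(windows, max(1, n_spectra)),
         representation = rep_len(representation, max(1, n_spectra)),
         indexed = indexed, decoys = decoys, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

xesc <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

cvp <- function(acc, name, value = "", unit = NULL) {
  ref <- acc_prefix(acc)
  u <- if (!is.null(unit)) {
    sprintf(' unitCvRef="%s" unitAccession="%s" unitName="%s"',
            acc_prefix(unit[1]), unit[1], xesc(unit[2]))
  } else ""
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"%s/>',
          ref, acc, xesc(name), xesc(value), u)
}

# cvParam line for an injected catalog entry
inj_cvp <- function(entry, value) {
  if (entry$kind == "class") {
    cvp(entry$terms[[value]], value)
  } else {
    cvp(entry$acc, entry$name, value = value,
        unit = entry$unit %||% NULL)
  }
}

#' Generate one synthetic data file
#'
#' Writes the XML file described by a fixture spec and returns the path
#' together with the manifest of expected extraction results: one row per
#' (term key, value) the extractor must recover, including values implied
#' rather than directly injected (the derived instrument manufacturer and
#' the four spectra-summary keys of MS files). The instrument model is
#' always injected through a referenceable parameter group so that group
#' dereferencing is exercised.
#'
#' @param spec A `fixture_spec`.
#' @param out_dir Output directory.
#' @param file_name Optional file name; defaults to a name derived from the
#'   spec seed.
#' @return List with `path` and `manifest` (tibble `file`, `term_key`,
#'   `value`).
#' @export
generate_file <- function(spec, out_dir, file_name = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- spec$technology
  file_name <- file_name %||% sprintf("fixture_seed%03d.%s", spec$seed, ext)
  path <- file.path(out_dir, file_name)
  xmltext <- if (spec$technology == "nmrML") nmrml_text(spec) else mzml_text(spec)
  write_lf(xmltext, path)
  list(path = path, manifest = fixture_manifest(spec, file_name))
}

fixture_manifest <- function(spec, file_name) {
  inj <- spec$injected
  rows <- list()
  push <- function(key, value) {
    rows[[length(rows) + 1L]] <<- tibble(file = file_name, term_key = key,
                                         value = value)
  }
  for (k in names(inj)) push(k, unname(inj[[k]]))
  if ("instrument_model" %in% names(inj)) {
    push("instrument_manufacturer", unname(MODEL_FAMILY[[inj[["instrument_model"]]]]))
  }
  if (spec$technology != "nmrML") {
    push("scan_count", as.character(spec$n_spectra))
    if (spec$n_spectra > 0) {
      pol <- unique(spec$polarities[seq_len(spec$n_spectra)])
      push("scan_polarity",
           if (length(pol) == 1) paste(pol, "scan") else "alternating scan")
      lo <- min(vapply(spec$windows[seq_len(spec$n_spectra)], `[`, 0, 1))
      hi <- max(vapply(spec$windows[seq_len(spec$n_spectra)], `[`, 0, 2))
      push("mz_range", paste0(fmt_num(lo), "-", fmt_num(hi)))
      for (r in unique(spec$representation[seq_len(spec$n_spectra)])) {
        push("spectrum_representation", paste(r, "spectrum"))
      }
    }
  }
  bind_rows(rows)
}

mzml_text <- function(spec) {
  catalog <- fixture_catalog(spec$technology)
  inj <- spec$injected
  has <- function(k) k %in% names(inj)
  line <- function(...) sprintf(...)
  out <- c('<?xml version="1.0" encoding="utf-8"?>')
  if (spec$indexed) {
    out <- c(out, '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">')
  }
  out <- c(out, '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  out <- c(out,
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>')

  # fileDescription: content, source file, contact
  out <- c(out, '<fileDescription>', '<fileContent>')
  if (has("data_file_content")) out <- c(out, inj_cvp(catalog$data_file_content, inj[["data_file_content"]]))
  for (k in c("ibd_identifier", "ibd_checksum", "ibd_binary_type")) {
    if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
  }
  if (spec$decoys) out <- c(out, cvp("MS:1000484", "orbitrap"))  # analyzer decoy out of scope
  out <- c(out, '</fileContent>')
  sf_keys <- c("raw_data_file", "raw_data_file_format", "native_spectrum_id_format",
               "data_file_checksum")
  if (any(vapply(sf_keys, has, TRUE))) {
    name_attr <- if (has("raw_data_file")) sprintf(' name="%s"', xesc(inj[["raw_data_file"]])) else ""
    out <- c(out, '<sourceFileList count="1">',
             line('<sourceFile id="SF1"%s location="file:///data/">', name_attr))
    for (k in c("raw_data_file_format", "native_spectrum_id_format", "data_file_checksum")) {
      if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
    }
    out <- c(out, '</sourceFile>', '</sourceFileList>')
  }
  if (has("contact_name") || has("contact_organization")) {
    out <- c(out, '<contact>')
    for (k in c("contact_name", "contact_organization")) {
      if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
    }
    out <- c(out, '</contact>')
  }
  out <- c(out, '</fileDescription>')

  # instrument model always travels via a referenceable param group
  if (has("instrument_model")) {
    out <- c(out, '<referenceableParamGroupList count="1">',
             '<referenceableParamGroup id="CommonInstrumentParams">',
             inj_cvp(catalog$instrument_model, inj[["instrument_model"]]),
             '</referenceableParamGroup>', '</referenceableParamGroupList>')
  }

  if (has("matrix_solution")) {
    out <- c(out, '<sampleList count="1">', '<sample id="sample1" name="tissue section">',
             inj_cvp(catalog$matrix_solution, inj[["matrix_solution"]]),
             '</sample>', '</sampleList>')
  }

  if (has("software_name") || has("software_version")) {
    ver <- if (has("software_version")) sprintf(' version="%s"', xesc(inj[["software_version"]])) else ""
    out <- c(out, '<softwareList count="1">', line('<software id="sw1"%s>', ver))
    if (has("software_name")) out <- c(out, inj_cvp(catalog$software_name, inj[["software_name"]]))
    if (spec$decoys) out <- c(out, cvp("MS:1000563", "Thermo RAW format"))  # file-format decoy
    out <- c(out, '</software>', '</softwareList>')
  }

  ims_scan_keys <- c("scan_direction", "scan_pattern", "scan_type",
                     "line_scan_direction", "max_count_pixels_x",
                     "max_count_pixels_y", "max_dimension_x", "max_dimension_y",
                     "pixel_size_x", "pixel_size_y", "absolute_position_offset_x",
                     "absolute_position_offset_y", "target_material",
                     "spatial_resolution", "position_accuracy")
  if (any(vapply(ims_scan_keys, has, TRUE))) {
    out <- c(out, '<scanSettingsList count="1">', '<scanSettings id="scs1">')
    for (k in ims_scan_keys) if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
    out <- c(out, '</scanSettings>', '</scanSettingsList>')
  }

  out <- c(out, '<instrumentConfigurationList count="1">',
           '<instrumentConfiguration id="IC1">')
  if (has("instrument_model")) {
    out <- c(out, '<referenceableParamGroupRef ref="CommonInstrumentParams"/>')
  }
  for (k in c("instrument_serial_number", "customization")) {
    if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
  }
  if (has("ion_source") || has("mass_analyzer") || has("detector")) {
    out <- c(out, '<componentList count="3">', '<source order="1">')
    if (has("ion_source")) out <- c(out, inj_cvp(catalog$ion_source, inj[["ion_source"]]))
    out <- c(out, '</source>', '<analyzer order="2">')
    if (has("mass_analyzer")) out <- c(out, inj_cvp(catalog$mass_analyzer, inj[["mass_analyzer"]]))
    out <- c(out, '</analyzer>', '<detector order="3">')
    if (has("detector")) out <- c(out, inj_cvp(catalog$detector, inj[["detector"]]))
    out <- c(out, '</detector>', '</componentList>')
  }
  out <- c(out, '</instrumentConfiguration>', '</instrumentConfigurationList>')

  out <- c(out, '<dataProcessingList count="1">', '<dataProcessing id="DP1">',
           '<processingMethod order="1" softwareRef="sw1">')
  for (k in c("file_conversion", "data_processing_action")) {
    if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
  }
  if (spec$decoys) out <- c(out, cvp("MS:1000253", "electron multiplier"))  # detector decoy
  out <- c(out, '</processingMethod>', '</dataProcessing>', '</dataProcessingList>')

  # run + spectra
  out <- c(out, '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
           sprintf('<spectrumList count="%d" defaultDataProcessingRef="DP1">',
                   spec$n_spectra))
  for (i in seq_len(spec$n_spectra)) {
    w <- spec$windows[[i]]
    pol <- spec$polarities[i]
    pol_acc <- if (pol == "positive") "MS:1000130" else "MS:1000129"
    rep_i <- spec$representation[i]
    rep_acc <- if (rep_i == "profile") "MS:1000128" else "MS:1000127"
    out <- c(out,
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="0">', i - 1L, i),
      cvp(rep_acc, paste(rep_i, "spectrum")),
      cvp(pol_acc, paste(pol, "scan")),
      '<scanList count="1">', '<scan>',
      '<scanWindowList count="1">', '<scanWindow>',
      cvp("MS:1000501", "scan window lower limit", fmt_num(w[1])),
      cvp("MS:1000500", "scan window upper limit", fmt_num(w[2])),
      '</scanWindow>', '</scanWindowList>', '</scan>', '</scanList>',
      '<binaryDataArrayList count="1">', '<binaryDataArray encodedLength="12">')
    if (i == 1 && "binary_compression" %in% names(inj)) {
      out <- c(out, inj_cvp(catalog$binary_compression, inj[["binary_compression"]]))
    }
    out <- c(out, '<binary>AAAAAAAAAAA=</binary>', '</binaryDataArray>',
             '</binaryDataArrayList>', '</spectrum>')
  }
  out <- c(out, '</spectrumList>', '</run>', '</mzML>')
  if (spec$indexed) out <- c(out, '</indexedmzML>')
  out
}

nmrml_text <- function(spec) {
  catalog <- nmr_catalog()
  inj <- spec$injected
  has <- function(k) k %in% names(inj)
  velem <- function(tag, key) {
    e <- catalog[[key]]
    u <- if (!is.null(e$unit)) {
      sprintf(' unitCvRef="UO" unitAccession="%s" unitName="%s"',
              e$unit[1], xesc(e$unit[2]))
    } else ""
    sprintf('<%s value="%s"%s/>', tag, xesc(inj[[key]]), u)
  }
  wrap_cv <- function(tag, key) {
    c(sprintf('<%s>', tag), inj_cvp(catalog[[key]], inj[[key]]), sprintf('</%s>', tag))
  }
  out <- c('<?xml version="1.0" encoding="utf-8"?>',
           '<nmrML xmlns="http://nmrml.org/schema" version="1.0.0">',
           '<cvList>',
           '<cv id="NMR" fullName="NMR Controlled Vocabulary" URI="http://nmrml.org/cv/nmrCV.owl"/>',
           '<cv id="UO" fullName="Unit Ontology" URI="http://purl.obolibrary.org/obo/uo.obo"/>',
           '</cvList>')

  out <- c(out, '<fileDescription>', '<fileContent>')
  if (has("data_file_content")) out <- c(out, inj_cvp(catalog$data_file_content, inj[["data_file_content"]]))
  out <- c(out, '</fileContent>')
  sf_keys <- c("raw_data_file", "raw_data_file_format", "data_file_checksum")
  if (any(vapply(sf_keys, has, TRUE))) {
    name_attr <- if (has("raw_data_file")) sprintf(' name="%s"', xesc(inj[["raw_data_file"]])) else ""
    out <- c(out, '<sourceFileList count="1">',
             sprintf('<sourceFile id="SF1"%s location="file:///data/">', name_attr))
    for (k in c("raw_data_file_format", "data_file_checksum")) {
      if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
    }
    out <- c(out, '</sourceFile>', '</sourceFileList>')
  }
  out <- c(out, '</fileDescription>')

  if (has("contact_name") || has("contact_organization")) {
    out <- c(out, '<contactList>', '<contact id="c1">')
    for (k in c("contact_name", "contact_organization")) {
      if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
    }
    out <- c(out, '</contact>', '</contactList>')
  }

  if (has("software_name") || has("software_version")) {
    ver <- if (has("software_version")) sprintf(' version="%s"', xesc(inj[["software_version"]])) else ""
    out <- c(out, '<softwareList count="1">', sprintf('<software id="sw1"%s>', ver))
    if (has("software_name")) out <- c(out, inj_cvp(catalog$software_name, inj[["software_name"]]))
    out <- c(out, '</software>', '</softwareList>')
  }

  out <- c(out, '<instrumentConfigurationList count="1">',
           '<instrumentConfiguration id="IC1">')
  for (k in c("instrument_model", "instrument_probe", "instrument_serial_number")) {
    if (has(k)) out <- c(out, inj_cvp(catalog[[k]], inj[[k]]))
  }
  if (spec$decoys) out <- c(out, cvp("NMR:1400312", "deuterium oxide"))  # solvent decoy
  out <- c(out, '</instrumentConfiguration>', '</instrumentConfigurationList>')

  # acquisition block (always present)
  aps_attrs <- ""
  for (pair in list(c("number_of_scans", "numberOfScans"),
                    c("number_of_steady_state_scans", "numberOfSteadyStateScans"),
                    c("sample_ph", "samplePH"))) {
    if (has(pair[1])) {
      aps_attrs <- paste0(aps_attrs, sprintf(' %s="%s"', pair[2], xesc(inj[[pair[1]]])))
    }
  }
  out <- c(out, '<acquisition>', '<acquisition1D>',
           sprintf('<acquisitionParameterSet%s>', aps_attrs))
  for (pair in list(c("magnetic_field_strength", "fieldStrength"),
                    c("irradiation_frequency", "irradiationFrequency"),
                    c("relaxation_delay", "relaxationDelay"),
                    c("spinning_rate", "spinningRate"),
                    c("sample_acquisition_temperature", "sampleAcquisitionTemperature"),
                    c("sample_volume", "sampleVolume"),
                    c("receiver_gain", "receiverGain"))) {
    if (has(pair[1])) out <- c(out, velem(pair[2], pair[1]))
  }
  for (pair in list(c("solvent", "solvent"),
                    c("solvent_suppression_method", "solventSuppressionMethod"),
                    c("sample_container", "sampleContainer"),
                    c("shim_method", "shimmingMethod"),
                    c("detection_method", "detectionMethod"))) {
    if (has(pair[1])) out <- c(out, wrap_cv(pair[2], pair[1]))
  }
  if (has("pulse_sequence_name")) {
    out <- c(out, sprintf('<pulseSequence name="%s"/>', xesc(inj[["pulse_sequence_name"]])))
  }
  ddp_keys <- c("number_of_data_points", "sweep_width", "pulse_width", "flip_angle",
                "effective_excitation_field", "acquisition_nucleus",
                "decoupling_nucleus", "decoupling_method")
  if (any(vapply(ddp_keys, has, TRUE))) {
    ndp <- if (has("number_of_data_points"))
      sprintf(' numberOfDataPoints="%s"', xesc(inj[["number_of_data_points"]])) else ""
    out <- c(out, sprintf('<DirectDimensionParameterSet%s>', ndp))
    for (pair in list(c("sweep_width", "sweepWidth"),
                      c("pulse_width", "pulseWidth"),
                      c("flip_angle", "flipAngle"),
                      c("effective_excitation_field", "effectiveExcitationField"))) {
      if (has(pair[1])) out <- c(out, velem(pair[2], pair[1]))
    }
    for (pair in list(c("acquisition_nucleus", "acquisitionNucleus"),
                      c("decoupling_nucleus", "decouplingNucleus"),
                      c("decoupling_method", "decouplingMethod"))) {
      if (has(pair[1])) out <- c(out, wrap_cv(pair[2], pair[1]))
    }
    out <- c(out, '</DirectDimensionParameterSet>')
  }
  out <- c(out, '</acquisitionParameterSet>', '</acquisition1D>', '</acquisition>')

  # processing + spectrum list
  proc_keys <- c("data_transformation", "window_function", "window_function_parameter",
                 "zero_order_phase_correction", "first_order_phase_correction",
                 "zero_fill_size", "baseline_correction_method", "calibration_compound")
  if (any(vapply(proc_keys, has, TRUE))) {
    zf <- if (has("zero_fill_size"))
      sprintf(' zeroFillSize="%s"', xesc(inj[["zero_fill_size"]])) else ""
    out <- c(out, '<spectrumList count="1">', '<spectrum1D id="sp1">',
             sprintf('<processingParameterSet%s>', zf))
    if (has("data_transformation"))
      out <- c(out, inj_cvp(catalog$data_transformation, inj[["data_transformation"]]))
    if (has("window_function") || has("window_function_parameter")) {
      out <- c(out, '<windowFunction>')
      if (has("window_function"))
        out <- c(out, inj_cvp(catalog$window_function, inj[["window_function"]]))
      if (has("window_function_parameter"))
        out <- c(out, velem("windowFunctionParameter", "window_function_parameter"))
      out <- c(out, '</windowFunction>')
    }
    for (pair in list(c("zero_order_phase_correction", "zeroOrderPhaseCorrection"),
                      c("first_order_phase_correction", "firstOrderPhaseCorrection"))) {
      if (has(pair[1])) out <- c(out, velem(pair[2], pair[1]))
    }
    if (has("baseline_correction_method"))
      out <- c(out, inj_cvp(catalog$baseline_correction_method, inj[["baseline_correction_method"]]))
    if (has("calibration_compound"))
      out <- c(out, wrap_cv("calibrationCompound", "calibration_compound"))
    out <- c(out, '</processingParameterSet>', '</spectrum1D>', '</spectrumList>')
  }

  if (has("processing_software") || has("processing_software_version")) {
    ver <- if (has("processing_software_version"))
      sprintf(' softwareVersion="%s"', xesc(inj[["processing_software_version"]])) else ""
    out <- c(out, '<dataProcessingList count="1">',
             sprintf('<dataProcessing id="DP1"%s>', ver))
    if (has("processing_software"))
      out <- c(out, inj_cvp(catalog$processing_software, inj[["processing_software"]]))
    out <- c(out, '</dataProcessing>', '</dataProcessingList>')
  }

  c(out, '</nmrML>')
}

#' Generate a corpus of synthetic files with a ground-truth manifest
#'
#' Writes `n` files of one technology with randomly sampled injected key
#' subsets and values, emulating batches of instrument output. The sampled
#' specs, and therefore the output bytes, are fully determined by `seed`.
#'
#' @param n Number of files (>= 1).
#' @param technology `"mzML"`, `"imzML"` or `"nmrML"`.
#' @param seed Integer seed driving all sampling.
#' @param out_dir Output directory.
#' @param p_inject Probability that each injectable key is present in a
#'   given file.
#' @param decoys Plant out-of-scope decoy cvParams in every file.
#' @return A `corpus_manifest`: list with `dir`, `technology`, `files`,
#'   `specs` and the ground-truth `manifest` tibble (`file`, `term_key`,
#'   `value`).
#' @export
generate_corpus <- function(n, technology = c("mzML", "imzML", "nmrML"),
                            seed = 1L, out_dir = tempfile("corpus"),
                            p_inject = 0.7, decoys = FALSE) {
  stopifnot(n >= 1)
  technology <- match.arg(technology)
  set.seed(seed)
  catalog <- fixture_catalog(technology)
  keys <- names(catalog)
  specs <- vector("list", n)
  results <- vector("list", n)
  files <- character(n)
  for (i in seq_len(n)) {
    pick <- keys[stats::runif(length(keys)) < p_inject]
    injected <- vapply(pick, function(k) {
      e <- catalog[[k]]
      if (e$kind == "class") {
        sample(names(e$terms), 1)
      } else if (k %in% c("instrument_serial_number", "data_file_checksum",
                          "ibd_checksum")) {
        paste0(substr(e$default, 1, 4), sprintf("%06d", sample.int(999999L, 1)))
      } else {
        e$default
      }
    }, "")
    if (technology == "nmrML") {
      spec <- fixture_spec(technology, injected = injected, n_spectra = 0,
                           decoys = decoys, seed = seed + i)
    } else {
      ns <- sample(1:4, 1)
      pols <- if (ns > 1 && stats::runif(1) < 0.2) {
        sample(c("positive", "negative"), ns, replace = TRUE)
      } else {
        rep(sample(c("positive", "negative"), 1), ns)
      }
      wins <- lapply(seq_len(ns), function(j) {
        lo <- round(stats::runif(1, 50, 200), 1)
        c(lo, lo + round(stats::runif(1, 500, 1800), 1))
      })
      spec <- fixture_spec(technology, injected = injected, n_spectra = ns,
                           polarities = pols, windows = wins,
                           representation = sample(c("profile", "centroid"), 1),
                           indexed = stats::runif(1) < 0.3,
                           decoys = decoys, seed = seed + i)
    }
    fname <- sprintf("fixture_%03d.%s", i, technology)
    res <- generate_file(spec, out_dir, file_name = fname)
    specs[[i]] <- spec
    results[[i]] <- res$manifest
    files[i] <- res$path
  }
  structure(
    list(dir = out_dir, technology = technology, files = files,
         specs = specs, manifest = bind_rows(results)),
    class = "corpus_manifest"
  )
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf("<corpus_manifest> %d %s file(s) in %s, %d injected value(s)\n",
              length(x$files), x$technology, x$dir, nrow(x$manifest)))
  invisible(x)
}
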