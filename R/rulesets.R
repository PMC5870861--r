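#' Extraction rulesets
#'
#' An extraction rule is one row of the extraction table: where to
#' look in the XML (`xml_scope`, a slash-joined element-path fragment), what
#' to match (`source`: a `cvParam` by accession, an XML `attribute`, a
#' `value-element` carrying `value`/`unitAccession`/`unitName` attributes, a
#' whole-file spectra `summary`, or a `derived` value), which vocabulary
#' subtree counts as a match (`match_mode` `"exact"` or `"descendant"` of
#' `cv_target`), how many values to keep (`cardinality`, `aggregation`), and
#' which Assay-file column the result populates (`isa_field`). The `protocol`
#' column assigns the field to the instrument-analysis or data-transformation
#' protocol block of the assay table.
#'
#' The default sets pin 23 terms for mzML, 42 for imzML (the 23 mzML rules
#' plus 19 imaging rules in the IMS namespace) and 46 for nmrML.
#'
#' @return A tibble with one row per rule, columns `term_key`, `isa_field`,
#'   `source`, `xml_scope`, `match_mode`, `cv_target`, `element`,
#'   `attribute`, `cardinality`, `aggregation`, `protocol`.
#' @name rulesets
NULL

rule <- function(term_key, isa_field, source, xml_scope,
                 match_mode = NA_character_, cv_target = NA_character_,
                 element = NA_character_, attribute = NA_character_,
                 cardinality = "single", aggregation = "first",
                 protocol = "instrument") {
  tibble(term_key = term_key, isa_field = isa_field, source = source,
         xml_scope = xml_scope, match_mode = match_mode, cv_target = cv_target,
         element = element, attribute = attribute, cardinality = cardinality,
         aggregation = aggregation, protocol = protocol)
}

#' @rdname rulesets
#' @export
default_mzml_ruleset <- function() {
  bind_rows(
    rule("instrument_model", "Instrument", "cvParam", "instrumentConfiguration",
         "descendant", "MS:1000031"),
    rule("instrument_manufacturer", "Instrument manufacturer", "derived",
         "instrumentConfiguration", cv_target = "MS:1000031",
         aggregation = "manufacturer"),
    rule("instrument_serial_number", "Instrument serial number", "cvParam",
         "instrumentConfiguration", "exact", "MS:1000529"),
    rule("customization", "Instrument customization", "cvParam",
         "instrumentConfiguration", "exact", "MS:1000032"),
    rule("ion_source", "Ion source", "cvParam", "instrumentConfiguration",
         "descendant", "MS:1000008", cardinality = "multi", aggregation = "all"),
    rule("mass_analyzer", "Mass analyzer", "cvParam", "instrumentConfiguration",
         "descendant", "MS:1000443", cardinality = "multi", aggregation = "all"),
    rule("detector", "Detector", "cvParam", "instrumentConfiguration",
         "descendant", "MS:1000026", cardinality = "multi", aggregation = "all"),
    rule("software_name", "Instrument software", "cvParam",
         "softwareList/software", "descendant", "MS:1000531"),
    rule("software_version", "Instrument software version", "attribute",
         "softwareList/software", element = "software", attribute = "version"),
    rule("file_conversion", "File conversion", "cvParam", "dataProcessing",
         "descendant", "MS:1000530", protocol = "data transformation"),
    rule("data_processing_action", "Data transformation", "cvParam",
         "dataProcessing", "descendant", "MS:1000543",
         cardinality = "multi", aggregation = "all",
         protocol = "data transformation"),
    rule("binary_compression", "Binary data compression", "cvParam",
         "binaryDataArray", "descendant", "MS:1000572",
         protocol = "data transformation"),
    rule("raw_data_file_format", "Raw data file format", "cvParam",
         "sourceFile", "descendant", "MS:1000560"),
    rule("raw_data_file", "Raw data file", "attribute",
         "sourceFileList/sourceFile", element = "sourceFile", attribute = "name"),
    rule("native_spectrum_id_format", "Native spectrum identifier format",
         "cvParam", "sourceFile", "descendant", "MS:1000767"),
    rule("data_file_checksum", "Data file checksum", "cvParam", "sourceFile",
         "descendant", "MS:1000561"),
    rule("data_file_content", "Data file content", "cvParam",
         "fileDescription/fileContent", "descendant", "MS:1000524",
         cardinality = "multi", aggregation = "all"),
    rule("contact_name", "Contact name", "cvParam", "fileDescription/contact",
         "exact", "MS:1000586"),
    rule("contact_organization", "Contact affiliation", "cvParam",
         "fileDescription/contact", "exact", "MS:1000590"),
    rule("spectrum_representation", "Spectrum representation", "summary",
         "run/spectrumList", cardinality = "multi",
         aggregation = "spectra-summary"),
    rule("scan_polarity", "Scan polarity", "summary", "run/spectrumList",
         aggregation = "spectra-summary"),
    rule("mz_range", "Scan m/z range", "summary", "run/spectrumList",
         aggregation = "spectra-summary"),
    rule("scan_count", "Number of scans", "summary", "run/spectrumList",
         aggregation = "spectra-summary")
  )
}

#' @rdname rulesets
#' @export
default_imzml_ruleset <- function() {
  bind_rows(
    default_mzml_ruleset(),
    rule("ibd_identifier", "IBD identifier", "cvParam",
         "fileDescription/fileContent", "exact", "IMS:1000080"),
    rule("ibd_checksum", "IBD checksum", "cvParam",
         "fileDescription/fileContent", "descendant", "IMS:1000009"),
    rule("ibd_binary_type", "IBD binary type", "cvParam",
         "fileDescription/fileContent", "descendant", "IMS:1000003"),
    rule("scan_direction", "Scan direction", "cvParam", "scanSettings",
         "descendant", "IMS:1000040"),
    rule("scan_pattern", "Scan pattern", "cvParam", "scanSettings",
         "descendant", "IMS:1000041"),
    rule("scan_type", "Scan type", "cvParam", "scanSettings",
         "descendant", "IMS:1000048"),
    rule("line_scan_direction", "Line scan direction", "cvParam",
         "scanSettings", "descendant", "IMS:1000049"),
    rule("max_count_pixels_x", "Max count of pixels x", "cvParam",
         "scanSettings", "exact", "IMS:1000042"),
    rule("max_count_pixels_y", "Max count of pixels y", "cvParam",
         "scanSettings", "exact", "IMS:1000043"),
    rule("max_dimension_x", "Max dimension x", "cvParam", "scanSettings",
         "exact", "IMS:1000044"),
    rule("max_dimension_y", "Max dimension y", "cvParam", "scanSettings",
         "exact", "IMS:1000045"),
    rule("pixel_size_x", "Pixel size x", "cvParam", "scanSettings",
         "exact", "IMS:1000046"),
    rule("pixel_size_y", "Pixel size y", "cvParam", "scanSettings",
         "exact", "IMS:1000047"),
    rule("absolute_position_offset_x", "Absolute position offset x",
         "cvParam", "scanSettings", "exact", "IMS:1000053"),
    rule("absolute_position_offset_y", "Absolute position offset y",
         "cvParam", "scanSettings", "exact", "IMS:1000054"),
    rule("target_material", "Target material", "cvParam", "scanSettings",
         "exact", "IMS:1000202"),
    rule("spatial_resolution", "Spatial resolution", "cvParam",
         "scanSettings", "exact", "IMS:1000802"),
    rule("position_accuracy", "Position accuracy", "cvParam", "scanSettings",
         "exact", "IMS:1000806"),
    rule("matrix_solution", "Matrix solution", "cvParam", "sampleList/sample",
         "exact", "IMS:1000835")
  )
}

#' @rdname rulesets
#' @export
default_nmrml_ruleset <- function() {
  bind_rows(
    rule("instrument_model", "Instrument", "cvParam", "instrumentConfiguration",
         "descendant", "NMR:1400014"),
    rule("instrument_manufacturer", "Instrument manufacturer", "derived",
         "instrumentConfiguration", cv_target = "NMR:1400014",
         aggregation = "manufacturer"),
    rule("instrument_probe", "NMR probe", "cvParam", "instrumentConfiguration",
         "descendant", "NMR:1400121"),
    rule("instrument_serial_number", "Instrument serial number", "cvParam",
         "instrumentConfiguration", "exact", "NMR:1400034"),
    rule("software_name", "Acquisition software", "cvParam",
         "softwareList/software", "descendant", "NMR:1400224"),
    rule("software_version", "Acquisition software version", "attribute",
         "softwareList/software", element = "software", attribute = "version"),
    rule("contact_name", "Contact name", "cvParam", "contactList/contact",
         "exact", "NMR:1400301"),
    rule("contact_organization", "Contact affiliation", "cvParam",
         "contactList/contact", "exact", "NMR:1400302"),
    rule("raw_data_file_format", "Raw data file format", "cvParam",
         "sourceFileList/sourceFile", "descendant", "NMR:1400285"),
    rule("raw_data_file", "Raw data file", "attribute",
         "sourceFileList/sourceFile", element = "sourceFile", attribute = "name"),
    rule("data_file_checksum", "Data file checksum", "cvParam",
         "sourceFileList/sourceFile", "descendant", "NMR:1400291"),
    rule("data_file_content", "Data file content", "cvParam",
         "fileDescription/fileContent", "descendant", "NMR:1400295",
         cardinality = "multi", aggregation = "all"),
    rule("magnetic_field_strength", "Magnetic field strength", "value-element",
         "acquisitionParameterSet", element = "fieldStrength"),
    rule("irradiation_frequency", "Irradiation frequency", "value-element",
         "acquisitionParameterSet", element = "irradiationFrequency"),
    rule("effective_excitation_field", "Effective excitation field",
         "value-element", "DirectDimensionParameterSet",
         element = "effectiveExcitationField"),
    rule("number_of_scans", "Number of scans", "attribute",
         "acquisitionParameterSet", element = "acquisitionParameterSet",
         attribute = "numberOfScans"),
    rule("number_of_steady_state_scans", "Number of steady state scans",
         "attribute", "acquisitionParameterSet",
         element = "acquisitionParameterSet",
         attribute = "numberOfSteadyStateScans"),
    rule("number_of_data_points", "Number of data points", "attribute",
         "DirectDimensionParameterSet", element = "DirectDimensionParameterSet",
         attribute = "numberOfDataPoints"),
    rule("sweep_width", "Sweep width", "value-element",
         "DirectDimensionParameterSet", element = "sweepWidth"),
    rule("relaxation_delay", "Relaxation delay", "value-element",
         "acquisitionParameterSet", element = "relaxationDelay"),
    rule("pulse_width", "Pulse width", "value-element",
         "DirectDimensionParameterSet", element = "pulseWidth"),
    rule("spinning_rate", "Spinning rate", "value-element",
         "acquisitionParameterSet", element = "spinningRate"),
    rule("sample_acquisition_temperature", "Temperature", "value-element",
         "acquisitionParameterSet", element = "sampleAcquisitionTemperature"),
    rule("acquisition_nucleus", "Acquisition nucleus", "cvParam",
         "DirectDimensionParameterSet/acquisitionNucleus", "descendant",
         "NMR:1400151"),
    rule("decoupling_nucleus", "Decoupling nucleus", "cvParam",
         "DirectDimensionParameterSet/decouplingNucleus", "descendant",
         "NMR:1400151"),
    rule("decoupling_method", "Decoupling method", "cvParam",
         "DirectDimensionParameterSet/decouplingMethod", "descendant",
         "NMR:1400341"),
    rule("pulse_sequence_name", "Pulse sequence name", "attribute",
         "pulseSequence", element = "pulseSequence", attribute = "name"),
    rule("solvent", "Solvent", "cvParam", "acquisitionParameterSet/solvent",
         "descendant", "NMR:1400311"),
    rule("solvent_suppression_method", "Solvent suppression method", "cvParam",
         "acquisitionParameterSet/solventSuppressionMethod", "descendant",
         "NMR:1400321"),
    rule("sample_container", "NMR tube type", "cvParam",
         "acquisitionParameterSet/sampleContainer", "descendant", "NMR:1400331"),
    rule("sample_ph", "Sample pH", "attribute", "acquisitionParameterSet",
         element = "acquisitionParameterSet", attribute = "samplePH"),
    rule("sample_volume", "Sample volume", "value-element",
         "acquisitionParameterSet", element = "sampleVolume"),
    rule("receiver_gain", "Receiver gain", "value-element",
         "acquisitionParameterSet", element = "receiverGain"),
    rule("flip_angle", "Flip angle", "value-element",
         "DirectDimensionParameterSet", element = "flipAngle"),
    rule("shim_method", "Shimming method", "cvParam",
         "acquisitionParameterSet/shimmingMethod", "descendant", "NMR:1400391"),
    rule("detection_method", "Detection method", "cvParam",
         "acquisitionParameterSet/detectionMethod", "descendant", "NMR:1400401"),
    rule("data_transformation", "Data transformation", "cvParam",
         "processingParameterSet", "descendant", "NMR:1400351",
         cardinality = "multi", aggregation = "all",
         protocol = "data transformation"),
    rule("window_function", "Window function", "cvParam",
         "processingParameterSet/windowFunction", "descendant", "NMR:1400361",
         protocol = "data transformation"),
    rule("window_function_parameter", "Window function parameter",
         "value-element", "processingParameterSet/windowFunction",
         element = "windowFunctionParameter", protocol = "data transformation"),
    rule("zero_order_phase_correction", "Zero order phase correction",
         "value-element", "processingParameterSet",
         element = "zeroOrderPhaseCorrection", protocol = "data transformation"),
    rule("first_order_phase_correction", "First order phase correction",
         "value-element", "processingParameterSet",
         element = "firstOrderPhaseCorrection", protocol = "data transformation"),
    rule("zero_fill_size", "Zero fill size", "attribute",
         "processingParameterSet", element = "processingParameterSet",
         attribute = "zeroFillSize", protocol = "data transformation"),
    rule("baseline_correction_method", "Baseline correction method", "cvParam",
         "processingParameterSet", "descendant", "NMR:1400371",
         protocol = "data transformation"),
    rule("calibration_compound", "Chemical shift calibration compound",
         "cvParam", "processingParameterSet/calibrationCompound", "descendant",
         "NMR:1400381", protocol = "data transformation"),
    rule("processing_software", "Processing software", "cvParam",
         "dataProcessingList/dataProcessing", "descendant", "NMR:1400224",
         protocol = "data transformation"),
    rule("processing_software_version", "Processing software version",
         "attribute", "dataProcessingList/dataProcessing",
         element = "dataProcessing", attribute = "softwareVersion",
         protocol = "data transformation")
  )
}

default_ruleset <- function(technology) {
  switch(technology,
    mzML  = default_mzml_ruleset(),
    imzML = default_imzml_ruleset(),
    nmrML = default_nmrml_ruleset(),
    stopf("unknown technology '%s'", technology)
  )
}
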