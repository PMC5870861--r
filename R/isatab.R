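#' Assemble a study dataset into an ISA-Tab document
#'
#' Builds the in-memory three-part ISA-Tab structure: an Investigation with
#' the standard section skeleton (empty optional fields are kept as empty
#' cells for later manual completion), one Study-table row and one
#' Assay-table row per input data file, and a `Parameter Value[...]` assay
#' column per captured term key. Sample names default to the file basename
#' without extension, with one source per sample. Values resolved against a
#' vocabulary emit the ontology-annotation triple (value, Term Source REF,
#' Term Accession Number); a triple is emitted only when the cell holds a
#' single vocabulary-resolved value, since a semicolon-joined multi-value
#' cell cannot carry one unambiguous accession. Values with units render as
#' "value unit-label" in the cell (the JSON export keeps the full
#' structure). The measurement type is "metabolite profiling" and the
#' technology type "mass spectrometry" (mzML/imzML) or "NMR spectroscopy"
#' (nmrML). A default protocol chain is declared when the user supplies
#' none, with extracted parameters attached to the instrument-analysis and
#' data-transformation protocols, so the stub can be completed in standard
#' ISA editors.
#'
#' @param dataset A `study_dataset` from [merge_corpus()].
#' @param rules Extraction-rule tibble used to label and group the columns;
#'   defaults to the technology's default ruleset.
#' @return An `isatab_document`.
#' @export
build_isatab <- function(dataset, rules = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (length(dataset$files) == 0) {
    stopf("cannot build ISA-Tab from a dataset with zero files",
          class = "spec2isa_isatab_error")
  }
  rules <- rules %||% default_ruleset(dataset$technology)
  desc <- dataset$descriptor
  is_nmr <- dataset$technology == "nmrML"
  tech_type <- if (is_nmr) "NMR spectroscopy" else "mass spectrometry"
  slug <- if (is_nmr) "metabolite_profiling_NMR_spectroscopy" else
    "metabolite_profiling_mass_spectrometry"
  study_file <- paste0("s_", desc$study_identifier, ".txt")
  assay_file <- paste0("a_", desc$study_identifier, "_", slug, ".txt")

  samples <- vapply(dataset$files, function(f) {
    sub("\\.[A-Za-z0-9]+$", "", f$source_file)
  }, "")

  # column metadata: label and protocol block per captured key
  keys <- dataset$column_union
  meta <- tibble(term_key = keys) |>
    left_join(rules[, c("term_key", "isa_field", "protocol")], by = "term_key")
  missing <- is.na(meta$isa_field)
  meta$isa_field[missing] <- pretty_key(meta$term_key[missing])
  meta$protocol[missing] <- "instrument"

  cellify <- function(fm, key) {
    rows <- fm$entries[fm$entries$term_key == key, ]
    if (nrow(rows) == 0) {
      extra <- dataset$descriptor$extra_parameters[[key]]
      if (!is.null(extra)) {
        return(list(value = as.character(extra), source = "", accession = ""))
      }
      return(list(value = "", source = "", accession = ""))
    }
    shown <- ifelse(nzchar(rows$unit_label),
                    paste(rows$value, rows$unit_label), rows$value)
    out <- list(value = paste(shown, collapse = ";"), source = "", accession = "")
    if (nrow(rows) == 1 && nzchar(rows$term_accession)) {
      out$source <- unname(PREFIX_TO_SOURCE[acc_prefix(rows$term_accession)] %||% "")
      out$accession <- rows$term_accession
    }
    out
  }

  block_cols <- function(block_keys) {
    header <- character(); col_cells <- list()
    for (k in block_keys) {
      cells <- lapply(dataset$files, cellify, key = k)
      lab <- meta$isa_field[meta$term_key == k]
      header <- c(header, paste0("Parameter Value[", lab, "]"))
      col_cells[[length(col_cells) + 1L]] <- vapply(cells, `[[`, "", "value")
      if (any(vapply(cells, function(c) nzchar(c$accession), TRUE))) {
        header <- c(header, "Term Source REF", "Term Accession Number")
        col_cells[[length(col_cells) + 1L]] <- vapply(cells, `[[`, "", "source")
        col_cells[[length(col_cells) + 1L]] <- vapply(cells, `[[`, "", "accession")
      }
    }
    list(header = header, cols = col_cells)
  }

  instr_keys <- meta$term_key[meta$protocol != "data transformation"]
  dt_keys <- meta$term_key[meta$protocol == "data transformation"]
  instr <- block_cols(instr_keys)
  dt <- block_cols(dt_keys)

  if (is_nmr) {
    pre_protocols <- c("Extraction", "NMR sample", "NMR spectroscopy")
    assay_name_col <- "NMR Assay Name"
    mid_protocols <- c("NMR assay", "Data transformation")
    protocol_chain <- c("Sample collection", "Extraction", "NMR sample",
                        "NMR spectroscopy", "NMR assay", "Data transformation",
                        "Metabolite identification")
    instr_protocol <- "NMR spectroscopy"
  } else {
    pre_protocols <- c("Extraction", "Chromatography", "Mass spectrometry")
    assay_name_col <- "MS Assay Name"
    mid_protocols <- "Data transformation"
    protocol_chain <- c("Sample collection", "Extraction", "Chromatography",
                        "Mass spectrometry", "Data transformation",
                        "Metabolite identification")
    instr_protocol <- "Mass spectrometry"
  }

  assay_header <- c("Sample Name", rep("Protocol REF", length(pre_protocols)),
                    instr$header, assay_name_col, "Raw Spectral Data File",
                    rep("Protocol REF", length(mid_protocols)), dt$header,
                    "Protocol REF")
  n <- length(dataset$files)
  assay_rows <- lapply(seq_len(n), function(i) {
    c(samples[i], pre_protocols,
      vapply(instr$cols, `[`, "", i),
      samples[i], dataset$files[[i]]$source_file,
      mid_protocols,
      vapply(dt$cols, `[`, "", i),
      "Metabolite identification")
  })

  study_header <- c("Source Name", "Protocol REF", "Sample Name")
  study_rows <- lapply(samples, function(s) c(s, "Sample collection", s))

  sources <- if (is_nmr) "NMRCV" else if (dataset$technology == "imzML")
    c("MS", "IMS") else "MS"
  source_desc <- c(
    MS = "PSI Mass Spectrometry Ontology",
    IMS = "Imaging Mass Spectrometry Ontology",
    NMRCV = "NMR Controlled Vocabulary")[sources]

  param_names <- function(proto) {
    if (proto == instr_protocol) {
      paste(meta$isa_field[meta$term_key %in% instr_keys], collapse = ";")
    } else if (proto == "Data transformation") {
      paste(meta$isa_field[meta$term_key %in% dt_keys], collapse = ";")
    } else ""
  }
  protocols <- tibble(
    name = protocol_chain,
    type = tolower(protocol_chain),
    description = "",
    parameters = vapply(protocol_chain, param_names, "")
  )
  if (nrow(desc$protocols)) {
    extra_p <- tibble(name = desc$protocols$name,
                      type = desc$protocols$type %||% tolower(desc$protocols$name),
                      description = desc$protocols$description %||% "",
                      parameters = "")
    protocols <- bind_rows(protocols, extra_p[!extra_p$name %in% protocols$name, ])
  }

  contacts <- desc$contacts
  ncontact <- max(1L, nrow(contacts))
  contact_cell <- function(col) {
    if (nrow(contacts) == 0) return("")
    v <- contacts[[col]] %||% rep("", nrow(contacts))
    ifelse(is.na(v), "", v)
  }

  investigation <- list(
    isection("ONTOLOGY SOURCE REFERENCE",
      "Term Source Name" = sources,
      "Term Source File" = rep("", length(sources)),
      "Term Source Version" = rep("", length(sources)),
      "Term Source Description" = unname(source_desc)),
    isection("INVESTIGATION",
      "Investigation Identifier" = desc$study_identifier,
      "Investigation Title" = desc$title,
      "Investigation Description" = desc$description,
      "Investigation Submission Date" = desc$submission_date,
      "Investigation Public Release Date" = desc$release_date),
    isection("STUDY",
      "Study Identifier" = desc$study_identifier,
      "Study Title" = desc$title,
      "Study Description" = desc$description,
      "Study Submission Date" = desc$submission_date,
      "Study Public Release Date" = desc$release_date,
      "Study File Name" = study_file),
    isection("STUDY DESIGN DESCRIPTORS",
      "Study Design Type" = "",
      "Study Design Type Term Accession Number" = "",
      "Study Design Type Term Source REF" = ""),
    isection("STUDY PUBLICATIONS",
      "Study PubMed ID" = "",
      "Study Publication DOI" = "",
      "Study Publication Author List" = "",
      "Study Publication Title" = "",
      "Study Publication Status" = ""),
    isection("STUDY FACTORS",
      "Study Factor Name" = "",
      "Study Factor Type" = "",
      "Study Factor Type Term Accession Number" = "",
      "Study Factor Type Term Source REF" = ""),
    isection("STUDY ASSAYS",
      "Study Assay File Name" = assay_file,
      "Study Assay Measurement Type" = "metabolite profiling",
      "Study Assay Measurement Type Term Accession Number" = "",
      "Study Assay Measurement Type Term Source REF" = "",
      "Study Assay Technology Type" = tech_type,
      "Study Assay Technology Type Term Accession Number" = "",
      "Study Assay Technology Type Term Source REF" = "",
      "Study Assay Technology Platform" = ""),
    isection("STUDY PROTOCOLS",
      "Study Protocol Name" = protocols$name,
      "Study Protocol Type" = protocols$type,
      "Study Protocol Type Term Accession Number" = rep("", nrow(protocols)),
      "Study Protocol Type Term Source REF" = rep("", nrow(protocols)),
      "Study Protocol Description" = protocols$description,
      "Study Protocol URI" = rep("", nrow(protocols)),
      "Study Protocol Version" = rep("", nrow(protocols)),
      "Study Protocol Parameters Name" = protocols$parameters),
    isection("STUDY CONTACTS",
      "Study Person Last Name" = contact_cell("last_name"),
      "Study Person First Name" = contact_cell("first_name"),
      "Study Person Email" = contact_cell("email"),
      "Study Person Affiliation" = contact_cell("affiliation"),
      "Study Person Roles" = contact_cell("role"))
  )

  structure(
    list(investigation = investigation,
         study_table = list(header = study_header, rows = study_rows),
         assay_table = list(header = assay_header, rows = assay_rows),
         study_file = study_file, assay_file = assay_file,
         technology = dataset$technology),
    class = "isatab_document"
  )
}

isection <- function(name, ...) {
  rows <- list(...)
  list(name = name,
       rows = lapply(seq_along(rows), function(i) {
         list(label = names(rows)[i], cells = as.character(rows[[i]]))
       }))
}

pretty_key <- function(k) {
  s <- gsub("_", " ", k)
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' @export
print.isatab_document <- function(x, ...) {
  cat(sprintf("<isatab_document> %s | %d study row(s), %d assay row(s), %d assay column(s)\n",
              x$technology, length(x$study_table$rows), length(x$assay_table$rows),
              length(x$assay_table$header)))
  invisible(x)
}
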