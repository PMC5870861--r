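#' Extracted metadata containers
#'
#' A single extracted metadata value (a "param value") is one row of a
#' tibble with columns `term_key`, `term_accession`, `term_label`, `value`,
#' `unit_accession`, `unit_label`, `source_file` and `xml_path` (the
#' slash-joined element path where the value was found). `term_accession`
#' and `unit_accession` may be empty strings for free-text values, but a
#' nonempty accession always comes with a nonempty label.
#'
#' A `file_metadata` object is the complete extraction result for one data
#' file: the source file name, its technology, the param-value tibble
#' (ordered by the active ruleset), the ruleset's key order, and any
#' extraction warnings. Missing metadata is represented by key absence,
#' never by empty strings.
#'
#' @name metadata-model
NULL

param_value <- function(term_key, value, term_accession = "", term_label = "",
                        unit_accession = "", unit_label = "",
                        source_file = "", xml_path = "") {
  stopifnot(!(nzchar(term_accession) && !nzchar(term_label)),
            !(nzchar(unit_accession) && !nzchar(unit_label)))
  tibble(term_key = term_key, term_accession = term_accession,
         term_label = term_label, value = value,
         unit_accession = unit_accession, unit_label = unit_label,
         source_file = source_file, xml_path = xml_path)
}

empty_params <- function() {
  tibble(term_key = character(), term_accession = character(),
         term_label = character(), value = character(),
         unit_accession = character(), unit_label = character(),
         source_file = character(), xml_path = character())
}

new_file_metadata <- function(source_file, technology, entries, term_keys,
                              warnings = character()) {
  entries <- entries[entries$term_key %in% term_keys, ]
  # ruleset order between keys, document order within a key
  entries <- entries[order(match(entries$term_key, term_keys)), ]
  structure(
    list(source_file = source_file, technology = technology,
         entries = entries, term_keys = term_keys, warnings = warnings),
    class = "file_metadata"
  )
}

#' @export
print.file_metadata <- function(x, ...) {
  cat(sprintf("<file_metadata> %s (%s): %d term(s), %d warning(s)\n",
              x$source_file, x$technology,
              length(unique(x$entries$term_key)), length(x$warnings)))
  print(x$entries)
  invisible(x)
}

#' Tidy a file-metadata object into its param-value tibble
#' @param x A `file_metadata`.
#' @param ... Unused.
#' @export
tidy.file_metadata <- function(x, ...) x$entries

#' Render file metadata as canonical JSON
#'
#' Serializes a `file_metadata` object to UTF-8 JSON with top-level keys
#' `source_file`, `technology`, `entries` and `warnings`. `entries` is keyed
#' by term key in ruleset order; within a key, values appear in document
#' order as an array of objects (multi-valued keys keep their structure in
#' JSON even though ISA-Tab cells later flatten them). The serializer is
#' byte-deterministic: two calls on equal inputs produce identical output.
#' The JSON shape is documented by the schema in
#' `system.file("schema", "file-metadata.schema.json", package = "spec2isa")`.
#'
#' @param metadata A `file_metadata` object.
#' @return A single JSON string.
#' @export
to_canonical_json <- function(metadata) {
  stopifnot(inherits(metadata, "file_metadata"))
  keys <- intersect(metadata$term_keys, unique(metadata$entries$term_key))
  entry_json <- vapply(keys, function(k) {
    rows <- metadata$entries[metadata$entries$term_key == k, ]
    objs <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      paste0("{",
        json_kv("term_accession", r$term_accession), ",",
        json_kv("term_label", r$term_label), ",",
        json_kv("value", r$value), ",",
        json_kv("unit_accession", r$unit_accession), ",",
        json_kv("unit_label", r$unit_label), ",",
        json_kv("source_file", r$source_file), ",",
        json_kv("xml_path", r$xml_path),
      "}")
    }, "")
    paste0(json_str(k), ":[", paste(objs, collapse = ","), "]")
  }, "")
  paste0("{",
    json_kv("source_file", metadata$source_file), ",",
    json_kv("technology", metadata$technology), ",",
    "\"entries\":{", paste(entry_json, collapse = ","), "},",
    "\"warnings\":[",
      paste(vapply(metadata$warnings, json_str, ""), collapse = ","),
    "]}")
}

json_str <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

json_kv <- function(k, v) paste0(json_str(k), ":", json_str(v))

#' Describe a study for ISA-Tab assembly
#'
#' Holds the user-supplied study-level metadata that cannot be read from the
#' XML data files: minimally a study identifier, optionally title,
#' description, ISO-8601 submission/release dates, contacts, protocols and
#' extra parameter columns (e.g. chromatography details, which MS XML
#' formats do not carry).
#'
#' @param study_identifier Nonempty study identifier (required).
#' @param title,description,submission_date,release_date Optional text;
#'   dates must be ISO-8601 and are copied verbatim.
#' @param contacts Tibble with columns `last_name`, `first_name`, `email`,
#'   `affiliation`, `role` (zero rows allowed).
#' @param protocols Tibble with columns `name`, `type`, `description`;
#'   appended to the default protocol chain.
#' @param extra_parameters Named character vector or named list mapping a
#'   term key to a study-wide value, added as extra assay columns.
#' @return A `study_descriptor` object.
#' @export
study_descriptor <- function(study_identifier, title = "", description = "",
                             submission_date = "", release_date = "",
                             contacts = NULL, protocols = NULL,
                             extra_parameters = NULL) {
  if (!is.character(study_identifier) || length(study_identifier) != 1 ||
      !nzchar(study_identifier)) {
    stopf("study_identifier must be a nonempty string",
          class = "spec2isa_descriptor_error")
  }
  for (d in c(submission_date, release_date)) {
    if (nzchar(d) && !is_iso8601(d)) {
      stopf("date '%s' is not ISO-8601", d, class = "spec2isa_descriptor_error")
    }
  }
  contacts <- contacts %||%
    tibble(last_name = character(), first_name = character(),
           email = character(), affiliation = character(), role = character())
  protocols <- protocols %||%
    tibble(name = character(), type = character(), description = character())
  extra <- as.list(extra_parameters %||% list())
  structure(
    list(study_identifier = study_identifier, title = title,
         description = description, submission_date = submission_date,
         release_date = release_date, contacts = as_tibble(contacts),
         protocols = as_tibble(protocols), extra_parameters = extra),
    class = "study_descriptor"
  )
}

#' Read a study descriptor from a JSON file
#'
#' Accepts the user-metadata document: a JSON object with the
#' `study_descriptor` shape (`study_identifier` required; `title`,
#' `description`, `submission_date`, `release_date`, `contacts`,
#' `protocols`, `extra_parameters` optional).
#'
#' @param path Path to a JSON file.
#' @return A `study_descriptor`.
#' @export
read_study_descriptor <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  study_descriptor(
    study_identifier = x$study_identifier %||% "",
    title = x$title %||% "", description = x$description %||% "",
    submission_date = x$submission_date %||% "",
    release_date = x$release_date %||% "",
    contacts = x$contacts, protocols = x$protocols,
    extra_parameters = x$extra_parameters
  )
}

#' Merge per-file metadata into one study-level dataset
#'
#' Combines the extraction results of a corpus of files (all of one
#' technology) with the user-supplied study descriptor. The column union is
#' the ruleset-ordered union of term keys populated in at least one file;
#' descriptor extra parameters contribute additional columns. Files missing
#' a key later serialize as empty assay cells. File order is preserved and
#' the column union does not depend on it.
#'
#' @param files List of `file_metadata` objects (nonempty, same technology).
#' @param descriptor A `study_descriptor`.
#' @return A `study_dataset` object.
#' @export
merge_corpus <- function(files, descriptor) {
  if (length(files) == 0) {
    stopf("no input files", class = "spec2isa_merge_error")
  }
  stopifnot(all(vapply(files, inherits, TRUE, "file_metadata")),
            inherits(descriptor, "study_descriptor"))
  techs <- unique(vapply(files, `[[`, "", "technology"))
  if (length(techs) > 1) {
    stopf("mixed technologies in one corpus: %s", paste(techs, collapse = " vs "),
          class = "spec2isa_merge_error")
  }
  ruleset_keys <- files[[1]]$term_keys
  present <- unique(unlist(lapply(files, function(f) unique(f$entries$term_key))))
  column_union <- ruleset_keys[ruleset_keys %in% present]
  extra_keys <- setdiff(names(descriptor$extra_parameters), column_union)
  structure(
    list(descriptor = descriptor, files = files, technology = techs,
         column_union = c(column_union, extra_keys),
         ruleset_keys = ruleset_keys),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %s: %d file(s) [%s], %d metadata column(s)\n",
              x$descriptor$study_identifier, length(x$files), x$technology,
              length(x$column_union)))
  invisible(x)
}

#' Tidy a study dataset into one long param-value tibble
#' @param x A `study_dataset`.
#' @param ... Unused.
#' @export
tidy.study_dataset <- function(x, ...) {
  bind_rows(lapply(x$files, `[[`, "entries"))
}

#' One-row summary of a study dataset
#' @param x A `study_dataset`.
#' @param ... Unused.
#' @export
glance.study_dataset <- function(x, ...) {
  tibble(study_identifier = x$descriptor$study_identifier,
         technology = x$technology, n_files = length(x$files),
         n_columns = length(x$column_union),
         n_warnings = sum(lengths(lapply(x$files, `[[`, "warnings"))))
}

#' Heatmap of term coverage across a corpus
#'
#' Tile plot of file versus term key, showing which metadata terms were
#' captured in which files — a quick visual check of corpus completeness
#' before submission.
#'
#' @param object A `study_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_dataset <- function(object, ...) {
  long <- tidy(object)
  long <- distinct(long, .data$source_file, .data$term_key)
  long$term_key <- factor(long$term_key, levels = rev(object$ruleset_keys))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$source_file, y = .data$term_key)) +
    ggplot2::geom_tile(fill = "steelblue") +
    ggplot2::labs(x = "data file", y = "metadata term",
                  title = "Captured metadata terms per file") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
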