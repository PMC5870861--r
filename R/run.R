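#' Run the metadata-capture pipeline over a directory of files
#'
#' `run_ms()` processes a directory of mzML / imzML files (technology is
#' detected per file from the document root and vocabulary accessions, not
#' the file extension; imzML presence switches to the 42-term imaging
#' ruleset), `run_nmr()` a directory of nmrML files with the 46-term NMR
#' ruleset. Each file is extracted, the corpus is merged with the
#' user-supplied study descriptor, and the requested outputs are written:
#' an ISA-Tab tree (`i_`/`s_`/`a_` files) and/or one canonical JSON document
#' per input file. Files that fail to parse are skipped with a warning
#' rather than aborting the batch; the run fails only when no file succeeds.
#' A directory mixing mzML and imzML files is refused, since one assay
#' cannot span two technologies.
#'
#' @param input_dir Directory of input XML files.
#' @param output_dir Directory for outputs (created if needed).
#' @param study_identifier Study identifier (required unless `metadata`
#'   supplies one).
#' @param metadata Optional `study_descriptor`, or path to a JSON file with
#'   its shape.
#' @param ontology_paths Optional named character vector of OBO paths keyed
#'   by accession prefix, overriding the bundled vocabulary subsets.
#' @param output_mode `"both"`, `"isatab"` or `"json"`.
#' @param verbose Emit line-oriented progress messages with severity
#'   prefixes.
#' @return Invisibly, a `spec2isa_run`: list with `status` (0 on success),
#'   `dataset`, `outputs` (written paths), `failed` (files skipped) and
#'   `warnings` (tibble of file / term key / reason).
#' @export
run_ms <- function(input_dir, output_dir, study_identifier = NULL,
                   metadata = NULL, ontology_paths = NULL,
                   output_mode = c("both", "isatab", "json"),
                   verbose = FALSE) {
  run_pipeline(input_dir, output_dir, study_identifier, metadata,
               ontology_paths, match.arg(output_mode), verbose,
               pattern = "\\.(mzml|imzml)$", extractor = extract_mzml_metadata)
}

#' @rdname run_ms
#' @export
run_nmr <- function(input_dir, output_dir, study_identifier = NULL,
                    metadata = NULL, ontology_paths = NULL,
                    output_mode = c("both", "isatab", "json"),
                    verbose = FALSE) {
  run_pipeline(input_dir, output_dir, study_identifier, metadata,
               ontology_paths, match.arg(output_mode), verbose,
               pattern = "\\.nmrml$", extractor = extract_nmrml_metadata)
}

run_pipeline <- function(input_dir, output_dir, study_identifier, metadata,
                         ontology_paths, output_mode, verbose, pattern,
                         extractor) {
  if (!dir.exists(input_dir)) {
    stopf("input directory '%s' does not exist", input_dir,
          class = "spec2isa_usage_error")
  }
  descriptor <- if (inherits(metadata, "study_descriptor")) {
    metadata
  } else if (is.character(metadata) && length(metadata) == 1) {
    read_study_descriptor(metadata)
  } else if (!is.null(study_identifier)) {
    study_descriptor(study_identifier)
  } else {
    stopf("a study identifier is required (directly or via the metadata document)",
          class = "spec2isa_usage_error")
  }
  if (!is.null(study_identifier) && inherits(metadata, "study_descriptor") == FALSE &&
      is.character(metadata)) {
    # explicit flag wins over the metadata document
    descriptor$study_identifier <- study_identifier
  }

  say <- function(level, fmt, ...) {
    if (verbose) message(sprintf("%s: %s", level, sprintf(fmt, ...)))
  }

  paths <- sort(list.files(input_dir, full.names = TRUE))
  paths <- paths[grepl(pattern, tolower(paths))]
  if (length(paths) == 0) {
    stopf("no input files in '%s'", input_dir, class = "spec2isa_usage_error")
  }

  files <- list()
  failed <- character()
  for (p in paths) {
    fm <- tryCatch({
      reg <- if (is.null(ontology_paths)) NULL else {
        default_registries(read_xml_view(p)$technology, paths = ontology_paths)
      }
      extractor(p, registries = reg)
    }, error = function(e) {
      say("WARN", "%s skipped: %s", basename(p), conditionMessage(e))
      NULL
    })
    if (is.null(fm)) {
      failed <- c(failed, basename(p))
    } else {
      say("INFO", "%s: %d term(s) captured", fm$source_file,
          length(unique(fm$entries$term_key)))
      for (w in fm$warnings) say("WARN", "%s: %s", fm$source_file, w)
      files[[length(files) + 1L]] <- fm
    }
  }
  if (length(files) == 0) {
    stopf("all %d input file(s) failed to parse", length(paths),
          class = "spec2isa_run_error")
  }

  dataset <- merge_corpus(files, descriptor)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  if (output_mode %in% c("both", "isatab")) {
    doc <- build_isatab(dataset)
    outputs <- c(outputs, write_isatab(doc, output_dir))
  }
  if (output_mode %in% c("both", "json")) {
    for (fm in files) {
      jpath <- file.path(output_dir,
                         paste0(sub("\\.[A-Za-z0-9]+$", "", fm$source_file), ".json"))
      write_lf(to_canonical_json(fm), jpath)
      outputs <- c(outputs, jpath)
    }
  }
  say("INFO", "wrote %d output file(s) to %s", length(outputs), output_dir)

  warn_tbl <- bind_rows(lapply(files, function(fm) {
    if (length(fm$warnings) == 0) return(NULL)
    tibble(file = fm$source_file, reason = fm$warnings)
  }))

  invisible(structure(
    list(status = 0L, dataset = dataset, outputs = unname(outputs),
         failed = failed, warnings = warn_tbl),
    class = "spec2isa_run"
  ))
}

#' @export
print.spec2isa_run <- function(x, ...) {
  cat(sprintf("<spec2isa_run> status %d: %d file(s) processed, %d skipped, %d output(s)\n",
              x$status, length(x$dataset$files), length(x$failed), length(x$outputs)))
  invisible(x)
}
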