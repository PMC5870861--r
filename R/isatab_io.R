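#' Write an ISA-Tab document to disk
#'
#' Serializes the three tab-delimited files: `i_Investigation.txt`,
#' `s_<study identifier>.txt` and
#' `a_<study identifier>_<technology slug>.txt`. Output is UTF-8 without
#' BOM, LF line endings; any cell containing a tab, double quote or newline
#' is wrapped in double quotes with internal quotes doubled. Column order is
#' deterministic, so identical documents produce byte-identical trees.
#'
#' @param document An `isatab_document`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three written paths.
#' @export
write_isatab <- function(document, out_dir) {
  stopifnot(inherits(document, "isatab_document"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stopf("cannot write to directory '%s'", out_dir, class = "spec2isa_io_error")
  }
  inv <- file.path(out_dir, "i_Investigation.txt")
  stu <- file.path(out_dir, document$study_file)
  asy <- file.path(out_dir, document$assay_file)
  write_investigation(document$investigation, inv)
  write_isatab_table(document$study_table, stu)
  write_isatab_table(document$assay_table, asy)
  invisible(c(investigation = inv, study = stu, assay = asy))
}

tsv_escape <- function(cells) {
  needs <- grepl("[\t\"\n\r]", cells)
  cells[needs] <- paste0("\"", gsub("\"", "\"\"", cells[needs]), "\"")
  cells
}

tsv_line <- function(cells) paste(tsv_escape(cells), collapse = "\t")

write_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

write_investigation <- function(sections, path) {
  lines <- unlist(lapply(sections, function(sec) {
    c(sec$name, vapply(sec$rows, function(r) {
      cells <- if (length(r$cells)) r$cells else ""
      tsv_line(c(r$label, cells))
    }, ""))
  }))
  write_lf(lines, path)
}

write_isatab_table <- function(table, path) {
  lines <- c(tsv_line(table$header),
             vapply(table$rows, tsv_line, ""))
  write_lf(lines, path)
}

# Split one tab-delimited line honoring the quoting dialect.
tsv_split <- function(line) {
  out <- character()
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  buf <- character()
  i <- 1L
  in_quote <- FALSE
  field_quoted <- FALSE
  flush <- function() {
    val <- paste(buf, collapse = "")
    out[length(out) + 1L] <<- val
    buf <<- character()
    field_quoted <<- FALSE
  }
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "\"") {
        if (i < n && chars[i + 1] == "\"") {
          buf <- c(buf, "\"")
          i <- i + 1L
        } else {
          in_quote <- FALSE
        }
      } else {
        buf <- c(buf, ch)
      }
    } else if (ch == "\"" && length(buf) == 0 && !field_quoted) {
      in_quote <- TRUE
      field_quoted <- TRUE
    } else if (ch == "\t") {
      flush()
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  flush()
  out
}

read_isatab_table <- function(path) {
  raw <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  # quoted cells may contain newlines: rejoin lines with unbalanced quotes
  merged <- character()
  carry <- NULL
  for (ln in lines) {
    ln <- if (is.null(carry)) ln else paste0(carry, "\n", ln)
    nquotes <- lengths(regmatches(ln, gregexpr("\"", ln)))
    if (nquotes %% 2 == 1) carry <- ln else { merged <- c(merged, ln); carry <- NULL }
  }
  cells <- lapply(merged, tsv_split)
  list(header = cells[[1]], rows = cells[-1])
}

read_investigation <- function(path) {
  tab <- read_isatab_table(path)
  all_rows <- c(list(tab$header), tab$rows)
  sections <- list()
  current <- NULL
  for (cells in all_rows) {
    first <- cells[1]
    is_header <- length(cells) == 1 && grepl("^[A-Z][A-Z ]+$", first)
    if (is_header) {
      if (!is.null(current)) sections[[length(sections) + 1L]] <- current
      current <- list(name = first, rows = list())
    } else if (!is.null(current)) {
      current$rows[[length(current$rows) + 1L]] <-
        list(label = first, cells = if (length(cells) > 1) cells[-1] else "")
    }
  }
  if (!is.null(current)) sections[[length(sections) + 1L]] <- current
  sections
}

#' Read an ISA-Tab directory back into tabular form
#'
#' Parses `i_Investigation.txt` plus every study (`s_*.txt`) and assay
#' (`a_*.txt`) file in a directory using the package's tab-delimited
#' dialect. Used by the validator and to check that serialization is a
#' fixpoint (write, read, re-write yields byte-identical files).
#'
#' @param dir Directory holding an ISA-Tab tree.
#' @return List with `investigation` (sections), `studies` and `assays`
#'   (named lists of `header`/`rows` tables).
#' @export
read_isatab <- function(dir) {
  inv_path <- file.path(dir, "i_Investigation.txt")
  if (!file.exists(inv_path)) {
    stopf("no i_Investigation.txt in '%s'", dir, class = "spec2isa_io_error")
  }
  studies <- list()
  for (f in sort(list.files(dir, pattern = "^s_.*\\.txt$"))) {
    studies[[f]] <- read_isatab_table(file.path(dir, f))
  }
  assays <- list()
  for (f in sort(list.files(dir, pattern = "^a_.*\\.txt$"))) {
    assays[[f]] <- read_isatab_table(file.path(dir, f))
  }
  list(investigation = read_investigation(inv_path),
       studies = studies, assays = assays)
}

# re-serialize a parsed ISA-Tab tree with the package writers (fixpoint check)
isatab_rewrite <- function(dir, out_dir) {
  tree <- read_isatab(dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_investigation(tree$investigation, file.path(out_dir, "i_Investigation.txt"))
  for (f in names(tree$studies)) write_isatab_table(tree$studies[[f]], file.path(out_dir, f))
  for (f in names(tree$assays)) write_isatab_table(tree$assays[[f]], file.path(out_dir, f))
  invisible(out_dir)
}

inv_section <- function(sections, name) {
  for (s in sections) if (s$name == name) return(s)
  NULL
}

inv_row <- function(section, label) {
  if (is.null(section)) return(NULL)
  for (r in section$rows) if (r$label == label) return(r$cells)
  NULL
}

#' Structurally validate an ISA-Tab directory
#'
#' Self-contained structural checks modeled on the reference ISA validator:
#' the three file types exist and parse; the investigation declares every
#' Term Source REF used in the tables; every assay Sample Name resolves in
#' a study file; ontology-annotation triples are complete (an accession
#' requires a term source and a value); every `Parameter Value[...]` column
#' is declared by a protocol's parameter list; and every table row has as
#' many cells as its header. Problems are reported as findings with
#' machine-readable codes, never as R errors.
#'
#' @param dir Directory holding an ISA-Tab tree.
#' @return An `isatab_validation` object: `passed` (no error findings) and
#'   a `findings` tibble with columns `severity`, `code`, `message`,
#'   `location`.
#' @export
validate_isatab <- function(dir) {
  f <- list()
  add <- function(severity, code, message, location) {
    f[[length(f) + 1L]] <<- tibble(severity = severity, code = code,
                                   message = message, location = location)
  }

  inv_path <- file.path(dir, "i_Investigation.txt")
  if (!file.exists(inv_path)) {
    add("error", "missing-investigation-file", "no i_Investigation.txt found", dir)
    return(validation_result(f))
  }
  study_files <- sort(list.files(dir, pattern = "^s_.*\\.txt$"))
  assay_files <- sort(list.files(dir, pattern = "^a_.*\\.txt$"))
  if (length(study_files) == 0) add("error", "missing-study-file", "no s_*.txt found", dir)
  if (length(assay_files) == 0) add("error", "missing-assay-file", "no a_*.txt found", dir)

  inv <- tryCatch(read_investigation(inv_path), error = function(e) {
    add("error", "parse-error", conditionMessage(e), "i_Investigation.txt")
    NULL
  })
  if (is.null(inv) || length(f) && any(vapply(f, function(x) x$code, "") %in%
                                       c("missing-study-file", "missing-assay-file"))) {
    if (is.null(inv)) return(validation_result(f))
  }

  declared_sources <- inv_row(inv_section(inv, "ONTOLOGY SOURCE REFERENCE"),
                              "Term Source Name") %||% character()
  declared_sources <- declared_sources[nzchar(declared_sources)]

  declared_study <- inv_row(inv_section(inv, "STUDY"), "Study File Name") %||% character()
  declared_assay <- inv_row(inv_section(inv, "STUDY ASSAYS"), "Study Assay File Name") %||% character()
  for (df in c(declared_study, declared_assay)) {
    if (nzchar(df) && !file.exists(file.path(dir, df))) {
      add("error", "missing-declared-file",
          sprintf("investigation declares '%s' but the file is absent", df),
          "i_Investigation.txt")
    }
  }

  proto_params <- inv_row(inv_section(inv, "STUDY PROTOCOLS"),
                          "Study Protocol Parameters Name") %||% character()
  declared_params <- unlist(strsplit(proto_params, ";", fixed = TRUE))
  declared_params <- trimws(declared_params[nzchar(declared_params)])

  read_table_checked <- function(fname) {
    tryCatch(read_isatab_table(file.path(dir, fname)), error = function(e) {
      add("error", "parse-error", conditionMessage(e), fname)
      NULL
    })
  }

  check_table <- function(tab, fname) {
    hl <- length(tab$header)
    for (i in seq_along(tab$rows)) {
      if (length(tab$rows[[i]]) != hl) {
        add("error", "ragged-row",
            sprintf("row %d has %d cells, header has %d", i,
                    length(tab$rows[[i]]), hl), fname)
      }
    }
    cell <- function(row, j) if (j <= length(row)) row[j] else ""
    # annotation triples around every Term Source REF column
    for (j in which(tab$header == "Term Source REF")) {
      acc_col <- if (j < hl && tab$header[j + 1] == "Term Accession Number") j + 1L else NA
      for (i in seq_along(tab$rows)) {
        row <- tab$rows[[i]]
        src <- cell(row, j)
        acc <- if (!is.na(acc_col)) cell(row, acc_col) else ""
        val <- cell(row, j - 1L)
        if (nzchar(acc) && (!nzchar(src) || !nzchar(val))) {
          add("error", "incomplete-annotation",
              sprintf("row %d column %d: accession '%s' lacks %s", i, j, acc,
                      if (nzchar(src)) "a value" else "a Term Source REF"), fname)
        }
        if (nzchar(src) && !src %in% declared_sources) {
          add("error", "undeclared-term-source",
              sprintf("row %d uses Term Source REF '%s' not declared in the investigation",
                      i, src), fname)
        }
      }
    }
  }

  sample_names <- character()
  for (sf in study_files) {
    tab <- read_table_checked(sf)
    if (is.null(tab)) next
    check_table(tab, sf)
    sn <- which(tab$header == "Sample Name")
    if (length(sn) == 0) {
      add("error", "missing-sample-name-column", "study table has no Sample Name column", sf)
    } else {
      sample_names <- c(sample_names,
                        vapply(tab$rows, function(r) if (sn[1] <= length(r)) r[sn[1]] else "", ""))
    }
  }

  for (af in assay_files) {
    tab <- read_table_checked(af)
    if (is.null(tab)) next
    check_table(tab, af)
    sn <- which(tab$header == "Sample Name")
    if (length(sn) == 0) {
      add("error", "missing-sample-name-column", "assay table has no Sample Name column", af)
    } else {
      for (i in seq_along(tab$rows)) {
        s <- if (sn[1] <= length(tab$rows[[i]])) tab$rows[[i]][sn[1]] else ""
        if (!s %in% sample_names) {
          add("error", "unresolved-sample-name",
              sprintf("assay row %d Sample Name '%s' not found in any study file", i, s), af)
        }
      }
    }
    pv <- grepl("^Parameter Value\\[.*\\]$", tab$header)
    for (lab in sub("^Parameter Value\\[(.*)\\]$", "\\1", tab$header[pv])) {
      if (!lab %in% declared_params) {
        add("error", "undeclared-parameter",
            sprintf("Parameter Value[%s] is not declared by any protocol", lab), af)
      }
    }
  }

  validation_result(f)
}

validation_result <- function(findings) {
  tbl <- if (length(findings)) bind_rows(findings) else
    tibble(severity = character(), code = character(),
           message = character(), location = character())
  structure(list(passed = !any(tbl$severity == "error"), findings = tbl),
            class = "isatab_validation")
}

#' @export
print.isatab_validation <- function(x, ...) {
  cat(sprintf("<isatab_validation> %s: %d finding(s)\n",
              if (x$passed) "PASSED" else "FAILED", nrow(x$findings)))
  if (nrow(x$findings)) print(x$findings)
  invisible(x)
}

#' Tidy a validation report into its findings tibble
#' @param x An `isatab_validation`.
#' @param ... Unused.
#' @export
tidy.isatab_validation <- function(x, ...) x$findings

#' One-row summary of a validation report
#' @param x An `isatab_validation`.
#' @param ... Unused.
#' @export
glance.isatab_validation <- function(x, ...) {
  tibble(passed = x$passed,
         n_errors = sum(x$findings$severity == "error"),
         n_warnings = sum(x$findings$severity == "warning"))
}
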