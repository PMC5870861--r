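#' Extract instrument metadata from one data file
#'
#' Runs the extraction ruleset over an mzML, imzML or nmrML document:
#' referenceable parameter groups are dereferenced, every cvParam inside a
#' rule's scope is matched against the rule's vocabulary target (exactly or
#' as a subtree descendant), nmrML's structural attributes and value
#' elements are read by their dedicated rules, and the per-spectrum facts of
#' MS files are aggregated into file-level summaries (scan count, polarity,
#' m/z range, spectrum representation). Unmatched rules are simply absent
#' from the result; cvParams whose accessions do not resolve in the supplied
#' vocabularies produce a warning and keep the file-supplied name as their
#' label. `userParam` elements are ignored (no default rule targets them).
#' The instrument manufacturer is derived from the instrument model term as
#' its vendor-family ancestor: the ancestor that is a direct child of the
#' instrument-model root, which is how the PSI-MS vocabulary organizes
#' vendor subtrees.
#'
#' Technology is detected from the document, not the file name: an `nmrML`
#' root is NMR; an `mzML` (or `indexedmzML`) root is imaging MS when any
#' `IMS:` accession is present, plain MS otherwise. When several
#' `instrumentConfiguration` elements are present the first is used and a
#' warning lists the ignored ones.
#'
#' @param path Path to the XML file.
#' @param registries List of `cv_registry` objects; defaults to the bundled
#'   vocabulary subsets for the detected technology.
#' @param rules Extraction-rule tibble; defaults to the technology's
#'   default ruleset.
#' @return A `file_metadata` object.
#' @export
extract_file_metadata <- function(path, registries = NULL, rules = NULL) {
  view <- read_xml_view(path)
  registries <- registries %||% default_registries(view$technology)
  rules <- rules %||% default_ruleset(view$technology)
  extract_from_view(view, registries, rules, basename(path))
}

#' @rdname extract_file_metadata
#' @details `extract_mzml_metadata()` and `extract_nmrml_metadata()` guard
#'   the technology: feeding an nmrML file to the MS extractor (or an mzML
#'   file to the NMR extractor) raises an error that names the offending
#'   format rather than returning a silent partial result.
#' @export
extract_mzml_metadata <- function(path, registries = NULL, rules = NULL) {
  view <- read_xml_view(path)
  if (view$root != "mzML") {
    stopf("extraction error: '%s' has an nmrML root, not mzML; use the NMR extractor",
          basename(path), class = "spec2isa_extraction_error")
  }
  registries <- registries %||% default_registries(view$technology)
  rules <- rules %||% default_ruleset(view$technology)
  extract_from_view(view, registries, rules, basename(path))
}

#' @rdname extract_file_metadata
#' @export
extract_nmrml_metadata <- function(path, registries = NULL, rules = NULL) {
  view <- read_xml_view(path)
  if (view$root != "nmrML") {
    stopf("extraction error: '%s' looks like mzML (root '%s'), not nmrML",
          basename(path), view$root, class = "spec2isa_extraction_error")
  }
  registries <- registries %||% default_registries("nmrML")
  rules <- rules %||% default_nmrml_ruleset()
  extract_from_view(view, registries, rules, basename(path))
}

extract_from_view <- function(view, registries, rules, source_file) {
  view <- dereference_param_groups(view)
  warnings <- character()
  params <- view$params

  # single-instrument policy: only the first instrumentConfiguration counts
  cfg <- xml2::xml_find_all(view$doc, ".//instrumentConfigurationList/instrumentConfiguration")
  if (length(cfg) > 1) {
    cfg_paths <- vapply(cfg, xml2::xml_path, "")
    ids <- xml2::xml_attr(cfg, "id")
    warnings <- c(warnings, sprintf(
      "multiple instrumentConfiguration elements; using the first, ignoring: %s",
      paste(ids[-1], collapse = ", ")))
    drop <- rep(FALSE, nrow(params))
    for (cp in cfg_paths[-1]) drop <- drop | under_path(params$parent_raw, cp)
    params <- params[!drop, ]
  }

  unresolved_seen <- character()
  entries <- list()

  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    vals <- switch(r$source,
      "cvParam" = {
        cand <- params[params$kind == "cvParam" &
                         scope_match(params$parent_norm, r$xml_scope), ]
        matched <- cand[vapply(seq_len(nrow(cand)), function(j) {
          cv_matches(cand$accession[j], r, registries)
        }, FALSE), ]
        rows <- list()
        for (j in seq_len(nrow(matched))) {
          m <- matched[j, ]
          term <- registries_resolve(registries, m$accession)
          if (is.null(term)) {
            if (!m$accession %in% unresolved_seen) {
              unresolved_seen <- c(unresolved_seen, m$accession)
              warnings <- c(warnings, sprintf(
                "accession %s does not resolve in the supplied vocabularies; keeping file-supplied name '%s'",
                m$accession, m$name))
            }
            label <- m$name
          } else {
            label <- term$label
            if (term$obsolete) {
              warnings <- c(warnings, sprintf(
                "obsolete term %s (%s) matched for %s", m$accession, label, r$term_key))
            }
          }
          rows[[j]] <- param_value(
            r$term_key,
            value = if (nzchar(m$value)) m$value else label,
            term_accession = m$accession, term_label = label,
            unit_accession = m$unit_accession, unit_label = m$unit_label,
            source_file = source_file, xml_path = m$parent_norm)
        }
        bind_rows(rows)
      },
      "attribute" = {
        els <- matching_elements(view$doc, r$element, r$xml_scope)
        vals <- xml2::xml_attr(els, r$attribute)
        keep <- !is.na(vals)
        rows <- lapply(which(keep), function(j) {
          param_value(r$term_key, value = vals[j],
                      term_label = r$isa_field,
                      source_file = source_file,
                      xml_path = norm_path(xml2::xml_path(els[[j]])))
        })
        bind_rows(rows)
      },
      "value-element" = {
        els <- matching_elements(view$doc, r$element, r$xml_scope)
        rows <- list()
        for (j in seq_along(els)) {
          v <- xml2::xml_attr(els[[j]], "value")
          if (is.na(v)) next
          ua <- xml2::xml_attr(els[[j]], "unitAccession")
          ul <- xml2::xml_attr(els[[j]], "unitName")
          rows[[length(rows) + 1L]] <- param_value(
            r$term_key, value = v, term_label = r$isa_field,
            unit_accession = if (is.na(ua)) "" else ua,
            unit_label = if (is.na(ul)) "" else ul,
            source_file = source_file,
            xml_path = norm_path(xml2::xml_path(els[[j]])))
        }
        bind_rows(rows)
      },
      "summary" = NULL,   # handled once below
      "derived" = NULL,   # handled after instrument_model
      empty_params()
    )
    if (!is.null(vals) && nrow(vals)) {
      if (r$aggregation == "first" && nrow(vals) > 1) {
        if (r$cardinality == "single") {
          warnings <- c(warnings, sprintf(
            "multiple matches for %s; keeping the first", r$term_key))
        }
        vals <- vals[1, ]
      }
      entries[[length(entries) + 1L]] <- vals
    }
  }

  entries <- bind_rows(entries)
  if (nrow(entries) == 0) entries <- empty_params()

  # spectra-level summaries (MS technologies only)
  if (any(rules$source == "summary")) {
    sm <- summarize_spectra(view, source_file)
    entries <- bind_rows(entries, sm$params)
    warnings <- c(warnings, sm$warnings)
  }

  # derived manufacturer
  drv <- rules[rules$source == "derived", ]
  for (i in seq_len(nrow(drv))) {
    r <- drv[i, ]
    model <- entries[entries$term_key == "instrument_model", ]
    if (nrow(model) == 0 || !nzchar(model$term_accession[1])) next
    reg <- registries_for_prefix(registries, acc_prefix(model$term_accession[1]))
    fam <- vendor_family(reg, model$term_accession[1], r$cv_target)
    if (is.null(fam)) next
    entries <- bind_rows(entries, param_value(
      r$term_key, value = fam$label, term_accession = fam$accession,
      term_label = fam$label, source_file = source_file,
      xml_path = model$xml_path[1]))
  }

  new_file_metadata(source_file, view$technology, entries,
                    term_keys = rules$term_key, warnings = warnings)
}

cv_matches <- function(accession, r, registries) {
  if (identical(r$match_mode, "exact")) return(accession == r$cv_target)
  if (acc_prefix(accession) != acc_prefix(r$cv_target)) return(FALSE)
  reg <- registries_for_prefix(registries, acc_prefix(accession))
  if (is.null(reg) || !accession %in% reg$terms$accession) return(FALSE)
  is_descendant(reg, accession, r$cv_target)
}

matching_elements <- function(doc, element, scope) {
  els <- xml2::xml_find_all(doc, paste0(".//", element))
  if (length(els) == 0) return(els)
  paths <- norm_path(vapply(els, xml2::xml_path, ""))
  els[scope_match(paths, scope)]
}

# the ancestor of `model` (possibly model itself) that is a direct child of
# the instrument-model root: the vocabulary's vendor family
vendor_family <- function(registry, model, root) {
  if (is.null(registry) || !model %in% registry$terms$accession) return(NULL)
  root_children <- registry$terms$accession[vapply(
    registry$terms$parent_accessions, function(p) root %in% p, FALSE)]
  frontier <- model
  seen <- character()
  while (length(frontier)) {
    hit <- intersect(frontier, root_children)
    if (length(hit)) {
      t <- registry$terms[registry$terms$accession == hit[1], ]
      return(list(accession = t$accession, label = t$label))
    }
    seen <- c(seen, frontier)
    nxt <- unique(unlist(registry$parents[frontier], use.names = FALSE))
    frontier <- setdiff(intersect(nxt, registry$terms$accession), seen)
  }
  NULL
}

#' Summarize per-spectrum facts into file-level descriptors
#'
#' Aggregates the spectrum list of an MS document into the four summary
#' keys: `scan_count` (the declared `spectrumList` count when present, with
#' the element count winning over a mismatching declaration), `scan_polarity`
#' (`"positive scan"` / `"negative scan"` when uniform, the literal
#' `"alternating scan"` when both occur), `mz_range` (min over scan-window
#' lower limits to max over upper limits, rendered `"L-U"` with trailing
#' `".0"` stripped for integral values) and `spectrum_representation`
#' (profile/centroid; both values when mixed). A missing spectrum list
#' degrades to a warning with all four keys absent.
#'
#' @param view An `xml_document_view` (mzML or imzML).
#' @param source_file File name recorded in the resulting values.
#' @return List with `params` (param-value tibble) and `warnings`.
#' @export
summarize_spectra <- function(view, source_file = "") {
  warnings <- character()
  slist <- xml2::xml_find_first(view$doc, ".//run/spectrumList")
  if (inherits(slist, "xml_missing")) {
    return(list(params = empty_params(),
                warnings = "no spectrumList present; spectra summaries absent"))
  }
  spectra <- xml2::xml_find_all(slist, "./spectrum")
  n <- length(spectra)
  declared <- xml2::xml_attr(slist, "count")
  if (!is.na(declared) && as.integer(declared) != n) {
    warnings <- c(warnings, sprintf(
      "spectrumList declares count %s but holds %d spectrum elements; using the element count",
      declared, n))
  }
  base_path <- norm_path(xml2::xml_path(slist))
  params <- view$params
  rows <- list(param_value("scan_count", value = as.character(n),
                           term_label = "Number of scans",
                           source_file = source_file, xml_path = base_path))

  pol <- character(); rep_acc <- character(); lo <- numeric(); hi <- numeric()
  for (sp in spectra) {
    sp_path <- xml2::xml_path(sp)
    within <- params[params$kind == "cvParam" &
                       under_path(params$parent_raw, sp_path), ]
    if ("MS:1000130" %in% within$accession) pol <- c(pol, "positive scan")
    if ("MS:1000129" %in% within$accession) pol <- c(pol, "negative scan")
    rep_acc <- c(rep_acc, intersect(within$accession, c("MS:1000128", "MS:1000127")))
    lo <- c(lo, as.numeric(within$value[within$accession == "MS:1000501"]))
    hi <- c(hi, as.numeric(within$value[within$accession == "MS:1000500"]))
  }

  upol <- unique(pol)
  if (length(upol) == 1) {
    acc <- if (upol == "positive scan") "MS:1000130" else "MS:1000129"
    rows[[length(rows) + 1L]] <- param_value(
      "scan_polarity", value = upol, term_accession = acc, term_label = upol,
      source_file = source_file, xml_path = base_path)
  } else if (length(upol) == 2) {
    rows[[length(rows) + 1L]] <- param_value(
      "scan_polarity", value = "alternating scan", term_label = "alternating scan",
      source_file = source_file, xml_path = base_path)
  }

  if (length(lo) && length(hi)) {
    rows[[length(rows) + 1L]] <- param_value(
      "mz_range", value = paste0(fmt_num(min(lo)), "-", fmt_num(max(hi))),
      term_label = "Scan m/z range", source_file = source_file,
      xml_path = base_path)
  }

  rep_labels <- c("MS:1000128" = "profile spectrum", "MS:1000127" = "centroid spectrum")
  for (acc in unique(rep_acc)) {
    rows[[length(rows) + 1L]] <- param_value(
      "spectrum_representation", value = rep_labels[[acc]],
      term_accession = acc, term_label = rep_labels[[acc]],
      source_file = source_file, xml_path = base_path)
  }

  list(params = bind_rows(rows), warnings = warnings)
}
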