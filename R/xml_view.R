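#' Parse a data file into an XML document view
#'
#' Reads an mzML, imzML or nmrML document into a namespace-normalized view:
#' XML namespaces are stripped to local names (both the mzML 1.0 and 1.1
#' namespace URIs are accepted this way), `indexedmzML` wrappers are
#' transparently unwrapped (the index is ignored), and every `cvParam` and
#' `referenceableParamGroupRef` in the document is collected into a tabular
#' record set with its element path. Binary payloads are never decoded.
#'
#' @param path Path to an XML file.
#' @return An `xml_document_view`: list with `doc` (the xml2 document),
#'   `root` (local name of the effective root), `technology` (`"mzML"`,
#'   `"imzML"` or `"nmrML"`), `params` (tibble of raw cvParam /
#'   group-reference records), `groups` (named list of referenceable
#'   param-group record tibbles) and `dereferenced` flag.
#' @export
read_xml_view <- function(path) {
  if (!file.exists(path)) {
    stopf("cannot read '%s': no such file", path, class = "spec2isa_io_error")
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stopf("extraction error: '%s' is not well-formed XML (%s)",
                          basename(path), conditionMessage(e),
                          class = "spec2isa_extraction_error")
                  })
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_name(xml2::xml_root(doc))
  effective_root <- if (root == "indexedmzML") "mzML" else root
  if (!effective_root %in% c("mzML", "nmrML")) {
    stopf("extraction error: unknown XML root element '%s' in '%s'",
          root, basename(path), class = "spec2isa_extraction_error")
  }

  nodes <- xml2::xml_find_all(doc, ".//cvParam | .//referenceableParamGroupRef")
  params <- param_records(nodes)

  group_nodes <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  groups <- list()
  for (g in group_nodes) {
    gid <- xml2::xml_attr(g, "id")
    groups[[gid]] <- param_records(xml2::xml_find_all(g, "./cvParam"))
  }

  technology <- if (effective_root == "nmrML") {
    "nmrML"
  } else if (any(acc_prefix(params$accession[params$kind == "cvParam"]) == "IMS")) {
    "imzML"
  } else {
    "mzML"
  }

  structure(
    list(doc = doc, root = effective_root, technology = technology,
         params = params, groups = groups, dereferenced = FALSE),
    class = "xml_document_view"
  )
}

param_records <- function(nodes) {
  n <- length(nodes)
  if (n == 0) {
    return(tibble(kind = character(), parent_raw = character(),
                  parent_norm = character(), accession = character(),
                  name = character(), value = character(),
                  unit_accession = character(), unit_label = character(),
                  ref_id = character(), origin = character()))
  }
  kind <- xml2::xml_name(nodes)
  parent_raw <- vapply(seq_len(n), function(i) {
    xml2::xml_path(xml2::xml_parent(nodes[[i]]))
  }, "")
  attr_or <- function(a) {
    v <- xml2::xml_attr(nodes, a)
    ifelse(is.na(v), "", v)
  }
  tibble(
    kind = ifelse(kind == "cvParam", "cvParam", "groupRef"),
    parent_raw = parent_raw,
    parent_norm = norm_path(parent_raw),
    accession = attr_or("accession"),
    name = attr_or("name"),
    value = attr_or("value"),
    unit_accession = attr_or("unitAccession"),
    unit_label = attr_or("unitName"),
    ref_id = attr_or("ref"),
    origin = "local"
  )
}

norm_path <- function(p) gsub("\\[\\d+\\]", "", p)

# path containment at segment boundaries
scope_match <- function(norm, scope) {
  grepl(paste0("(^|/)", scope, "(/|$)"), norm)
}

# TRUE where `paths` lie at or below the element at `prefix` (raw paths)
under_path <- function(paths, prefix) {
  paths == prefix | startsWith(paths, paste0(prefix, "/"))
}

#' Expand referenceable parameter groups in place
#'
#' Replaces every `referenceableParamGroupRef` by the referenced group's
#' cvParam records, inserted before the locally declared params of the same
#' element; a local cvParam with the same accession as a group cvParam
#' overrides it. After expansion the group definitions themselves are
#' removed from the record set, so no record retains an unexpanded
#' reference. A document with no group references is returned unchanged.
#'
#' @param view An `xml_document_view`.
#' @return The view with expanded `params` and `dereferenced = TRUE`.
#' @export
dereference_param_groups <- function(view) {
  stopifnot(inherits(view, "xml_document_view"))
  p <- view$params
  refs <- which(p$kind == "groupRef")
  if (length(refs) == 0) {
    view$dereferenced <- TRUE
    return(view)
  }
  pieces <- list()
  for (i in seq_len(nrow(p))) {
    row <- p[i, ]
    if (row$kind == "cvParam") {
      pieces[[length(pieces) + 1L]] <- row
      next
    }
    gid <- row$ref_id
    grp <- view$groups[[gid]]
    if (is.null(grp)) {
      stopf("extraction error: reference to undeclared referenceableParamGroup '%s'",
            gid, class = "spec2isa_extraction_error")
    }
    if (nrow(grp)) {
      inj <- grp
      inj$parent_raw <- row$parent_raw
      inj$parent_norm <- row$parent_norm
      inj$origin <- "group"
      pieces[[length(pieces) + 1L]] <- inj
    }
  }
  out <- bind_rows(pieces)
  # local params override group-injected params with the same accession
  # within the same host element
  drop <- logical(nrow(out))
  grp_rows <- which(out$origin == "group")
  for (i in grp_rows) {
    same <- out$parent_raw == out$parent_raw[i] &
      out$accession == out$accession[i] & out$origin == "local"
    if (any(same)) drop[i] <- TRUE
  }
  out <- out[!drop, ]
  # the group definitions themselves are not extraction sites
  out <- out[!grepl("(^|/)referenceableParamGroupList(/|$)", out$parent_norm), ]
  view$params <- out
  view$dereferenced <- TRUE
  view
}
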