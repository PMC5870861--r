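#' Load an OBO-format controlled vocabulary
#'
#' Parses an OBO 1.2/1.4 flat file into a searchable vocabulary registry.
#' Only the stanza tags `id`, `name`, `is_a`, `namespace` and `is_obsolete`
#' and the header tag `data-version` are interpreted; every other tag line is
#' ignored. One term is created per `[Term]` stanza, so no stanza is silently
#' lost. Parent accessions that do not resolve within the loaded file are
#' recorded in the registry's `unresolved_parents` rather than dropped, and
#' `is_a` cycles are detected at load time and flagged in the registry log.
#'
#' @param source Path to an OBO file, or a character vector holding OBO text
#'   (either one string with embedded newlines or one element per line).
#' @return A `cv_registry` object: a list with elements `namespace`
#'   (vocabulary id: `"MS"`, `"IMS"` or `"NMRCV"`), `prefix` (accession
#'   prefix), `version` (the header `data-version`, `""` if absent), `terms`
#'   (a tibble with columns `accession`, `label`, `namespace`, `obsolete` and
#'   the list-column `parent_accessions`), `unresolved_parents` and a `log`
#'   environment collecting lookup warnings.
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: MS:1", "name: root", "",
#'          "[Term]", "id: MS:2", "name: child", "is_a: MS:1 ! root")
#' reg <- load_obo(obo)
#' reg$terms
#' @export
load_obo <- function(source) {
  lines <- obo_lines(source)
  if (length(lines) == 0) stopf("OBO load error: no terms", class = "spec2isa_obo_error")

  # header = everything before the first stanza
  stanza_starts <- grep("^\\[", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1] - 1L else length(lines)
  header <- lines[seq_len(header_end)]
  version <- tag_value(header, "data-version") %||% ""

  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) {
    stopf("OBO load error: no terms", class = "spec2isa_obo_error")
  }
  bounds <- c(stanza_starts, length(lines) + 1L)

  terms <- vector("list", length(term_starts))
  for (i in seq_along(term_starts)) {
    s <- term_starts[i]
    e <- bounds[match(s, bounds) + 1L] - 1L
    block <- lines[(s + 1L):e]
    id <- tag_value(block, "id")
    if (is.null(id)) {
      stopf("OBO load error: [Term] stanza %d has no id tag", i,
            class = "spec2isa_obo_error")
    }
    parents <- tag_values(block, "is_a")
    parents <- setdiff(parents, id)  # no self-loops
    terms[[i]] <- list(
      accession = id,
      label = tag_value(block, "name") %||% "",
      obsolete = identical(tolower(tag_value(block, "is_obsolete") %||% "false"), "true"),
      parents = parents
    )
  }

  acc <- vapply(terms, `[[`, "", "accession")
  prefix <- acc_prefix(acc[1])
  namespace <- unname(PREFIX_TO_SOURCE[prefix] %||% prefix)
  if (is.na(namespace)) namespace <- prefix

  tbl <- tibble(
    accession = acc,
    label = vapply(terms, `[[`, "", "label"),
    namespace = namespace,
    obsolete = vapply(terms, `[[`, FALSE, "obsolete"),
    parent_accessions = lapply(terms, `[[`, "parents")
  )

  all_parents <- unique(unlist(tbl$parent_accessions))
  unresolved <- setdiff(all_parents, tbl$accession)

  reg <- structure(
    list(
      namespace = namespace,
      prefix = prefix,
      version = version,
      terms = tbl,
      parents = stats::setNames(tbl$parent_accessions, tbl$accession),
      unresolved_parents = unresolved,
      log = new.env(parent = emptyenv())
    ),
    class = "cv_registry"
  )
  reg$log$messages <- character()

  cycles <- detect_cycles(reg)
  if (length(cycles)) {
    registry_log(reg, sprintf("is_a cycle detected involving: %s",
                              paste(cycles, collapse = ", ")))
  }
  reg
}

obo_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  trimws(lines, which = "right")
}

tag_value <- function(lines, tag) {
  v <- tag_values(lines, tag)
  if (length(v) == 0) NULL else v[1]
}

tag_values <- function(lines, tag) {
  pat <- paste0("^", tag, ":")
  hits <- lines[grepl(pat, lines)]
  if (length(hits) == 0) return(character())
  v <- sub(pat, "", hits)
  v <- sub("\\s*!.*$", "", v)  # strip trailing OBO comment
  trimws(v)
}

registry_log <- function(registry, message) {
  registry$log$messages <- c(registry$log$messages, message)
  invisible(message)
}

#' Retrieve warnings accumulated in a registry's log channel
#' @param registry A `cv_registry`.
#' @return Character vector of log messages.
#' @export
registry_warnings <- function(registry) registry$log$messages

detect_cycles <- function(registry) {
  color <- new.env(parent = emptyenv())
  in_cycle <- character()
  visit <- function(a, stack) {
    st <- get0(a, envir = color, ifnotfound = "white")
    if (st == "grey") {
      in_cycle <<- union(in_cycle, stack[which(stack == a)[1]:length(stack)])
      return()
    }
    if (st == "black") return()
    assign(a, "grey", envir = color)
    for (p in registry$parents[[a]] %||% character()) {
      if (p %in% names(registry$parents)) visit(p, c(stack, p))
    }
    assign(a, "black", envir = color)
  }
  for (a in names(registry$parents)) visit(a, a)
  in_cycle
}

#' Resolve an accession to its vocabulary term
#'
#' Exact-match lookup; a miss is a value (`NULL`), never an error. Looking up
#' an accession whose prefix does not match the registry's vocabulary logs a
#' namespace-mismatch warning in the registry's log channel and returns
#' `NULL`, so mixed-vocabulary files (imzML carries `MS:` and `IMS:`
#' accessions side by side) never abort extraction. Obsolete terms resolve
#' normally but carry `obsolete = TRUE`.
#'
#' @param registry A `cv_registry`.
#' @param accession Accession string, e.g. `"MS:1000031"`.
#' @return A one-row tibble (the term), or `NULL` when not found.
#' @export
resolve_accession <- function(registry, accession) {
  if (acc_prefix(accession) != registry$prefix) {
    registry_log(registry, sprintf(
      "namespace mismatch: %s looked up in %s registry", accession, registry$namespace))
    return(NULL)
  }
  hit <- registry$terms[registry$terms$accession == accession, ]
  if (nrow(hit) == 0) NULL else hit
}

#' Test is_a reachability between two vocabulary terms
#'
#' `TRUE` iff `root` is reachable from `accession` by zero or more `is_a`
#' edges. The relation is reflexive: every term is its own descendant, so a
#' rule matching "any term under root R" includes R itself. Traversal keeps a
#' visited set, so cyclic vocabularies terminate.
#'
#' @param registry A `cv_registry`.
#' @param accession Accession of the candidate descendant.
#' @param root Accession of the candidate ancestor.
#' @return Logical scalar.
#' @export
is_descendant <- function(registry, accession, root) {
  for (a in c(accession, root)) {
    if (!a %in% registry$terms$accession) {
      stopf("query error: accession %s does not resolve in the %s registry",
            a, registry$namespace, class = "spec2isa_query_error")
    }
  }
  frontier <- accession
  seen <- character()
  while (length(frontier)) {
    if (root %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    nxt <- unique(unlist(registry$parents[frontier], use.names = FALSE))
    frontier <- setdiff(intersect(nxt, registry$terms$accession), seen)
  }
  FALSE
}

#' All terms in the subtree rooted at an accession
#'
#' Returns exactly the terms `T` with `is_descendant(registry, T, root)`
#' true, sorted by accession for deterministic order.
#'
#' @param registry A `cv_registry`.
#' @param root Accession of the subtree root.
#' @return Tibble of terms (same columns as `registry$terms`).
#' @export
subtree_terms <- function(registry, root) {
  if (!root %in% registry$terms$accession) {
    stopf("query error: accession %s does not resolve in the %s registry",
          root, registry$namespace, class = "spec2isa_query_error")
  }
  keep <- vapply(registry$terms$accession, function(a) is_descendant(registry, a, root), FALSE)
  out <- registry$terms[keep, ]
  out[order(out$accession), ]
}

# Resolve across a list of registries by accession prefix (no warning spam
# for cross-namespace lookups: the right registry is chosen up front).
registries_resolve <- function(registries, accession) {
  pre <- acc_prefix(accession)
  for (reg in registries) {
    if (reg$prefix == pre) return(resolve_accession(reg, accession))
  }
  NULL
}

registries_for_prefix <- function(registries, prefix) {
  for (reg in registries) if (reg$prefix == prefix) return(reg)
  NULL
}

#' Load the bundled controlled-vocabulary subsets
#'
#' Small OBO subsets of PSI-MS, imagingMS and the NMR vocabulary ship with
#' the package for testing and the default extraction rulesets; paths to full
#' vocabularies can be supplied instead.
#'
#' @param technology `"mzML"`, `"imzML"` or `"nmrML"`.
#' @param paths Optional named character vector of OBO paths keyed by
#'   accession prefix (`MS`, `IMS`, `NMR`) overriding the bundled subsets.
#' @return A list of `cv_registry` objects (MS for mzML; MS + IMS for imzML;
#'   NMR for nmrML).
#' @export
default_registries <- function(technology = c("mzML", "imzML", "nmrML"), paths = NULL) {
  technology <- match.arg(technology)
  bundled <- c(
    MS  = system.file("extdata", "psi-ms-subset.obo", package = "spec2isa"),
    IMS = system.file("extdata", "imagingms-subset.obo", package = "spec2isa"),
    NMR = system.file("extdata", "nmrcv-subset.obo", package = "spec2isa")
  )
  if (!is.null(paths)) bundled[names(paths)] <- paths
  prefixes <- switch(technology,
    mzML  = "MS",
    imzML = c("MS", "IMS"),
    nmrML = "NMR"
  )
  lapply(prefixes, function(p) load_obo(bundled[[p]]))
}

#' @export
print.cv_registry <- function(x, ...) {
  cat(sprintf("<cv_registry %s> %d terms, version '%s', %d unresolved parent(s)\n",
              x$namespace, nrow(x$terms), x$version, length(x$unresolved_parents)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a vocabulary registry into its term table
#' @param x A `cv_registry`.
#' @param ... Unused.
#' @return The registry's term tibble.
#' @export
tidy.cv_registry <- function(x, ...) x$terms

#' One-row summary of a vocabulary registry
#' @param x A `cv_registry`.
#' @param ... Unused.
#' @export
glance.cv_registry <- function(x, ...) {
  tibble(namespace = x$namespace, version = x$version,
         n_terms = nrow(x$terms), n_obsolete = sum(x$terms$obsolete),
         n_unresolved_parents = length(x$unresolved_parents))
}
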