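# Shared helpers: tiny OBO builders, a random-DAG generator and an
# independent breadth-first reachability oracle used to cross-check the
# registry's hierarchy queries.

obo_text <- function(..., header = "format-version: 1.2") {
  stanzas <- vapply(list(...), function(t) {
    lines <- c("[Term]", paste0("id: ", t$id))
    if (!is.null(t$name)) lines <- c(lines, paste0("name: ", t$name))
    for (p in t$is_a %||% character()) lines <- c(lines, paste0("is_a: ", p))
    if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
    paste(lines, collapse = "\n")
  }, "")
  paste(c(header, "", paste(stanzas, collapse = "\n\n")), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DAG over n terms: term i may only point at earlier terms, so the
# graph is acyclic by construction; returns OBO text plus the edge list
random_dag <- function(n = 50, seed = 1, p_edge = 0.08) {
  set.seed(seed)
  acc <- sprintf("MS:9%06d", seq_len(n))
  parents <- vector("list", n)
  names(parents) <- acc
  terms <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1) {
      pick <- which(stats::runif(i - 1) < p_edge)
      parents[[i]] <- acc[pick]
    } else {
      parents[[i]] <- character()
    }
    terms[[i]] <- list(id = acc[i], name = paste("node", i), is_a = parents[[i]])
  }
  list(obo = do.call(obo_text, terms), accessions = acc, parents = parents)
}

# independent oracle: set of accessions reachable from `from` via parent edges
bfs_reach <- function(parents, from) {
  seen <- character()
  frontier <- from
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)), seen)
  }
  seen
}

extract_kv <- function(fm) fm$entries[, c("term_key", "value")]

# set equality between a corpus manifest and extraction results
expect_manifest_equal <- function(manifest, files_metadata) {
  ex <- dplyr::bind_rows(lapply(files_metadata, function(f) {
    cbind(file = f$source_file, extract_kv(f))
  }))
  m <- manifest[, c("file", "term_key", "value")]
  expect_equal(nrow(dplyr::anti_join(m, ex, by = names(m))), 0)
  expect_equal(nrow(dplyr::anti_join(ex, m, by = names(m))), 0)
  expect_equal(nrow(m), nrow(ex))
}
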