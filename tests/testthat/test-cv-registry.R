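test_that("OBO loading keeps every stanza and the header version", {
  reg <- load_obo(obo_text(
    list(id = "MS:1", name = "root"),
    list(id = "MS:2", name = "a", is_a = "MS:1"),
    list(id = "MS:3", name = "b"),
    header = "format-version: 1.2\ndata-version: 9.9.9"
  ))
  expect_s3_class(reg, "cv_registry")
  expect_equal(nrow(reg$terms), 3)
  expect_equal(sum(lengths(reg$terms$parent_accessions)), 1)
  expect_equal(reg$version, "9.9.9")
  expect_equal(reg$namespace, "MS")
})

test_that("malformed and empty OBO inputs fail with informative errors", {
  expect_error(load_obo("[Term]\nname: no id here"), "stanza 1",
               class = "spec2isa_obo_error")
  expect_error(load_obo("format-version: 1.2\n"), "no terms",
               class = "spec2isa_obo_error")
})

test_that("bundled vocabulary subsets load completely", {
  for (f in c("psi-ms-subset.obo", "imagingms-subset.obo", "nmrcv-subset.obo")) {
    path <- system.file("extdata", f, package = "spec2isa")
    n_stanzas <- sum(readLines(path) == "[Term]")  # independent text scan
    reg <- load_obo(path)
    expect_equal(nrow(reg$terms), n_stanzas)
    expect_length(reg$unresolved_parents, 0)
  }
})

test_that("accession lookup is exact, and a miss is a value not an error", {
  reg <- default_registries("mzML")[[1]]
  hit <- resolve_accession(reg, "MS:1000031")
  expect_equal(hit$label, "instrument model")
  expect_null(resolve_accession(reg, "MS:9999999"))
  # wrong prefix: not-found plus a warning in the registry's log channel
  before <- length(registry_warnings(reg))
  expect_null(resolve_accession(reg, "IMS:1000030"))
  expect_match(registry_warnings(reg)[before + 1], "namespace mismatch")
})

test_that("obsolete terms resolve but are flagged", {
  reg <- default_registries("mzML")[[1]]
  t <- resolve_accession(reg, "MS:1000030")
  expect_true(t$obsolete)
})

test_that("descendant queries are reflexive and follow single is_a edges", {
  reg <- load_obo(obo_text(
    list(id = "MS:1", name = "root"),
    list(id = "MS:2", name = "child", is_a = "MS:1")
  ))
  expect_true(is_descendant(reg, "MS:1", "MS:1"))
  expect_true(is_descendant(reg, "MS:2", "MS:1"))
  expect_false(is_descendant(reg, "MS:1", "MS:2"))
  expect_error(is_descendant(reg, "MS:404", "MS:1"), "MS:404",
               class = "spec2isa_query_error")
  expect_error(subtree_terms(reg, "MS:404"), class = "spec2isa_query_error")
})

test_that("hierarchy queries agree with a brute-force BFS oracle on a random DAG", {
  dag <- random_dag(n = 50, seed = 7)
  reg <- load_obo(dag$obo)
  expect_equal(nrow(reg$terms), 50)
  oracle_up <- lapply(dag$accessions, function(a) bfs_reach(dag$parents, a))
  names(oracle_up) <- dag$accessions
  for (a in dag$accessions) {
    for (r in dag$accessions) {
      expect_identical(is_descendant(reg, a, r), r %in% oracle_up[[a]])
    }
  }
  # subtree_terms is the inverse view of the same relation
  for (r in dag$accessions) {
    expected <- sort(dag$accessions[vapply(dag$accessions, function(a)
      r %in% oracle_up[[a]], FALSE)])
    expect_identical(subtree_terms(reg, r)$accession, expected)
  }
})

test_that("loading is idempotent and subtree of a leaf is itself", {
  dag <- random_dag(n = 20, seed = 11)
  r1 <- load_obo(dag$obo)
  r2 <- load_obo(dag$obo)
  expect_identical(r1$terms, r2$terms)
  reg <- default_registries("mzML")[[1]]
  expect_identical(subtree_terms(reg, "MS:1000449")$accession, "MS:1000449")
})

test_that("an is_a cycle terminates and is flagged rather than looping", {
  reg <- load_obo(obo_text(
    list(id = "MS:1", name = "a", is_a = "MS:2"),
    list(id = "MS:2", name = "b", is_a = "MS:1")
  ))
  expect_match(paste(registry_warnings(reg), collapse = " "), "cycle")
  expect_true(is_descendant(reg, "MS:1", "MS:2"))
  expect_true(is_descendant(reg, "MS:2", "MS:1"))
  expect_setequal(subtree_terms(reg, "MS:1")$accession, c("MS:1", "MS:2"))
})

test_that("unresolved parents are recorded, never dropped", {
  reg <- load_obo(obo_text(list(id = "MS:5", name = "orphan", is_a = "MS:77")))
  expect_identical(reg$unresolved_parents, "MS:77")
})
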