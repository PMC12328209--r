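toy_obo <- function(...) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("OBO terms and typed relationships are parsed", {
  path <- toy_obo(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: root", "",
    "[Term]", "id: T:2", "name: organelle", "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: membrane", "is_a: T:1",
    "relationship: part_of T:2", ""
  )
  g <- load_obo(path)
  expect_length(g$nodes, 3L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$edges$relation[g$edges$child == "T:3"],
               c("is_a", "part_of"))
})

test_that("obsolete terms load but are excluded from traversal", {
  path <- toy_obo(
    "[Term]", "id: T:1", "name: root", "",
    "[Term]", "id: T:2", "name: old mid", "is_obsolete: true",
    "is_a: T:1", "",
    "[Term]", "id: T:3", "name: leaf", "is_a: T:2", "is_a: T:1", ""
  )
  g <- load_obo(path)
  anc <- ancestors_within_hops(g, "T:3", 5)
  expect_equal(anc$term_id, "T:1")
})

test_that("malformed stanzas fail with the line number", {
  path <- toy_obo("[Term]", "id: T:1", "name ok missing colon separator?")
  expect_error(load_obo(path), "line 3")
  cyc <- toy_obo(
    "[Term]", "id: A", "name: a", "is_a: B", "",
    "[Term]", "id: B", "name: b", "is_a: A", ""
  )
  expect_error(load_obo(cyc), "cycle")
})

test_that("hop-bounded ancestors on the diamond match hand enumeration", {
  g <- diamond_graph()
  expect_equal(nrow(ancestors_within_hops(g, "root", 3)), 0L)
  expect_equal(nrow(ancestors_within_hops(g, "leaf", 0)), 0L)

  anc3 <- ancestors_within_hops(g, "leaf", 3)
  expect_equal(
    stats::setNames(anc3$distance, anc3$term_id),
    c(mid1 = 1L, mid2 = 1L, top = 2L, root = 3L))

  anc1 <- ancestors_within_hops(g, "leaf", 1)
  expect_setequal(anc1$term_id, c("mid1", "mid2"))

  expect_error(ancestors_within_hops(g, "nope", 3), "unknown term")
})

test_that("ancestor sets grow monotonically in the hop bound", {
  withr::local_seed(7)
  for (rep in 1:5) {
    dag <- random_dag(sample(5:30, 1))
    g <- ontology_graph(stats::setNames(dag$ids, dag$ids), dag$edges)
    start <- dag$ids[length(dag$ids)]
    prev <- character()
    for (k in 0:6) {
      cur <- ancestors_within_hops(g, start, k)$term_id
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("unbounded ancestors equal the matrix-power transitive closure", {
  withr::local_seed(11)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    dag <- random_dag(n, p_edge = 0.15)
    g <- ontology_graph(stats::setNames(dag$ids, dag$ids), dag$edges)

    adj <- matrix(0, n, n, dimnames = list(dag$ids, dag$ids))
    if (nrow(dag$edges) > 0) {
      adj[cbind(dag$edges$child, dag$edges$parent)] <- 1
    }
    reach <- adj
    pow <- adj
    for (i in 2:n) {
      pow <- (pow %*% adj) > 0
      reach <- reach + pow
    }
    for (start in sample(dag$ids, 5)) {
      got <- ancestors_within_hops(g, start, Inf)$term_id
      expected <- dag$ids[reach[start, ] > 0]
      expect_setequal(got, expected)
    }
  }
})

test_that("reported distances match the exhaustive path-enumeration oracle", {
  withr::local_seed(13)
  for (rep in 1:5) {
    dag <- random_dag(sample(6:25, 1), p_edge = 0.25)
    g <- ontology_graph(stats::setNames(dag$ids, dag$ids), dag$edges)
    start <- sample(dag$ids, 1)
    k <- sample(1:4, 1)
    got <- ancestors_within_hops(g, start, k)
    want <- oracle_ancestors(dag$edges, start, k)
    expect_setequal(got$term_id, as.character(names(want)))
    for (id in got$term_id) {
      expect_equal(got$distance[got$term_id == id], want[[id]],
                   info = paste("distance of", id))
    }
  }
})

test_that("OBO write/load round-trips a fixture ontology", {
  g <- shared_world$ontology
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(g, path)
  g2 <- load_obo(path)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(
    g2$edges[order(g2$edges$child, g2$edges$parent, g2$edges$relation), ],
    g$edges[order(g$edges$child, g$edges$parent, g$edges$relation), ],
    ignore_attr = TRUE)
})
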