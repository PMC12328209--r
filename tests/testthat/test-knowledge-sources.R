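# A tiny hand-planted knowledge base used throughout this file.
planted_kb <- function() {
  key <- "g1,g2"  # canonical: sorted, case-folded, comma-joined
  terms7 <- lapply(1:7, function(r)
    list(term = paste("term", r), p = r / 1000))
  list(
    GO = stats::setNames(list(terms7), key),
    KEGG_2021_Human = stats::setNames(list(terms7[1:2]), key),
    Gene = list(
      gpx7 = list(list(term = "glutathione peroxidase activity",
                       p = 0.001))
    ),
    ppi = list(
      gpx7 = lapply(1:12, function(r)
        list(term = paste("partner", r), p = r / 1000))
    )
  )
}

test_that("enrichment queries truncate to the top five planted terms", {
  reg <- fixture_registry(planted_kb())
  ev <- query_enrichment(c("G2", "g1"), reg$descriptors$gprofiler, reg)
  expect_equal(nrow(ev$retrieved_terms), 5L)
  expect_equal(ev$retrieved_terms$term, paste("term", 1:5))
  expect_equal(ev$source_id, "gprofiler")

  empty <- fixture_registry(list())
  ev0 <- query_enrichment(c("g1", "g2"), empty$descriptors$enrichr, empty)
  expect_equal(nrow(ev0$retrieved_terms), 0L)
})

test_that("gene-centric queries cap at ten records and tolerate absent genes", {
  reg <- fixture_registry(planted_kb())
  ev <- query_gene_centric("Gpx7", reg$descriptors$agentapi, reg, "ppi")
  expect_equal(nrow(ev$retrieved_terms), 10L)

  miss <- query_gene_centric("Nope1", reg$descriptors$agentapi, reg, "ppi")
  expect_equal(nrow(miss$retrieved_terms), 0L)

  summ <- query_gene_centric("gpx7", reg$descriptors$eutils_gene, reg, "Gene")
  expect_equal(summ$retrieved_terms$term, "glutathione peroxidase activity")
})

test_that("masking removes a dataset's own knowledge source", {
  reg <- fixture_registry(planted_kb())

  go <- apply_mask(reg, gene_set("a", "G1", source = "GO"))
  expect_false("gprofiler" %in% names(go$descriptors))
  expect_true("enrichr" %in% names(go$descriptors))

  msig <- apply_mask(reg, gene_set("b", "G1", source = "MSigDB"))
  expect_equal(
    sort(msig$descriptors$enrichr$databases),
    sort(c("KEGG_2021_Human", "Reactome_2022", "BioPlanet_2019")))
  expect_true("gprofiler" %in% names(msig$descriptors))

  for (src in c("custom", "NeST")) {
    same <- apply_mask(reg, gene_set("c", "G1", source = src))
    expect_equal(names(same$descriptors), names(reg$descriptors))
    expect_length(same$descriptors$enrichr$databases, 4L)
  }
})

test_that("significance filtering keeps terms at or below alpha, ascending", {
  kb <- list(GO = list(
    "g1,g2" = list(list(term = "a", p = 0.04), list(term = "b", p = 0.06),
                   list(term = "c", p = 0.01))
  ))
  reg <- fixture_registry(kb)
  gs <- gene_set("s", c("G1", "G2"))
  st <- significant_terms(gs, reg, alpha = 0.05)
  expect_equal(st$terms$term, c("c", "a"))
  expect_true(all(st$terms$p_value <= st$alpha))

  expect_equal(nrow(significant_terms(gs, reg, alpha = 0)$terms), 0L)

  # brute-force count on a planted 10-term fixture with 4 values <= 0.05
  ps <- c(0.01, 0.2, 0.03, 0.5, 0.05, 0.3, 0.04, 0.9, 0.6, 0.7)
  kb10 <- list(GO = list("g1,g2" = lapply(seq_along(ps), function(i)
    list(term = paste0("t", i), p = ps[i]))))
  st10 <- significant_terms(gs, fixture_registry(kb10), alpha = 0.05)
  expect_equal(nrow(st10$terms), sum(ps <= 0.05))
})

test_that("the cache keys on canonical gene order and can be disabled", {
  reg <- fixture_registry(planted_kb(), cache = TRUE)
  query_enrichment(c("G1", "G2"), reg$descriptors$gprofiler, reg)
  query_enrichment(c("g2", "G1"), reg$descriptors$gprofiler, reg)
  counts <- transport_call_counts(reg)
  expect_true(all(counts == 1))

  nocache <- fixture_registry(planted_kb(), cache = FALSE)
  query_enrichment(c("G1", "G2"), nocache$descriptors$gprofiler, nocache,
                   database = "GO")
  query_enrichment(c("G1", "G2"), nocache$descriptors$gprofiler, nocache,
                   database = "GO")
  expect_equal(unname(transport_call_counts(nocache)), 2)
})

test_that("no evidence item ever carries a masked source or database", {
  # randomized over dataset sources and worlds
  for (seed in 1:3) {
    world <- if (seed == 1) shared_world else
      generate_world(seed, n_terms = 20, n_genes = 60, n_sets = 2,
                     n_negative = 1)
    cfg <- world_config(world)
    for (gs in c(world$gene_sets, world$negative_sets)) {
      for (src in c("GO", "MSigDB", gs$source)) {
        gs2 <- gs
        gs2$source <- src
        # off-transcript prompts degrade to empty responses; that path is
        # exercised here on purpose, so silence the retention warnings
        res <- suppressWarnings(run_pipeline(gs2, cfg))
        masks <- default_mask_rules()[[src]] %||% list()
        items <- unlist(lapply(
          c(res$report_p$entries, res$report_a$entries), `[[`, "evidence"),
          recursive = FALSE)
        for (item in items) {
          dbs <- strsplit(item$database_name, "+", fixed = TRUE)[[1]]
          for (m in masks) {
            if (is.null(m$database)) {
              expect_false(identical(item$source_id, m$source_id))
            } else {
              expect_false(m$database %in% dbs)
            }
          }
        }
      }
    }
  }
})

test_that("removing a source never increases the evidence in a report", {
  gs <- shared_world$gene_sets[[2]]
  cfg <- world_config()
  full <- run_pipeline(gs, cfg)

  smaller <- cfg
  smaller$registry$descriptors$gprofiler <- NULL
  less <- suppressWarnings(run_pipeline(gs, pipeline_config(
    cfg$backend, smaller$registry, judge = cfg$judge)))

  n_items <- function(res) sum(lengths(lapply(
    c(res$report_p$entries, res$report_a$entries), `[[`, "evidence")))
  expect_lte(n_items(less), n_items(full))
})
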