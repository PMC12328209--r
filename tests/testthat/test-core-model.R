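test_that("gene-set validation dedups case-insensitively and trims", {
  gs <- validate_gene_set(list(id = "S1", genes = c("Tp53", "TP53", "KRAS")))
  expect_equal(gs$genes, c("Tp53", "KRAS"))

  gs2 <- validate_gene_set(list(id = "S3", genes = c("  BRCA1 ", "brca1", "")))
  expect_equal(gs2$genes, "BRCA1")

  big <- gene_set("mmu04015", sprintf("Rap%02d", 1:27),
                  ground_truth = "Rap1 signaling pathway")
  expect_length(big$genes, 27L)
})

test_that("an empty gene list is rejected with the set id named", {
  expect_error(validate_gene_set(list(id = "S2", genes = character())), "S2")
  expect_error(gene_set("S2", c("", "  ")), "empty gene list")
})

test_that("domain objects round-trip through JSON", {
  gs <- gene_set("rt1", c("Tp53", "Kras"), ground_truth = "example process",
                 source = "NeST", species = "mouse")
  expect_equal(from_json(to_json(gs)), gs)

  cl <- claim(c("Tp53"), "dna repair", "narrative",
              "Tp53 is involved in dna repair")
  expect_equal(from_json(to_json(cl)), cl)

  ev <- evidence_item("enrichr", "Reactome_2022", c("Tp53", "Kras"),
                      data.frame(term = c("a", "b"), description = c("d", NA),
                                 score = c(0.01, NA)), 5L)
  expect_equal(from_json(to_json(ev)), ev)

  rep <- verification_report("process_name", list(
    list(claim = cl, evidence = list(ev),
         decision = decision("supported", "seen in Reactome"))
  ))
  expect_equal(from_json(to_json(rep)), rep)
})

test_that("pipeline results round-trip and keep both reports", {
  res <- run_pipeline(shared_world$gene_sets[[1]], world_config())
  back <- from_json(to_json(res))
  expect_equal(back, res)
  expect_s3_class(back$report_p, "verification_report")
  expect_equal(back$report_a$target_stage, "narrative")
})

test_that("claim ids are deterministic digests of origin and text", {
  a <- claim("G1", "x", "narrative", "G1 is involved in x")
  b <- claim("G1", "x", "narrative", "G1 is involved in x")
  c2 <- claim("G1", "x", "process_name", "G1 is involved in x")
  expect_identical(a$claim_id, b$claim_id)
  expect_false(identical(a$claim_id, c2$claim_id))
})

test_that("claims and reports emit one JSON object per JSONL line", {
  gs <- gene_set("jl", c("G1", "G2"))
  claims <- make_claims_from_process(gs, process_name("px", "initial"))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_jsonl(claims, path)
  lines <- readLines(path)
  expect_length(lines, length(claims))
  parsed <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  expect_equal(parsed$type, "claim")
})
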