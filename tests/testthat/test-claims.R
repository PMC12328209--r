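test_that("the process-name claim ties the full gene list to the name", {
  genes <- c("ERBB2", "ERBB4", "FGFR2", "FGFR4", "HRAS", "KRAS")
  gs <- gene_set("fig1c", genes)
  claims <- make_claims_from_process(gs, process_name("RTK signaling",
                                                      "initial"))
  expect_length(claims, 1L)
  expect_equal(claims[[1]]$genes, genes)
  expect_equal(claims[[1]]$origin, "process_name")
  expect_match(claims[[1]]$raw_text, "is involved in RTK signaling")

  single <- make_claims_from_process(gene_set("one", "Gpx7"),
                                     process_name("X", "initial"))
  expect_equal(single[[1]]$raw_text, "Gpx7 is involved in X")
})

test_that("claims cover the gene set: union of claim genes equals the set", {
  gs <- gene_set("toy5", c("Ga", "Gb", "Gc", "Gd", "Ge"))
  p <- process_name("vesicle transport", "initial")
  a <- narrative(paste(
    "The gene Ga is involved in membrane fusion.",
    "Gb and Gc are involved in vesicle transport.",
    "Gd is related to cargo sorting.",
    "Ge plays a role in vesicle transport."
  ), "modified")
  claims <- c(make_claims_from_process(gs, p),
              make_claims_from_narrative(gs, a))
  covered <- sort(unique(unlist(lapply(claims, `[[`, "genes"))))
  expect_equal(covered, sort(gs$genes))
  # narrative mining emits one claim per gene-function pair
  narr <- Filter(function(cl) cl$origin == "narrative", claims)
  expect_length(narr, 5L)
  expect_true(all(lengths(lapply(narr, `[[`, "genes")) == 1L))
})

test_that("entity extraction matches vocabulary tokens case-insensitively", {
  hit <- extract_entities("KRAS, HRAS is involved in RTK signaling",
                          c("KRAS", "HRAS", "TP53"))
  expect_equal(hit$genes, c("KRAS", "HRAS"))
  expect_equal(hit$function_phrase, "RTK signaling")

  none <- extract_entities("These genes act together", c("KRAS"))
  expect_equal(none$genes, character())
  expect_equal(none$function_phrase, "")

  mouse <- extract_entities(
    "Ndufa10 is involved in respiratory chain complex.",
    c("Ndufa10", "Atxn1l", "Gpx7"))
  expect_equal(mouse$genes, "Ndufa10")
  expect_equal(mouse$function_phrase, "respiratory chain complex")

  # symbols are reported in the vocabulary's casing
  cased <- extract_entities("NDUFA10 is involved in x", "Ndufa10")
  expect_equal(cased$genes, "Ndufa10")
})

test_that("decision parsing applies the precedence rule", {
  expect_equal(
    parse_decision("The claim is partially supported because ...")$category,
    "partially_supported")
  expect_equal(parse_decision("Refuted. The databases show ...")$category,
               "refuted")
  expect_equal(parse_decision("Supported: strong evidence.")$category,
               "supported")
  expect_equal(parse_decision("")$category, "unknown")
  expect_equal(parse_decision("The evidence is inconclusive.")$category,
               "unknown")
  # "supported" is a substring of "partially supported"; precedence wins
  expect_equal(
    parse_decision("PARTIALLY SUPPORTED, though one term is supported")$category,
    "partially_supported")
  # rationale preserves the judge's words
  expect_equal(parse_decision("Refuted: x")$rationale, "Refuted: x")
})
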