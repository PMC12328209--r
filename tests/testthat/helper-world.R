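# One shared fixture world for the pipeline-level tests (built once per
# test run; everything below is deterministic in the seed).
shared_world <- generate_world(seed = 42, n_terms = 30, n_genes = 120,
                               n_sets = 5, n_negative = 2)

world_config <- function(world = shared_world, cache = TRUE) {
  pipeline_config(scripted_backend(world$transcript),
                  fixture_registry(world$kb, cache = cache))
}

# the digest the summarization prompt embeds for a report (recomputed here
# independently of the pipeline internals)
content_digest_for_tests <- function(report) {
  digest::digest(as.character(to_json(report)), algo = "xxhash32",
                 serialize = FALSE)
}

# a tiny diamond-with-tail ontology used across ontology/evaluation tests:
#   leaf -> (mid1, mid2) -> top -> root ; distances from leaf:
#   mid1 = mid2 = 1, top = 2, root = 3
diamond_graph <- function() {
  ontology_graph(
    c(leaf = "lymphocyte activation", mid1 = "leukocyte activation",
      mid2 = "cell activation", top = "immune response",
      root = "immune system", off = "unrelated process"),
    data.frame(
      child = c("leaf", "leaf", "mid1", "mid2", "top", "off"),
      parent = c("mid1", "mid2", "top", "top", "root", "root"),
      relation = c("is_a", "part_of", "is_a", "regulates",
                   "positively_regulates", "is_a"),
      stringsAsFactors = FALSE
    )
  )
}
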