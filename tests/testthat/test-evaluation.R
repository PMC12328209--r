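test_that("ROUGE worked examples match hand counts", {
  expect_equal(rouge_n("cytosolic ribosome", "cytosolic ribosome assembly", 1),
               2 / 3)
  expect_equal(rouge_n("alpha beta", "gamma delta", 1), 0)
  expect_equal(rouge_l("limb development", "limb morphogenesis"), 0.5)
  expect_equal(rouge_l("alpha beta", "gamma delta"), 0)
  # beta moves ROUGE-L between recall and precision
  cfg_recall <- rouge_config(beta = 8)
  val <- rouge_l("one two three four", "one two", cfg_recall)
  expect_gt(val, rouge_l("one two three four", "one two"))
})

test_that("ROUGE is 1 on identity, bounded, and missing when undefined", {
  phrases <- c("x", "protein transport", "regulation of cell division")
  for (p in phrases) {
    expect_equal(rouge_n(p, p, 1), 1)
    expect_equal(rouge_l(p, p), 1)
  }
  expect_equal(rouge_n(phrases[2], phrases[2], 2), 1)
  # reference shorter than n is undefined, not zero
  expect_true(is.na(rouge_n("anything", "single", 2)))
  expect_true(is.na(rouge_l("anything", "...")))
})

test_that("ROUGE agrees with independent reference implementations on random pairs", {
  withr::local_seed(101)
  for (i in 1:120) {
    hyp <- random_phrase()
    ref <- random_phrase()
    expect_equal(rouge_n(hyp, ref, 1), oracle_rouge_n(hyp, ref, 1),
                 info = paste(hyp, "//", ref))
    expect_equal(rouge_n(hyp, ref, 2), oracle_rouge_n(hyp, ref, 2),
                 info = paste(hyp, "//", ref))
    expect_equal(rouge_l(hyp, ref), oracle_rouge_l(hyp, ref),
                 info = paste(hyp, "//", ref))
    expect_true(all(rouge_scores(hyp, ref) >= 0 &
                      rouge_scores(hyp, ref) <= 1, na.rm = TRUE))
  }
})

test_that("cosine similarity behaves on the canonical cases", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2), c(-1, -2)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("semantic similarity reproduces a hand-computed count-vector cosine", {
  enc <- toy_encoder()
  expect_equal(semantic_similarity("limb morphogenesis",
                                   "Limb Morphogenesis!", enc), 1)
  # two 2-token phrases sharing one token: cosine = 1/2 on count vectors
  expect_equal(semantic_similarity("limb morphogenesis", "limb development",
                                   enc), 0.5)
  # determinism of the encoder contract
  expect_identical(enc$embed("a phrase"), enc$embed("a phrase"))
})

test_that("background percentile matches the sort-and-count oracle", {
  enc <- toy_encoder()
  # ground truth is the unique top-scoring candidate
  q <- background_set(c("limb morphogenesis", "apple pie", "stone wall",
                        "iron gate"))
  top <- background_percentile("limb morphogenesis", "limb morphogenesis",
                               q, enc)
  expect_equal(top$percentile, 100 * 3 / 4)
  # ground truth strictly below every candidate
  q2 <- background_set(c("protein transport", "protein binding",
                         "unrelated thing"))
  low <- background_percentile("protein transport", "unrelated thing",
                               q2, enc)
  expect_equal(low$percentile, 0)
  expect_error(background_percentile("x", "y", background_set(character())),
               "empty")

  withr::local_seed(202)
  for (i in 1:110) {
    terms <- unique(replicate(sample(4:9, 1), random_phrase(2, 4)))
    gt <- sample(terms, 1)
    p <- random_phrase(2, 4)
    got <- background_percentile(p, gt, background_set(terms), enc)
    sims <- vapply(terms, function(t) semantic_similarity(p, t, enc),
                   numeric(1))
    gt_sim <- sims[[match(tolower(gt), tolower(terms))]]
    expect_equal(got$percentile, 100 * sum(sims < gt_sim) / length(terms))
    # monotonicity: the ground-truth pair never outranks a strictly
    # higher-scoring variant of itself
    expect_gte(
      background_percentile(gt, gt, background_set(terms), enc)$percentile,
      got$percentile - 1e-9)
  }
})

test_that("background assembly concatenates without deduplication", {
  bg <- assemble_background(paste0("go", 1:5), paste0("nest", 1:3), "go1")
  expect_length(bg$terms, 9L)
  expect_equal(length(assemble_background("a", "b", "b")$terms), 3L)
  expect_equal(bg$terms[1:5], paste0("go", 1:5))
})

test_that("hierarchical comparison flags names closer to an ancestor", {
  g <- diamond_graph()
  # no ancestors within reach -> flag down
  none <- hierarchical_comparison("anything", "immune system", g, k = 0)
  expect_false(none$ancestor_higher)

  # recorded-similarity injection: generated name scores 0.746 against the
  # ground truth and 0.929 against an ancestor
  recorded <- c("lymphocyte activation" = 0.746,
                "leukocyte activation" = 0.929,
                "cell activation" = 0.41, "immune response" = 0.40)
  inj <- hierarchical_comparison(
    "Immune system signature", "lymphocyte activation", g, k = 2,
    sim_fun = function(p, term) unname(recorded[[term]]))
  expect_true(inj$ancestor_higher)
  expect_equal(inj$sim_gt, 0.746)
  expect_equal(inj$best_ancestor, "leukocyte activation")
  expect_equal(inj$sim_best_ancestor, 0.929)

  skipped <- hierarchical_comparison("x", "not a term", g)
  expect_true(skipped$skipped)

  # toy encoder result equals exhaustive comparison over all ancestors
  enc <- toy_encoder()
  got <- hierarchical_comparison("leukocyte activation", "lymphocyte activation",
                                 g, k = 3, enc)
  anc_ids <- ancestors_within_hops(g, "leaf", 3)$term_id
  sims <- vapply(unname(g$nodes[anc_ids]), function(nm)
    semantic_similarity("leukocyte activation", nm, enc), numeric(1))
  expect_equal(got$ancestor_higher,
               max(sims) > semantic_similarity("leukocyte activation",
                                               "lymphocyte activation", enc))
  expect_equal(got$sim_best_ancestor, max(sims))
})

test_that("exact matching compares word multisets", {
  res <- exact_match_accuracy(c("a b", "c d"), c("b a", "c d"))
  expect_equal(res$accuracy, 1)
  # word sets differ: a subset phrase is not a match
  res2 <- exact_match_accuracy("peroxisome protein",
                               "Protein localization to peroxisome")
  expect_equal(res2$matched, 0L)
  # invariant under word-order permutation
  expect_equal(
    exact_match_accuracy("epithelial cells of invasion bacterial",
                         "Bacterial invasion of epithelial cells")$matched,
    1L)
  # string mode requires the ordered sequence
  expect_equal(
    exact_match_accuracy("b a", "a b", mode = "string")$matched, 0L)
  expect_true(is.na(exact_match_accuracy(character(), "a")$accuracy))
})

test_that("Wilson intervals match the closed form and the printed bounds", {
  got <- wilson_interval(124, 132, 0.95)
  expect_equal(round(100 * got[["lower"]], 1), 88.5)
  expect_equal(round(100 * got[["upper"]], 1), 96.9)

  expect_equal(wilson_interval(0, 10)[["lower"]], 0)
  expect_equal(wilson_interval(10, 10)[["upper"]], 1)

  # independent oracle: prop.test without continuity correction computes
  # the Wilson score interval
  for (case in list(c(5, 10), c(1, 7), c(296, 367), c(50, 1000))) {
    got <- wilson_interval(case[1], case[2], 0.95)
    want <- suppressWarnings(
      stats::prop.test(case[1], case[2], correct = FALSE))$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-10)
    phat <- case[1] / case[2]
    expect_true(got[["lower"]] <= phat && phat <= got[["upper"]])
  }
  # width shrinks with trials at fixed proportion
  w <- function(x, n) diff(wilson_interval(x, n))
  expect_lt(w(300, 1000), w(30, 100))
  expect_error(wilson_interval(5, 0), "trials")
  expect_error(wilson_interval(11, 10), "trials")
})

test_that("batch aggregation reproduces direct computation", {
  const <- batch_aggregate(rep(0.4, 50), batch_size = 10, n_batches = 9)
  expect_equal(const$sd, 0)
  expect_equal(const$mean, 0.4)

  scores <- as.numeric(1:180)
  agg <- batch_aggregate(scores, batch_size = 20, n_batches = 9,
                         seed = 3, method = "partition")
  # disjoint batches covering the vector: overall mean is the plain mean
  expect_equal(agg$mean, mean(scores))
  # direct recomputation of the batch means from the same permutation
  set.seed(3)
  perm <- sample(length(scores))
  bm <- vapply(1:9, function(i)
    mean(scores[perm[((i - 1) * 20 + 1):(i * 20)]]), numeric(1))
  expect_equal(agg$sd, sd(bm))

  expect_error(batch_aggregate(1:5, batch_size = 10), "batch_size")
})
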