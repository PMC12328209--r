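# Evaluation suite: ROUGE-1/2/L against ground-truth names, embedding
# cosine similarity, background-percentile ranking, hop-bounded ancestor
# comparison, exact-match enrichment-term testing, Wilson score intervals,
# and batch-sampled aggregation.

#' Tokenize a term for metric computation
#'
#' One normalization policy is shared by the ROUGE metrics and the
#' exact-match test so their scores are comparable: lower-case, strip
#' punctuation, split on whitespace.
#'
#' @param x Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' metric_tokens("Protein localization to peroxisome.")
metric_tokens <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character())
  vapply(seq_len(length(tokens) - n + 1L), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = " "), character(1))
}

#' ROUGE-N recall
#'
#' Clipped n-gram match count over the reference's n-gram count: each
#' reference n-gram can be matched at most as often as it occurs in the
#' hypothesis. Recall-oriented, so a hypothesis containing the whole
#' reference scores 1.
#'
#' @param hyp Generated name (hypothesis).
#' @param ref Ground-truth name (reference).
#' @param n N-gram order, 1 or 2.
#' @param config A [rouge_config()].
#' @return Score in `[0, 1]`, or `NA` when the reference has fewer than `n`
#'   tokens (undefined, reported as missing rather than 0).
#' @export
#' @examples
#' rouge_n("cytosolic ribosome", "cytosolic ribosome assembly", 1)
rouge_n <- function(hyp, ref, n, config = rouge_config()) {
  stopifnot(n %in% c(1L, 2L))
  ref_grams <- ngrams(config$tokenizer(ref), n)
  if (length(ref_grams) == 0L) return(NA_real_)
  hyp_grams <- ngrams(config$tokenizer(hyp), n)
  if (length(hyp_grams) == 0L) return(0)
  hyp_counts <- table(hyp_grams)
  ref_counts <- table(ref_grams)
  shared <- intersect(names(ref_counts), names(hyp_counts))
  matched <- sum(pmin(as.integer(ref_counts[shared]),
                      as.integer(hyp_counts[shared])))
  matched / length(ref_grams)
}

lcs_length <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  prev <- integer(length(b) + 1L)
  for (i in seq_along(a)) {
    cur <- integer(length(b) + 1L)
    for (j in seq_along(b)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else
        max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[length(b) + 1L]
}

#' ROUGE-L F-measure
#'
#' Token-level longest common subsequence. With `m` and `n` the token
#' lengths of reference and hypothesis, recall is `LCS/m`, precision is
#' `LCS/n`, and the score is the F-measure
#' `(1 + beta^2) R P / (R + beta^2 P)`.
#'
#' @inheritParams rouge_n
#' @return Score in `[0, 1]`, or `NA` when either side tokenizes to nothing.
#' @export
#' @examples
#' rouge_l("limb development", "limb morphogenesis")
rouge_l <- function(hyp, ref, config = rouge_config()) {
  ref_tok <- config$tokenizer(ref)
  hyp_tok <- config$tokenizer(hyp)
  if (length(ref_tok) == 0L || length(hyp_tok) == 0L) return(NA_real_)
  lcs <- lcs_length(ref_tok, hyp_tok)
  if (lcs == 0L) return(0)
  r <- lcs / length(ref_tok)
  p <- lcs / length(hyp_tok)
  b2 <- config$beta^2
  (1 + b2) * r * p / (r + b2 * p)
}

#' ROUGE configuration
#'
#' @param beta Weight of recall in the ROUGE-L F-measure (`beta = 1` is the
#'   balanced F1, the default).
#' @param tokenizer Tokenization function; defaults to [metric_tokens()].
#' @return A `rouge_config` list.
#' @export
rouge_config <- function(beta = 1, tokenizer = metric_tokens) {
  stopifnot(is.numeric(beta), beta > 0, is.function(tokenizer))
  structure(list(beta = beta, tokenizer = tokenizer), class = "rouge_config")
}

#' All three ROUGE scores at once
#'
#' @inheritParams rouge_n
#' @return Named numeric vector `rouge1`, `rouge2`, `rougeL`.
#' @export
rouge_scores <- function(hyp, ref, config = rouge_config()) {
  c(rouge1 = rouge_n(hyp, ref, 1L, config),
    rouge2 = rouge_n(hyp, ref, 2L, config),
    rougeL = rouge_l(hyp, ref, config))
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return Value in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) > 0L)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Semantic similarity of two term strings
#'
#' Encodes both terms with the supplied encoder contract and returns the
#' cosine of the embeddings. Live biomedical encoders plug in through the
#' same contract as the deterministic [toy_encoder()].
#'
#' @param p Generated name.
#' @param g Ground-truth (or candidate) name.
#' @param encoder An encoder: `function(text) -> numeric vector`, or a
#'   [text encoder object][toy_encoder()].
#' @return Cosine similarity in `[-1, 1]`.
#' @export
semantic_similarity <- function(p, g, encoder = toy_encoder()) {
  embed <- encoder_fn(encoder)
  cosine_similarity(embed(p), embed(g))
}

encoder_fn <- function(encoder) {
  if (inherits(encoder, "text_encoder")) encoder$embed else {
    stopifnot(is.function(encoder))
    encoder
  }
}

#' Background term set
#'
#' An ordered list of candidate terms against which generated names are
#' percentile-ranked. Order is fixed at construction and breaks ties.
#'
#' @param terms Character vector of candidate terms.
#' @return A `background_set` object.
#' @export
background_set <- function(terms) {
  structure(list(terms = as.character(terms)), class = "background_set")
}

#' Assemble the standard background set
#'
#' Concatenates the three candidate-term pools in fixed order with no
#' deduplication, so the pool sizes add exactly.
#'
#' @param go_terms,nest_terms,msigdb_terms Character vectors of candidate
#'   terms from the three dataset families.
#' @return A [background_set()] of length equal to the summed inputs.
#' @export
assemble_background <- function(go_terms, nest_terms, msigdb_terms) {
  background_set(c(as.character(go_terms), as.character(nest_terms),
                   as.character(msigdb_terms)))
}

#' Background percentile of a generated name
#'
#' Scores the generated name against every candidate term and against the
#' ground truth, then reports where the ground-truth pair ranks:
#' `100 * (number of candidates scoring strictly below sim(p, ground_truth))
#' / |background|`. A high percentile means the name is closer to its
#' ground truth than to almost all candidates. Ties with the ground-truth
#' score are counted as not-below and flagged.
#'
#' @param p Generated name.
#' @param ground_truth The curated name (appended to the background, with a
#'   flag, if absent).
#' @param q A [background_set()].
#' @param encoder Encoder contract (see [semantic_similarity()]).
#' @return List: `percentile` in `[0, 100]`, `sim_ground_truth`, `ties`
#'   (count of candidates tying the ground-truth score, excluding the
#'   ground truth itself), `appended` (was the ground truth missing from
#'   the background).
#' @export
background_percentile <- function(p, ground_truth, q, encoder = toy_encoder()) {
  stopifnot(inherits(q, "background_set"))
  if (length(q$terms) == 0L) {
    stop("background set is empty", call. = FALSE)
  }
  terms <- q$terms
  appended <- !any(tolower(terms) == tolower(ground_truth))
  if (appended) terms <- c(terms, ground_truth)
  embed <- encoder_fn(encoder)
  p_vec <- embed(p)
  sims <- vapply(terms, function(t) cosine_similarity(p_vec, embed(t)),
                 numeric(1))
  gt_idx <- which(tolower(terms) == tolower(ground_truth))[1]
  sim_gt <- sims[[gt_idx]]
  below <- sum(sims < sim_gt)
  ties <- sum(sims == sim_gt) - 1L
  list(
    percentile = 100 * below / length(terms),
    sim_ground_truth = sim_gt,
    ties = as.integer(ties),
    appended = appended
  )
}

#' Compare a name's similarity to the ground truth and to its ancestors
#'
#' Collects the ground truth's ontology ancestors within `k` hops and asks
#' whether the generated name is more similar to any ancestor than to the
#' ground truth itself — the signature of a generated name that captures a
#' broader concept.
#'
#' @param p Generated name.
#' @param ground_truth Curated name, resolved in the graph by exact
#'   case-insensitive name match.
#' @param graph An [ontology_graph()].
#' @param k Hop bound (default 3).
#' @param encoder Encoder contract.
#' @param sim_fun Similarity function `(p, term) -> number`; defaults to
#'   [semantic_similarity()] under `encoder`. Supply a lookup to inject
#'   externally computed scores.
#' @return List: `sim_gt`, `best_ancestor` (name or `NA`),
#'   `sim_best_ancestor` (`NA` when no ancestor), `ancestor_higher` (flag),
#'   `skipped` (ground truth unresolvable in the graph).
#' @export
hierarchical_comparison <- function(p, ground_truth, graph, k = 3,
                                    encoder = toy_encoder(),
                                    sim_fun = NULL) {
  sim_fun <- sim_fun %||% function(a, b) semantic_similarity(a, b, encoder)
  gt_id <- resolve_term(graph, ground_truth)
  if (is.na(gt_id)) {
    return(list(sim_gt = NA_real_, best_ancestor = NA_character_,
                sim_best_ancestor = NA_real_, ancestor_higher = FALSE,
                skipped = TRUE))
  }
  sim_gt <- sim_fun(p, graph$nodes[[gt_id]])
  anc <- ancestors_within_hops(graph, gt_id, k)
  if (nrow(anc) == 0L) {
    return(list(sim_gt = sim_gt, best_ancestor = NA_character_,
                sim_best_ancestor = NA_real_, ancestor_higher = FALSE,
                skipped = FALSE))
  }
  anc_names <- unname(graph$nodes[anc$term_id])
  sims <- vapply(anc_names, function(nm) sim_fun(p, nm), numeric(1))
  best <- which.max(sims)
  list(
    sim_gt = sim_gt,
    best_ancestor = anc_names[[best]],
    sim_best_ancestor = sims[[best]],
    ancestor_higher = sims[[best]] > sim_gt,
    skipped = FALSE
  )
}

#' Exact-match accuracy of tested enrichment terms
#'
#' A tested term counts as accurate only when all its words match one
#' ground-truth term exactly. The default comparison is equality of
#' normalized word multisets (case-folded, punctuation-stripped), making
#' the test invariant to word order; `mode = "string"` requires the
#' normalized token sequences to be identical.
#'
#' @param tested_terms Character vector of terms produced by summarization.
#' @param significant A `significant_term_set` (from [significant_terms()])
#'   or a character vector of ground-truth terms.
#' @param mode `"multiset"` (default) or `"string"`.
#' @return List: `matched`, `total`, `accuracy` (fraction; `NA` when no
#'   term was tested).
#' @export
#' @examples
#' exact_match_accuracy("peroxisome protein",
#'                      "Protein localization to peroxisome")
exact_match_accuracy <- function(tested_terms, significant,
                                 mode = c("multiset", "string")) {
  mode <- match.arg(mode)
  truth <- if (inherits(significant, "significant_term_set")) {
    significant$terms$term
  } else {
    as.character(significant)
  }
  normalize <- function(term) {
    tok <- metric_tokens(term)
    if (mode == "multiset") tok <- sort(tok)
    paste(tok, collapse = " ")
  }
  truth_keys <- unique(vapply(truth, normalize, character(1)))
  total <- length(tested_terms)
  if (total == 0L) {
    return(list(matched = 0L, total = 0L, accuracy = NA_real_))
  }
  matched <- sum(vapply(tested_terms, normalize, character(1)) %in%
                   truth_keys)
  list(matched = as.integer(matched), total = as.integer(total),
       accuracy = matched / total)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,trials Non-negative counts, `successes <= trials`,
#'   `trials > 0`.
#' @param confidence Two-sided confidence level (default 0.95).
#' @return Named numeric vector `lower`, `upper` on the proportion scale.
#' @export
#' @examples
#' wilson_interval(124, 132) # agreement of 93.9% with ~[0.885, 0.969]
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (trials <= 0 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials and trials > 0", call. = FALSE)
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (phat + z^2 / (2 * trials)) / denom
  half <- z * sqrt(phat * (1 - phat) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Batch-sampled mean and spread of a score vector
#'
#' Draws `n_batches` batches of `batch_size` scores and reports the mean of
#' the batch means and the standard deviation across them — the error-bar
#' construction for aggregate score plots. `method = "sample"` draws each
#' batch independently without replacement; `method = "partition"` shuffles
#' once and splits into disjoint batches, so when the batches cover the
#' whole vector the overall mean equals the plain mean exactly.
#'
#' @param scores Numeric vector of per-set scores.
#' @param batch_size Scores per batch; conventional defaults are 200 for a
#'   1,000-set collection and 20 for 50-to-56-set collections.
#' @param n_batches Number of batches (default 9).
#' @param seed Integer seed for the batch sampler.
#' @param method `"sample"` (default) or `"partition"`.
#' @return A `batch_aggregate`: list with `mean`, `sd`, `batch_size`,
#'   `n_batches`.
#' @export
batch_aggregate <- function(scores, batch_size, n_batches = 9, seed = 1,
                            method = c("sample", "partition")) {
  method <- match.arg(method)
  scores <- scores[!is.na(scores)]
  if (batch_size > length(scores)) {
    stop("batch_size exceeds the number of scores", call. = FALSE)
  }
  if (method == "partition" && batch_size * n_batches > length(scores)) {
    stop("partitioning needs batch_size * n_batches <= length(scores)",
         call. = FALSE)
  }
  means <- withr_seed(seed, function() {
    if (method == "sample") {
      vapply(seq_len(n_batches), function(i)
        mean(sample(scores, batch_size)), numeric(1))
    } else {
      perm <- sample(length(scores))
      vapply(seq_len(n_batches), function(i) {
        idx <- perm[((i - 1L) * batch_size + 1L):(i * batch_size)]
        mean(scores[idx])
      }, numeric(1))
    }
  })
  structure(
    list(mean = mean(means), sd = if (n_batches > 1) sd(means) else 0,
         batch_size = as.integer(batch_size),
         n_batches = as.integer(n_batches)),
    class = "batch_aggregate"
  )
}

# Run fn() under a temporary RNG state so callers' streams are untouched.
withr_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}
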