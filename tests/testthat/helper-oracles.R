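# Independent oracles, deliberately implemented with different mechanisms
# than the package (greedy matching instead of count clipping, exhaustive
# subsequence / path enumeration instead of dynamic programming and BFS).

oracle_tokens <- function(x) {
  tok <- strsplit(trimws(gsub("[[:punct:]]+", " ", tolower(x))), "\\s+")[[1]]
  tok[nzchar(tok)]
}

oracle_ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character())
  out <- character()
  for (i in 1:(length(tokens) - n + 1)) {
    out <- c(out, paste(tokens[i:(i + n - 1)], collapse = " "))
  }
  out
}

# greedy one-to-one matching of reference n-grams against hypothesis n-grams
oracle_rouge_n <- function(hyp, ref, n) {
  ref_g <- oracle_ngrams(oracle_tokens(ref), n)
  if (length(ref_g) == 0) return(NA_real_)
  pool <- oracle_ngrams(oracle_tokens(hyp), n)
  matched <- 0
  for (g in ref_g) {
    hit <- match(g, pool)
    if (!is.na(hit)) {
      matched <- matched + 1
      pool <- pool[-hit]
    }
  }
  matched / length(ref_g)
}

# exhaustive subsequence enumeration (tokens of the shorter side <= ~10)
oracle_lcs <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  if (length(a) == 0 || length(b) == 0) return(0L)
  is_subseq <- function(s, big) {
    j <- 1
    for (x in big) {
      if (j <= length(s) && identical(x, s[j])) j <- j + 1
    }
    j > length(s)
  }
  best <- 0L
  for (mask in 0:(2^length(a) - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_along(a) - 1)) > 0)
    if (length(idx) <= best) next
    if (is_subseq(a[idx], b)) best <- length(idx)
  }
  best
}

oracle_rouge_l <- function(hyp, ref, beta = 1) {
  rt <- oracle_tokens(ref)
  ht <- oracle_tokens(hyp)
  if (length(rt) == 0 || length(ht) == 0) return(NA_real_)
  l <- oracle_lcs(rt, ht)
  if (l == 0) return(0)
  r <- l / length(rt)
  p <- l / length(ht)
  (1 + beta^2) * r * p / (r + beta^2 * p)
}

# exhaustive enumeration of all directed paths of length <= k
oracle_ancestors <- function(edges, term, k) {
  found <- list()
  walk <- function(node, depth) {
    if (depth >= k) return()
    parents <- edges$parent[edges$child == node]
    for (p in parents) {
      if (is.null(found[[p]]) || found[[p]] > depth + 1) {
        found[[p]] <<- depth + 1
      }
      walk(p, depth + 1)
    }
  }
  walk(term, 0)
  found[names(found) != term]
}

# random DAG on ids n1..nN: node i may point only to lower-numbered nodes
random_dag <- function(n, p_edge = 0.3) {
  ids <- paste0("n", seq_len(n))
  edges <- list()
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      if (runif(1) < p_edge) {
        edges[[length(edges) + 1]] <- data.frame(
          child = ids[i], parent = ids[j],
          relation = sample(c("is_a", "part_of", "regulates",
                              "negatively_regulates",
                              "positively_regulates"), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ids = ids,
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(child = character(), parent = character(),
                    relation = character(), stringsAsFactors = FALSE))
}

random_phrase <- function(min_len = 1, max_len = 6) {
  vocab <- c("protein", "limb", "cell", "signal", "transport", "membrane",
             "regulation", "of", "the", "pathway", "response", "stress",
             "binding", "nuclear", "division")
  paste(sample(vocab, sample(min_len:max_len, 1), replace = TRUE),
        collapse = " ")
}
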