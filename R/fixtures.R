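# Deterministic stand-ins for every external dependency: a hashed
# bag-of-words text encoder, and a generated "fixture world" — toy
# ontology, synthetic gene sets with planted process names, knowledge bases
# in which each planted name is the rank-1 enrichment hit, and a scripted
# backend transcript — so the full pipeline and all metrics run offline.

#' Deterministic toy text encoder
#'
#' A hashed bag-of-words encoder: each token (via [metric_tokens()]) is
#' hashed into one of `dim` buckets and counted. Identical text always maps
#' to an identical vector, on any platform, which makes every
#' embedding-based metric bit-reproducible. It captures lexical overlap
#' only — none of the distributional semantics of a trained biomedical
#' encoder — so absolute similarity values are not comparable to a live
#' encoder's.
#'
#' @param dim Embedding dimension (default 256).
#' @return A `text_encoder` object with fields `identifier` and
#'   `embed(text)`.
#' @export
#' @examples
#' enc <- toy_encoder()
#' cosine_similarity(enc$embed("limb morphogenesis"),
#'                   enc$embed("limb development"))
toy_encoder <- function(dim = 256L) {
  dim <- as.integer(dim)
  embed <- function(text) {
    v <- numeric(dim)
    for (tok in metric_tokens(text)) {
      idx <- (strtoi(substr(content_digest(tok), 1L, 6L), 16L) %% dim) + 1L
      v[idx] <- v[idx] + 1
    }
    v
  }
  structure(list(identifier = sprintf("toy-bow-%d", dim), embed = embed),
            class = "text_encoder")
}

WORLD_NOUNS <- c(
  "vesicle", "ribosome", "chromatin", "membrane", "spindle", "lysosome",
  "axon", "cilium", "proteasome", "telomere"
)
WORLD_PROCESSES <- c(
  "assembly", "transport", "signaling", "biogenesis", "regulation",
  "repair", "fusion", "maintenance", "remodeling", "clearance"
)

#' Generate a deterministic fixture world
#'
#' Builds, from a single seed: a toy ontology (a DAG using all five
#' relation types), `n_sets` positive gene sets whose planted process name
#' is the rank-1 hit in the fixture enrichment knowledge bases plus
#' per-gene entries in the gene summary database, `n_negative` control sets
#' whose only annotating database is one the masking rules remove (their
#' evidence is withheld during verification), and a scripted transcript
#' recorded from one rule-based pipeline run per set. Replaying the
#' transcript through [scripted_backend()] reproduces every run byte for
#' byte.
#'
#' The rule-based backend behaves like an honest annotator: generation
#' proposes a perturbed name (the planted name plus a spurious word),
#' judgments compare the claimed phrase against the retrieved evidence
#' terms, and revision adopts the top evidence term from the verification
#' report — so positive sets recover their planted name through the
#' evidence flow and negative controls cannot.
#'
#' @param seed Integer seed; the world is fully determined by it and the
#'   size parameters.
#' @param n_terms Ontology terms (>= 12).
#' @param n_genes Gene symbol pool (>= genes needed by the sets).
#' @param n_sets Positive gene sets (>= 1).
#' @param n_negative Negative-control sets (default 3).
#' @param genes_per_set Range of set sizes (default 5 to 8).
#' @return A `fixture_world`: list with `seed`, `ontology`, `gene_sets`,
#'   `negative_sets`, `planted_truth` (named list set id -> name), `kb`
#'   (fixture knowledge base), `transcript`, `background` (all term names).
#' @export
generate_world <- function(seed, n_terms = 50L, n_genes = 200L,
                           n_sets = 10L, n_negative = 3L,
                           genes_per_set = c(5L, 8L)) {
  stopifnot(n_terms >= 12L, n_genes >= 1L, n_sets >= 1L, n_negative >= 0L)
  need <- (n_sets + n_negative) * max(genes_per_set)
  if (n_genes < need) {
    stop("infeasible sizes: ", n_genes, " genes cannot fill ",
         n_sets + n_negative, " disjoint sets of up to ",
         max(genes_per_set), call. = FALSE)
  }
  if (n_terms < n_sets + n_negative) {
    stop("infeasible sizes: need at least one ontology term per set",
         call. = FALSE)
  }
  withr_seed(seed, function() build_world(seed, n_terms, n_genes, n_sets,
                                          n_negative, genes_per_set))
}

build_world <- function(seed, n_terms, n_genes, n_sets, n_negative,
                        genes_per_set) {
  # ontology: term i >= 2 attaches to 1-2 earlier terms by a random relation
  combos <- expand.grid(noun = WORLD_NOUNS, process = WORLD_PROCESSES,
                        stringsAsFactors = FALSE)
  combos <- combos[sample(nrow(combos)), ]
  if (n_terms > nrow(combos)) {
    stop("infeasible sizes: at most ", nrow(combos), " distinct term names",
         call. = FALSE)
  }
  term_ids <- sprintf("SYN:%04d", seq_len(n_terms))
  term_names <- paste(combos$noun[seq_len(n_terms)],
                      combos$process[seq_len(n_terms)])
  nodes <- stats::setNames(term_names, term_ids)
  edges <- list()
  for (i in 2:n_terms) {
    for (p in sample(seq_len(i - 1L), min(i - 1L, sample(1:2, 1)))) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = term_ids[i], parent = term_ids[p],
        relation = sample(ONTOLOGY_RELATIONS, 1), stringsAsFactors = FALSE)
    }
  }
  ontology <- ontology_graph(nodes, do.call(rbind, edges))

  gene_pool <- sprintf("Syg%03d", seq_len(n_genes))
  total_sets <- n_sets + n_negative
  planted_terms <- sample(term_names, total_sets)
  sizes <- sample(seq(genes_per_set[1], genes_per_set[2]), total_sets,
                  replace = TRUE)
  assignment <- split(gene_pool[seq_len(sum(sizes))],
                      rep(seq_len(total_sets), times = sizes))

  kb <- list()
  plant <- function(db, key, terms, ps) {
    recs <- lapply(seq_along(terms), function(r)
      list(term = terms[r], p = ps[r]))
    kb[[db]][[key]] <<- recs
  }

  sets <- list()
  negatives <- list()
  planted_truth <- list()
  for (s in seq_len(total_sets)) {
    positive <- s <= n_sets
    set_id <- sprintf("%s%02d", if (positive) "SET" else "NEG", s)
    genes <- assignment[[s]]
    truth <- planted_terms[s]
    planted_truth[[set_id]] <- truth
    gs <- gene_set(set_id, genes, ground_truth = truth,
                   source = if (positive) "custom" else "MSigDB",
                   species = "synthetic")
    decoys <- sample(setdiff(term_names, truth), 3L)
    ranked <- c(truth, decoys)
    ps <- seq_along(ranked) / 1000  # fixture p-values assigned by rank
    key <- canonical_gene_key(genes)
    if (positive) {
      plant("GO", key, ranked, ps)
      plant("KEGG_2021_Human", key, ranked, ps)
      for (g in genes) {
        plant("Gene", canonical_gene_key(g), truth, 1 / 1000)
      }
      sets[[length(sets) + 1L]] <- gs
    } else {
      # the only annotating database is the one masked for MSigDB sets
      plant("MSigDB_Hallmark_2020", key, ranked, ps)
      negatives[[length(negatives) + 1L]] <- gs
    }
  }

  world <- structure(
    list(seed = seed, ontology = ontology, gene_sets = sets,
         negative_sets = negatives, planted_truth = planted_truth,
         kb = kb, transcript = NULL, background = term_names),
    class = "fixture_world"
  )
  rec <- recording_backend(world_rule_backend(world))
  config <- pipeline_config(rec$backend, fixture_registry(kb))
  for (gs in c(sets, negatives)) run_pipeline(gs, config)
  world$transcript <- rec$transcript()
  world
}

#' @export
print.fixture_world <- function(x, ...) {
  cat(sprintf(
    "<fixture_world seed=%d> %d terms, %d positive sets, %d controls, %d scripted responses\n",
    x$seed, length(x$ontology$nodes), length(x$gene_sets),
    length(x$negative_sets), length(x$transcript)))
  invisible(x)
}

normalized_term <- function(x) paste(metric_tokens(x), collapse = " ")

prompt_field <- function(prompt, field) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", field, ": "), lines, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", field, ": "), "", hit[1])
}

prompt_evidence_terms <- function(prompt) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  lines <- grep("^- \\[", lines, value = TRUE)
  lines <- lines[!grepl("no records$", lines)]
  sub("^- \\[[^]]+\\] ", "", lines)
}

#' Rule-based backend for a fixture world
#'
#' The deterministic generator used to record a world's transcript. It
#' derives every response from the rendered prompt alone: generation
#' returns the planted name perturbed by a spurious token plus a per-gene
#' narrative; judgments compare the claimed phrase with the evidence terms
#' in the prompt; modification adopts the report's top evidence term (or
#' retains the current name when the report carries no evidence);
#' summarization confirms the revised name.
#'
#' @param world A `fixture_world` (the transcript field may still be
#'   unset).
#' @return A `text_backend`.
#' @export
world_rule_backend <- function(world) {
  all_sets <- c(world$gene_sets, world$negative_sets)
  by_key <- stats::setNames(
    all_sets, vapply(all_sets, function(s) canonical_gene_key(s$genes),
                     character(1)))
  narrative_for <- function(genes, name) {
    paste(sprintf("The gene %s is involved in %s.", genes, name),
          collapse = " ")
  }
  function_backend("world-rules", function(prompt, temperature = 0) {
    genes_line <- prompt_field(prompt, "Genes")
    genes <- if (is.na(genes_line)) character() else
      trimws(strsplit(genes_line, ",", fixed = TRUE)[[1]])
    gs <- by_key[[canonical_gene_key(genes)]]
    first <- strsplit(prompt, "\n", fixed = TRUE)[[1]][1]

    if (grepl("propose the most prominent", first)) {
      truth <- world$planted_truth[[gs$set_id]]
      perturbed <- paste(truth, "dynamics")
      return(paste0(perturbed, "\n\n", narrative_for(gs$genes, truth)))
    }
    if (grepl("decide whether the claim", first)) {
      claimed <- prompt_field(prompt, "Claim")
      phrase <- sub(".*involved in ", "", claimed)
      terms <- prompt_evidence_terms(prompt)
      hit <- normalized_term(phrase) %in%
        vapply(terms, normalized_term, character(1))
      return(if (hit) {
        "Supported: the claimed process matches the curated terms."
      } else {
        "Refuted: the curated evidence does not list the claimed process."
      })
    }
    if (grepl("revise or retain", first)) {
      terms <- prompt_evidence_terms(prompt)
      name <- if (length(terms) > 0L) terms[1] else
        prompt_field(prompt, "Current process name")
      return(paste0(name, "\n\n", narrative_for(gs$genes, name)))
    }
    if (grepl("consolidate the verified findings", first)) {
      name <- prompt_field(prompt, "Process name")
      return(paste0(name, "\n\nTaken together, the genes ", genes_line,
                    " act in ", name, "."))
    }
    ""
  })
}

#' Write a fixture world to disk as plain-text files
#'
#' Writes `ontology.obo`, `sets.gmt` (positive sets), `controls.gmt`
#' (negative controls), `kb.json`, `transcript.json` and `background.txt`
#' under `dir`, the file formats the command-line interface consumes.
#'
#' @param world A `fixture_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(world$ontology, file.path(dir, "ontology.obo"))
  write_gene_sets(world$gene_sets, file.path(dir, "sets.gmt"))
  write_gene_sets(world$negative_sets, file.path(dir, "controls.gmt"))
  jsonlite::write_json(world$kb, file.path(dir, "kb.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(world$transcript, file.path(dir, "transcript.json"),
                       auto_unbox = TRUE)
  writeLines(world$background, file.path(dir, "background.txt"))
  invisible(dir)
}

#' Planted-name recovery rate of pipeline runs
#'
#' Fraction of runs whose final process name equals the planted name after
#' normalization ([metric_tokens()] token string equality).
#'
#' @param results List of [pipeline_result()] objects.
#' @param planted_truth Named list/character of set id -> planted name.
#' @return Fraction in `[0, 1]` (`NA` for an empty list).
#' @export
recovery_rate <- function(results, planted_truth) {
  if (length(results) == 0L) return(NA_real_)
  hits <- vapply(results, function(r) {
    truth <- planted_truth[[r$gene_set_id]]
    !is.null(truth) &&
      identical(normalized_term(r$p_final$text), normalized_term(truth))
  }, logical(1))
  mean(hits)
}
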