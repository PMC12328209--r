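# Domain types shared by every module. Plain lists with S3 classes, JSON
# round-trippable with stable field names; no computation beyond validation.

GENE_SET_SOURCES <- c("GO", "NeST", "MSigDB", "custom")
STAGES <- c("initial", "modified", "final")
CLAIM_ORIGINS <- c("process_name", "narrative")
DECISION_CATEGORIES <- c(
  "supported", "partially_supported", "refuted", "unknown", "unverified"
)

#' Construct a gene set
#'
#' A gene set couples an identifier with an ordered list of gene symbols and,
#' optionally, the curated ground-truth name of the function the set shares.
#' Symbols are stored verbatim but always compared case-insensitively, so
#' human upper-case (TP53) and mouse title-case (Trp53) symbols coexist.
#'
#' @param set_id Identifier, unique within a collection.
#' @param genes Character vector of gene symbols, length >= 1.
#' @param ground_truth Optional curated term naming the shared function.
#' @param source Dataset tag: one of `"GO"`, `"NeST"`, `"MSigDB"`,
#'   `"custom"`. Drives the masking rules during verification.
#' @param species Free-text species label.
#' @return A `gene_set` object.
#' @seealso [validate_gene_set()] for cleaning parsed records.
#' @export
#' @examples
#' gene_set("ex1", c("ERBB2", "FGFR2", "KRAS"), ground_truth = "RTK signaling")
gene_set <- function(set_id, genes, ground_truth = NULL, source = "custom",
                     species = "human") {
  validate_gene_set(list(
    id = set_id, genes = genes, ground_truth = ground_truth,
    source = source, species = species
  ))
}

#' Validate and normalize a parsed gene-set record
#'
#' Trims whitespace from symbols and removes case-insensitive duplicates,
#' keeping the first occurrence verbatim. Rejects records with no genes.
#'
#' @param raw A list with fields `id`, `genes`, and optionally
#'   `ground_truth`, `source`, `species`.
#' @return A `gene_set` object.
#' @export
#' @examples
#' validate_gene_set(list(id = "S1", genes = c("Tp53", "TP53", "KRAS")))
validate_gene_set <- function(raw) {
  stopifnot(is.list(raw), !is.null(raw$id))
  set_id <- as.character(raw$id)
  genes <- trimws(as.character(raw$genes %||% character()))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) {
    stop("gene set '", set_id, "' has an empty gene list", call. = FALSE)
  }
  genes <- genes[!duplicated(tolower(genes))]
  source <- match.arg(raw$source %||% "custom", GENE_SET_SOURCES)
  gt <- raw$ground_truth
  if (!is.null(gt) && (is.na(gt) || !nzchar(gt))) gt <- NULL
  structure(
    list(
      set_id = set_id,
      genes = genes,
      ground_truth = if (is.null(gt)) NULL else as.character(gt),
      source = source,
      species = as.character(raw$species %||% "human")
    ),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf(
    "<gene_set %s> %d genes (%s)%s\n", x$set_id, length(x$genes), x$source,
    if (is.null(x$ground_truth)) "" else paste0(" truth: ", x$ground_truth)
  ))
  cat(" ", paste(head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Construct a process name at a pipeline stage
#'
#' @param text Non-empty term string naming the biological process.
#' @param stage `"initial"`, `"modified"` or `"final"`.
#' @return A `process_name` object.
#' @export
process_name <- function(text, stage) {
  stage <- match.arg(stage, STAGES)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  structure(list(text = text, stage = stage), class = "process_name")
}

#' Construct an analytical narrative at a pipeline stage
#'
#' The multi-paragraph analysis of individual gene functions that accompanies
#' a process name.
#'
#' @param text Narrative text (may span paragraphs).
#' @param stage `"initial"`, `"modified"` or `"final"`.
#' @return A `narrative` object.
#' @export
narrative <- function(text, stage) {
  stage <- match.arg(stage, STAGES)
  stopifnot(is.character(text), length(text) == 1L)
  structure(list(text = text, stage = stage), class = "narrative")
}

#' Construct a claim
#'
#' A claim is an affirmative sentence linking gene symbols to a function
#' phrase, extracted from a pipeline stage's output so it can be verified
#' against knowledge sources. The claim id is a deterministic digest of
#' `(origin, raw_text)`, so reruns are diffable.
#'
#' @param genes Gene symbols the claim is about (may be empty when
#'   extraction found none; the claim is then unverifiable).
#' @param function_phrase The function the genes are claimed to share.
#' @param origin `"process_name"` or `"narrative"`.
#' @param raw_text The full claim sentence (non-empty).
#' @return A `claim` object.
#' @export
claim <- function(genes, function_phrase, origin, raw_text) {
  origin <- match.arg(origin, CLAIM_ORIGINS)
  stopifnot(is.character(raw_text), length(raw_text) == 1L, nzchar(raw_text))
  structure(
    list(
      claim_id = content_digest(paste0(origin, "\x1f", raw_text)),
      genes = as.character(genes),
      function_phrase = as.character(function_phrase),
      origin = origin,
      raw_text = raw_text
    ),
    class = "claim"
  )
}

#' Construct an evidence item
#'
#' One knowledge source's contribution to verifying a claim: the ranked
#' terms it returned for the queried genes, capped at the source's rank
#' limit (5 for enrichment sources, 10 for gene-centric sources).
#'
#' @param source_id Knowledge-source identifier.
#' @param database_name Backend database the terms came from.
#' @param query_genes Genes used in the query.
#' @param retrieved_terms A data.frame with columns `term`, `description`,
#'   `score` (ranked; may have zero rows).
#' @param rank_limit The source's rank limit.
#' @return An `evidence_item` object.
#' @export
evidence_item <- function(source_id, database_name, query_genes,
                          retrieved_terms, rank_limit) {
  terms <- as_term_frame(retrieved_terms)
  if (nrow(terms) > rank_limit) terms <- terms[seq_len(rank_limit), , drop = FALSE]
  structure(
    list(
      source_id = source_id,
      database_name = database_name,
      query_genes = as.character(query_genes),
      retrieved_terms = terms,
      retrieved_at_rank_limit = as.integer(rank_limit)
    ),
    class = "evidence_item"
  )
}

as_term_frame <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(data.frame(term = character(), description = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  if (is.character(x)) x <- data.frame(term = x, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x), "term" %in% names(x))
  if (is.null(x$description)) x$description <- NA_character_
  if (is.null(x$score)) x$score <- NA_real_
  rownames(x) <- NULL
  x[, c("term", "description", "score"), drop = FALSE]
}

#' Construct a verification decision
#'
#' @param category One of `"supported"`, `"partially_supported"`,
#'   `"refuted"`, `"unknown"`, `"unverified"`. `unverified` is reserved for
#'   claims whose extraction produced no gene symbols, so no knowledge
#'   source could be queried.
#' @param rationale Free-text justification (the judge's words, or the
#'   reason verification could not run).
#' @return A `decision` object.
#' @export
decision <- function(category, rationale = "") {
  category <- match.arg(category, DECISION_CATEGORIES)
  structure(list(category = category, rationale = as.character(rationale)),
            class = "decision")
}

#' Construct a verification report
#'
#' Couples every claim extracted from one stage's output with the evidence
#' gathered for it and exactly one decision.
#'
#' @param target_stage `"process_name"` or `"narrative"`.
#' @param entries A list of lists, each with fields `claim` ([claim()]),
#'   `evidence` (list of [evidence_item()]) and `decision` ([decision()]).
#' @return A `verification_report` object.
#' @export
verification_report <- function(target_stage, entries) {
  target_stage <- match.arg(target_stage, CLAIM_ORIGINS)
  for (e in entries) {
    stopifnot(inherits(e$claim, "claim"), inherits(e$decision, "decision"))
  }
  ids <- vapply(entries, function(e) e$claim$claim_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate claim in verification report", call. = FALSE)
  }
  structure(list(target_stage = target_stage, entries = entries),
            class = "verification_report")
}

#' Decision categories of a verification report
#'
#' @param report A [verification_report()].
#' @return Character vector, one category per entry.
#' @export
report_decisions <- function(report) {
  vapply(report$entries, function(e) e$decision$category, character(1))
}

#' Construct a full pipeline trace
#'
#' The complete record of one annotation run: initial, modified and final
#' process names and narratives, the two verification reports (the process
#' name is verified twice: once directly and once inside the revised
#' narrative), and the ordered log of every backend and knowledge-source
#' call.
#'
#' @param gene_set_id Identifier of the annotated set.
#' @param p_initial,p_modified,p_final [process_name()] objects.
#' @param a_initial,a_modified,a_final [narrative()] objects.
#' @param report_p Report for the process name ([verification_report()]).
#' @param report_a Report for the narrative ([verification_report()]).
#' @param call_log A data.frame with columns `backend`, `request_digest`,
#'   `response_digest` in call order.
#' @return A `pipeline_result` object.
#' @export
pipeline_result <- function(gene_set_id, p_initial, a_initial, report_p,
                            p_modified, a_modified, report_a,
                            p_final, a_final, call_log) {
  stopifnot(
    inherits(report_p, "verification_report"),
    inherits(report_a, "verification_report"),
    identical(report_p$target_stage, "process_name"),
    identical(report_a$target_stage, "narrative")
  )
  structure(
    list(
      gene_set_id = gene_set_id,
      p_initial = p_initial, a_initial = a_initial, report_p = report_p,
      p_modified = p_modified, a_modified = a_modified, report_a = report_a,
      p_final = p_final, a_final = a_final,
      call_log = call_log
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result %s>\n", x$gene_set_id))
  cat("  initial :", x$p_initial$text, "\n")
  cat("  modified:", x$p_modified$text, "\n")
  cat("  final   :", x$p_final$text, "\n")
  dp <- table(report_decisions(x$report_p))
  da <- table(report_decisions(x$report_a))
  cat("  report_p:", paste(names(dp), dp, sep = "=", collapse = " "), "\n")
  cat("  report_a:", paste(names(da), da, sep = "=", collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
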