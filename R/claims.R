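# Claim generation and entity extraction. Claims are produced by a
# deterministic sentence grammar (not by the text backend): one claim ties
# the full gene list to the process name, and one claim per gene-function
# pair is mined from the narrative's sentences.

LINKING_PHRASES <- c(
  "are involved in", "is involved in", "be involved in", "involved in",
  "are related to", "is related to", "related to",
  "play a role in", "plays a role in"
)

#' Generate claims for a process name
#'
#' Emits a single affirmative claim asserting that the full gene list is
#' involved in the proposed process, using the claim grammar template.
#'
#' @param gene_set A [gene_set()].
#' @param p A [process_name()] (any stage).
#' @param prompts Stage templates from [stage_prompts()].
#' @return A list with one [claim()] of origin `"process_name"`.
#' @export
#' @examples
#' gs <- gene_set("ex", c("KRAS", "HRAS"))
#' make_claims_from_process(gs, process_name("RTK signaling", "initial"))
make_claims_from_process <- function(gene_set, p, prompts = stage_prompts()) {
  stopifnot(inherits(gene_set, "gene_set"), inherits(p, "process_name"))
  raw <- render_prompt(prompts$claim_from_process, list(
    genes = paste(gene_set$genes, collapse = ", "),
    process_name = p$text
  ))
  list(claim(gene_set$genes, p$text, "process_name", raw))
}

#' Mine gene-function claims from a narrative
#'
#' Splits the narrative into sentences and, for each sentence that names at
#' least one gene from the set's vocabulary together with a linking phrase
#' ("is involved in", "related to", ...), emits one claim per gene-function
#' pair. Sentences naming no gene contribute no claim.
#'
#' @param gene_set A [gene_set()]; its symbols are the extraction vocabulary.
#' @param a A [narrative()].
#' @param prompts Stage templates from [stage_prompts()].
#' @return A list of [claim()] objects of origin `"narrative"` (possibly
#'   empty).
#' @export
make_claims_from_narrative <- function(gene_set, a, prompts = stage_prompts()) {
  stopifnot(inherits(gene_set, "gene_set"), inherits(a, "narrative"))
  sentences <- split_sentences(a$text)
  claims <- list()
  for (s in sentences) {
    hit <- extract_entities(s, gene_set$genes)
    if (length(hit$genes) == 0L || !nzchar(hit$function_phrase)) next
    for (g in hit$genes) {
      raw <- render_prompt(prompts$claim_from_narrative, list(
        genes = g, function_phrase = hit$function_phrase
      ))
      claims[[length(claims) + 1L]] <- claim(g, hit$function_phrase,
                                             "narrative", raw)
    }
  }
  claims
}

split_sentences <- function(text) {
  parts <- unlist(strsplit(text, "(?<=[.!?])\\s+|\\n+", perl = TRUE))
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Extract gene symbols and the function phrase from a claim sentence
#'
#' Gene symbols are recovered by case-insensitive token matching against the
#' input set's vocabulary (matched symbols are reported in the vocabulary's
#' casing, in order of first appearance). The function phrase is the text
#' trailing the first linking phrase, with surrounding punctuation stripped.
#' A sentence with no vocabulary hit yields an empty gene list; such a claim
#' is later marked `unverified`.
#'
#' @param x A [claim()] or a raw sentence string.
#' @param vocabulary Character vector of candidate gene symbols.
#' @return A list with fields `genes` and `function_phrase`.
#' @export
#' @examples
#' extract_entities("KRAS, HRAS is involved in RTK signaling",
#'                  c("KRAS", "HRAS", "TP53"))
extract_entities <- function(x, vocabulary) {
  text <- if (inherits(x, "claim")) x$raw_text else x
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(text, "[^A-Za-z0-9_-]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  idx <- match(tolower(tokens), tolower(vocabulary))
  genes <- vocabulary[unique(idx[!is.na(idx)])]

  phrase <- ""
  lowered <- tolower(text)
  for (link in LINKING_PHRASES) {
    pos <- regexpr(link, lowered, fixed = TRUE)
    if (pos > 0L) {
      phrase <- substr(text, pos + attr(pos, "match.length"), nchar(text))
      phrase <- trimws(gsub("[[:punct:][:space:]]+$", "", trimws(phrase)))
      break
    }
  }
  list(genes = as.character(genes), function_phrase = phrase)
}

#' Parse a verification decision from judge text
#'
#' Scans case-insensitively for "partially supported" first, then
#' "refuted", then "supported"; the precedence resolves the substring
#' ambiguity ("supported" occurs inside "partially supported"). Text with
#' no explicit decision parses to `unknown`.
#'
#' @param judge_text The verifying backend's response.
#' @return A [decision()] whose rationale is the judge text.
#' @export
#' @examples
#' parse_decision("The claim is partially supported because ...")$category
parse_decision <- function(judge_text) {
  if (is.null(judge_text) || is.na(judge_text)) judge_text <- ""
  lowered <- tolower(judge_text)
  category <- if (grepl("partially supported", lowered, fixed = TRUE)) {
    "partially_supported"
  } else if (grepl("refuted", lowered, fixed = TRUE)) {
    "refuted"
  } else if (grepl("supported", lowered, fixed = TRUE)) {
    "supported"
  } else {
    "unknown"
  }
  decision(category, judge_text)
}
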