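# JSON serialization with stable field names for every domain type, plus
# JSONL emission for claims and report entries. to_json_obj() produces plain
# R structures that jsonlite renders deterministically; from_json_obj()
# inverts them, so serialize -> parse is an identity on valid objects.

#' Convert a domain object to a JSON-ready structure
#'
#' @param x A package domain object (gene_set, claim, evidence_item,
#'   decision, verification_report, pipeline_result, process_name,
#'   narrative).
#' @return A named list mirroring the object's fields, with a `type` tag.
#' @export
to_json_obj <- function(x) UseMethod("to_json_obj")

#' @export
to_json_obj.gene_set <- function(x) {
  list(type = "gene_set", set_id = x$set_id, genes = as.list(x$genes),
       ground_truth = x$ground_truth, source = x$source, species = x$species)
}

#' @export
to_json_obj.process_name <- function(x) {
  list(type = "process_name", text = x$text, stage = x$stage)
}

#' @export
to_json_obj.narrative <- function(x) {
  list(type = "narrative", text = x$text, stage = x$stage)
}

#' @export
to_json_obj.claim <- function(x) {
  list(type = "claim", claim_id = x$claim_id, genes = as.list(x$genes),
       function_phrase = x$function_phrase, origin = x$origin,
       raw_text = x$raw_text)
}

#' @export
to_json_obj.evidence_item <- function(x) {
  list(
    type = "evidence_item", source_id = x$source_id,
    database_name = x$database_name, query_genes = as.list(x$query_genes),
    retrieved_terms = lapply(seq_len(nrow(x$retrieved_terms)), function(i) {
      r <- x$retrieved_terms[i, ]
      list(term = r$term,
           description = if (is.na(r$description)) NULL else r$description,
           score = if (is.na(r$score)) NULL else r$score)
    }),
    retrieved_at_rank_limit = x$retrieved_at_rank_limit
  )
}

#' @export
to_json_obj.decision <- function(x) {
  list(type = "decision", category = x$category, rationale = x$rationale)
}

#' @export
to_json_obj.verification_report <- function(x) {
  list(
    type = "verification_report", target_stage = x$target_stage,
    entries = lapply(x$entries, function(e) {
      list(claim = to_json_obj(e$claim),
           evidence = lapply(e$evidence, to_json_obj),
           decision = to_json_obj(e$decision))
    })
  )
}

#' @export
to_json_obj.pipeline_result <- function(x) {
  list(
    type = "pipeline_result", schema_version = "1",
    gene_set_id = x$gene_set_id,
    p_initial = to_json_obj(x$p_initial), a_initial = to_json_obj(x$a_initial),
    report_p = to_json_obj(x$report_p),
    p_modified = to_json_obj(x$p_modified),
    a_modified = to_json_obj(x$a_modified),
    report_a = to_json_obj(x$report_a),
    p_final = to_json_obj(x$p_final), a_final = to_json_obj(x$a_final),
    call_log = lapply(seq_len(nrow(x$call_log)), function(i) {
      as.list(x$call_log[i, c("backend", "request_digest", "response_digest")])
    })
  )
}

#' Rebuild a domain object from its JSON structure
#'
#' Inverse of [to_json_obj()]; dispatches on the `type` tag.
#'
#' @param obj A named list as produced by [to_json_obj()] (or parsed back
#'   from its JSON rendering with `simplifyVector = FALSE`).
#' @return The reconstructed domain object.
#' @export
from_json_obj <- function(obj) {
  switch(obj$type,
    gene_set = structure(list(
      set_id = obj$set_id, genes = as.character(unlist(obj$genes)),
      ground_truth = obj$ground_truth, source = obj$source,
      species = obj$species
    ), class = "gene_set"),
    process_name = process_name(obj$text, obj$stage),
    narrative = narrative(obj$text, obj$stage),
    claim = claim(as.character(unlist(obj$genes)), obj$function_phrase,
                  obj$origin, obj$raw_text),
    evidence_item = evidence_item(
      obj$source_id, obj$database_name, as.character(unlist(obj$query_genes)),
      if (length(obj$retrieved_terms) == 0L) NULL else data.frame(
        term = vapply(obj$retrieved_terms, `[[`, character(1), "term"),
        description = vapply(obj$retrieved_terms, function(t)
          t$description %||% NA_character_, character(1)),
        score = vapply(obj$retrieved_terms, function(t)
          t$score %||% NA_real_, numeric(1)),
        stringsAsFactors = FALSE
      ),
      obj$retrieved_at_rank_limit
    ),
    decision = decision(obj$category, obj$rationale),
    verification_report = verification_report(
      obj$target_stage,
      lapply(obj$entries, function(e) list(
        claim = from_json_obj(e$claim),
        evidence = lapply(e$evidence, from_json_obj),
        decision = from_json_obj(e$decision)
      ))
    ),
    pipeline_result = pipeline_result(
      obj$gene_set_id,
      from_json_obj(obj$p_initial), from_json_obj(obj$a_initial),
      from_json_obj(obj$report_p),
      from_json_obj(obj$p_modified), from_json_obj(obj$a_modified),
      from_json_obj(obj$report_a),
      from_json_obj(obj$p_final), from_json_obj(obj$a_final),
      call_log = if (length(obj$call_log) == 0L) empty_call_log() else
        do.call(rbind, lapply(obj$call_log, function(r)
          data.frame(backend = r$backend, request_digest = r$request_digest,
                     response_digest = r$response_digest,
                     stringsAsFactors = FALSE)))
    ),
    stop("unknown serialized type: ", obj$type, call. = FALSE)
  )
}

#' Serialize a domain object to a JSON string
#'
#' @param x A package domain object.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string with stable key order.
#' @export
to_json <- function(x, pretty = FALSE) {
  jsonlite::toJSON(to_json_obj(x), auto_unbox = TRUE, null = "null",
                   digits = NA, pretty = pretty)
}

#' Parse a domain object from a JSON string
#'
#' @param txt JSON text produced by [to_json()].
#' @return The reconstructed domain object.
#' @export
from_json <- function(txt) {
  from_json_obj(jsonlite::fromJSON(txt, simplifyVector = FALSE))
}

#' Write claims or report entries as JSONL
#'
#' One JSON object per line: claims directly, or a report's entries.
#'
#' @param x A list of [claim()] objects or a [verification_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(x, path) {
  objs <- if (inherits(x, "verification_report")) {
    lapply(x$entries, function(e) list(
      claim = to_json_obj(e$claim), evidence = lapply(e$evidence, to_json_obj),
      decision = to_json_obj(e$decision)
    ))
  } else {
    lapply(x, to_json_obj)
  }
  lines <- vapply(objs, function(o)
    as.character(jsonlite::toJSON(o, auto_unbox = TRUE, null = "null",
                                  digits = NA)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

empty_call_log <- function() {
  data.frame(backend = character(), request_digest = character(),
             response_digest = character(), stringsAsFactors = FALSE)
}
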