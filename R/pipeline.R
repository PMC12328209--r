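# The four-stage cascade: generation -> self-verification of the process
# name -> modification -> self-verification of the revised narrative ->
# summarization. Every text-generation call goes through the pluggable
# backend at temperature 0; every knowledge query goes through the
# mask-filtered source registry. The pipeline is seed-free: with a scripted
# backend and fixture sources two runs are byte-identical.

make_call_log <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  env$add <- function(backend, request_digest, response_digest) {
    env$entries[[length(env$entries) + 1L]] <- list(
      backend = backend, request_digest = request_digest,
      response_digest = response_digest
    )
  }
  env
}

call_log_frame <- function(log) {
  if (is.null(log) || length(log$entries) == 0L) return(empty_call_log())
  do.call(rbind, lapply(log$entries, function(e)
    data.frame(backend = e$backend, request_digest = e$request_digest,
               response_digest = e$response_digest, stringsAsFactors = FALSE)))
}

logged_generate <- function(backend, prompt, log = NULL, temperature = 0) {
  out <- backend_generate(backend, prompt, temperature)
  if (!is.null(log)) {
    log$add(backend$identifier, prompt_digest(prompt), content_digest(out))
  }
  out
}

# Split a backend response into (name, narrative): name is the first
# non-empty line, the narrative is everything after the first blank line.
# A response with no narrative portion reuses its full text, so both parts
# are non-empty whenever the response is.
split_name_narrative <- function(response) {
  lines <- strsplit(response, "\n", fixed = TRUE)[[1]]
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list(name = "", narrative = ""))
  name <- trimws(lines[nonblank[1]])
  blank_after <- which(!nzchar(trimws(lines)) & seq_along(lines) > nonblank[1])
  narr <- if (length(blank_after) > 0L) {
    trimws(paste(lines[seq(blank_after[1] + 1L, length(lines))],
                 collapse = "\n"))
  } else ""
  if (!nzchar(narr)) narr <- trimws(response)
  list(name = name, narrative = narr)
}

#' Configure a pipeline run
#'
#' @param backend The generating [text backend][function_backend()].
#' @param registry The [source_registry()] of knowledge sources.
#' @param judge Backend used for verification judgments; defaults to
#'   `backend`.
#' @param prompts Stage templates ([stage_prompts()]).
#' @param evidence_budget Character budget for the evidence digest handed to
#'   the judge and revision prompts; truncation respects whole-term (line)
#'   boundaries. Default 4000.
#' @param regenerate_narrative `"on_change"` (default) regenerates the
#'   narrative only when the process name is revised; `"always"` lets the
#'   backend rewrite it even when every claim was supported.
#' @param mask_rules Masking rules ([default_mask_rules()]).
#' @param temperature Sampling temperature, default 0 (deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(backend, registry, judge = NULL,
                            prompts = stage_prompts(),
                            evidence_budget = 4000,
                            regenerate_narrative = c("on_change", "always"),
                            mask_rules = default_mask_rules(),
                            temperature = 0) {
  stopifnot(inherits(backend, "text_backend"),
            inherits(registry, "source_registry"))
  structure(
    list(backend = backend, registry = registry,
         judge = judge %||% backend, prompts = prompts,
         evidence_budget = evidence_budget,
         regenerate_narrative = match.arg(regenerate_narrative),
         mask_rules = mask_rules, temperature = temperature),
    class = "pipeline_config"
  )
}

#' Generation stage
#'
#' Prompts the backend with the comma-separated gene list and parses the
#' response into the initial process name and analytical narrative.
#'
#' @param gene_set A [gene_set()].
#' @param backend A text backend.
#' @param prompts Stage templates.
#' @param log Internal call log (optional).
#' @param temperature Sampling temperature (default 0).
#' @return List with `p` ([process_name()], stage initial) and `a`
#'   ([narrative()], stage initial).
#' @export
run_generation <- function(gene_set, backend, prompts = stage_prompts(),
                           log = NULL, temperature = 0) {
  prompt <- render_prompt(prompts$generation, list(
    genes = paste(gene_set$genes, collapse = ", ")
  ))
  response <- logged_generate(backend, prompt, log, temperature)
  parts <- split_name_narrative(response)
  if (!nzchar(parts$name)) {
    stop("generation backend returned empty text for gene set '",
         gene_set$set_id, "'", call. = FALSE)
  }
  list(p = process_name(parts$name, "initial"),
       a = narrative(parts$narrative, "initial"))
}

# Render gathered evidence for the judge / revision prompts, truncated at
# whole-line boundaries to the configured character budget.
evidence_digest_text <- function(evidence, budget = 4000) {
  lines <- unlist(lapply(evidence, function(item) {
    if (nrow(item$retrieved_terms) == 0L) {
      return(sprintf("- [%s/%s] no records", item$source_id,
                     item$database_name))
    }
    vapply(seq_len(nrow(item$retrieved_terms)), function(i) {
      r <- item$retrieved_terms[i, ]
      sprintf("- [%s/%s] %s%s", item$source_id, item$database_name, r$term,
              if (is.na(r$description)) "" else paste0(": ", r$description))
    }, character(1))
  }))
  if (length(lines) == 0L) return("(no evidence retrieved)")
  out <- character()
  used <- 0L
  for (l in lines) {
    if (used + nchar(l) + 1L > budget) break
    out <- c(out, l)
    used <- used + nchar(l) + 1L
  }
  paste(out, collapse = "\n")
}

report_digest_text <- function(report, budget = 4000) {
  lines <- unlist(lapply(report$entries, function(e) {
    c(sprintf("claim: %s", e$claim$raw_text),
      sprintf("decision: %s", e$decision$category),
      evidence_digest_text(e$evidence, budget))
  }))
  paste(lines, collapse = "\n")
}

#' Verify one claim against the knowledge sources
#'
#' A claim with no extracted gene symbols is `unverified` and triggers no
#' query. Otherwise multi-gene claims consult the enrichment sources and
#' single-gene claims the gene-centric ones; each queried source
#' contributes at most one evidence item (pooled over its databases and
#' truncated at its rank limit). The evidence digest is handed to the judge
#' backend, whose text is parsed with [parse_decision()]. If every queried
#' source fails in transport the decision is `unknown` and the rationale
#' records the failures.
#'
#' @param cl A [claim()].
#' @param registry A mask-filtered [source_registry()].
#' @param judge Judging text backend.
#' @param prompts Stage templates.
#' @param evidence_budget Character budget for the evidence digest.
#' @param log Internal call log (optional).
#' @param temperature Sampling temperature (default 0).
#' @return List with `evidence` (list of [evidence_item()]) and `decision`
#'   ([decision()]).
#' @export
verify_claim <- function(cl, registry, judge, prompts = stage_prompts(),
                         evidence_budget = 4000, log = NULL,
                         temperature = 0) {
  stopifnot(inherits(cl, "claim"))
  if (length(cl$genes) == 0L) {
    return(list(
      evidence = list(),
      decision = decision("unverified",
                          "no gene symbols available to query the sources")
    ))
  }
  wanted <- if (length(cl$genes) > 1L) ENRICHMENT_SOURCES else
    GENE_CENTRIC_SOURCES
  evidence <- list()
  failures <- character()
  for (sid in wanted) {
    descriptor <- registry$descriptors[[sid]]
    if (is.null(descriptor)) next
    item <- tryCatch({
      if (sid %in% ENRICHMENT_SOURCES) {
        query_enrichment(cl$genes, descriptor, registry)
      } else {
        frames <- lapply(descriptor$databases, function(db)
          registry_fetch(registry, descriptor, cl$genes, db))
        terms <- do.call(rbind, c(list(as_term_frame(NULL)),
                                  lapply(frames, as_term_frame)))
        evidence_item(sid, paste(descriptor$databases, collapse = "+"),
                      cl$genes, terms, descriptor$rank_limit)
      }
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", sid, conditionMessage(e)))
      NULL
    })
    if (!is.null(item)) evidence[[length(evidence) + 1L]] <- item
  }
  if (length(evidence) == 0L && length(failures) > 0L) {
    return(list(
      evidence = list(),
      decision = decision("unknown",
                          paste("all sources failed:",
                                paste(failures, collapse = "; ")))
    ))
  }
  prompt <- render_prompt(prompts$verification_judgment, list(
    claim = cl$raw_text,
    evidence = evidence_digest_text(evidence, evidence_budget)
  ))
  judged <- logged_generate(judge, prompt, log, temperature)
  list(evidence = evidence, decision = parse_decision(judged))
}

verify_claims <- function(claims, target_stage, config, registry, log) {
  entries <- lapply(claims, function(cl) {
    v <- verify_claim(cl, registry, config$judge, config$prompts,
                      config$evidence_budget, log, config$temperature)
    list(claim = cl, evidence = v$evidence, decision = v$decision)
  })
  verification_report(target_stage, entries)
}

#' Modification stage
#'
#' Retains the initial process name when every decision in the report is
#' `supported`; otherwise asks the backend to revise it in light of the
#' report. With the default configuration the narrative is regenerated only
#' when the process name changes. An empty backend response retains the
#' initial values with a warning.
#'
#' @param p_ini,a_ini Initial [process_name()] and [narrative()].
#' @param report_p The process-name [verification_report()].
#' @param backend Text backend.
#' @param gene_set The [gene_set()] under annotation.
#' @param prompts Stage templates.
#' @param regenerate_narrative `"on_change"` or `"always"`.
#' @param evidence_budget Character budget for the report digest.
#' @param log Internal call log (optional).
#' @param temperature Sampling temperature (default 0).
#' @return List with `p` and `a` at stage `"modified"`.
#' @export
run_modification <- function(p_ini, a_ini, report_p, backend, gene_set,
                             prompts = stage_prompts(),
                             regenerate_narrative = "on_change",
                             evidence_budget = 4000, log = NULL,
                             temperature = 0) {
  stopifnot(identical(report_p$target_stage, "process_name"))
  cats <- report_decisions(report_p)
  all_supported <- length(cats) > 0L && all(cats == "supported")
  if (all_supported && regenerate_narrative == "on_change") {
    return(list(p = process_name(p_ini$text, "modified"),
                a = narrative(a_ini$text, "modified")))
  }
  prompt <- render_prompt(prompts$modification, list(
    genes = paste(gene_set$genes, collapse = ", "),
    process_name = p_ini$text,
    narrative = a_ini$text,
    evidence = report_digest_text(report_p, evidence_budget)
  ))
  response <- logged_generate(backend, prompt, log, temperature)
  parts <- split_name_narrative(response)
  if (!nzchar(parts$name)) {
    warning("modification backend returned empty text for gene set '",
            gene_set$set_id, "'; retaining initial output", call. = FALSE)
    return(list(p = process_name(p_ini$text, "modified"),
                a = narrative(a_ini$text, "modified")))
  }
  p_mod <- process_name(parts$name, "modified")
  a_mod <- if (identical(parts$name, p_ini$text) &&
               regenerate_narrative == "on_change") {
    narrative(a_ini$text, "modified")
  } else {
    narrative(parts$narrative, "modified")
  }
  list(p = p_mod, a = a_mod)
}

#' Summarization stage
#'
#' Consolidates the revised outputs and the narrative verification report
#' into the final process name and narrative. The prompt carries a content
#' digest of the report, so a scripted transcript pins the exact report the
#' summarization saw. An empty backend response retains the modified
#' values.
#'
#' @param p_mod,a_mod Modified [process_name()] and [narrative()].
#' @param report_a The narrative [verification_report()].
#' @param backend Text backend.
#' @param gene_set The [gene_set()] under annotation.
#' @param prompts Stage templates.
#' @param evidence_budget Character budget for the report digest.
#' @param log Internal call log (optional).
#' @param temperature Sampling temperature (default 0).
#' @return List with `p` and `a` at stage `"final"`.
#' @export
run_summarization <- function(p_mod, a_mod, report_a, backend, gene_set,
                              prompts = stage_prompts(),
                              evidence_budget = 4000, log = NULL,
                              temperature = 0) {
  stopifnot(identical(report_a$target_stage, "narrative"))
  prompt <- render_prompt(prompts$summarization, list(
    genes = paste(gene_set$genes, collapse = ", "),
    process_name = p_mod$text,
    narrative = a_mod$text,
    report_digest = content_digest(as.character(to_json(report_a))),
    evidence = report_digest_text(report_a, evidence_budget)
  ))
  response <- logged_generate(backend, prompt, log, temperature)
  parts <- split_name_narrative(response)
  if (!nzchar(parts$name)) {
    return(list(p = process_name(p_mod$text, "final"),
                a = narrative(a_mod$text, "final")))
  }
  list(p = process_name(parts$name, "final"),
       a = narrative(parts$narrative, "final"))
}

#' Run the full annotation pipeline on one gene set
#'
#' Executes the stages in fixed order: generation, claim extraction from
#' the process name, verification (report one), modification, claim mining
#' from the revised narrative, verification (report two), summarization.
#' The process name is thereby verified twice. Any stage error aborts with
#' the partial trace preserved in the error condition.
#'
#' @param gene_set A [gene_set()].
#' @param config A [pipeline_config()].
#' @return A [pipeline_result()].
#' @export
run_pipeline <- function(gene_set, config) {
  stopifnot(inherits(gene_set, "gene_set"),
            inherits(config, "pipeline_config"))
  log <- make_call_log()
  registry <- apply_mask(config$registry, gene_set, config$mask_rules)
  registry$run_log <- log  # transport calls join the run's call log
  trace <- list(gene_set_id = gene_set$set_id)

  run_stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf(
        "pipeline stage '%s' failed for gene set '%s': %s",
        what, gene_set$set_id, conditionMessage(e)))
      class(cond) <- c("veriset_stage_error", class(cond))
      cond$partial_trace <- trace
      cond$partial_trace$call_log <- call_log_frame(log)
      stop(cond)
    })
  }

  gen <- run_stage("generation", run_generation(
    gene_set, config$backend, config$prompts, log, config$temperature))
  trace$p_initial <- gen$p
  trace$a_initial <- gen$a

  claims_p <- make_claims_from_process(gene_set, gen$p, config$prompts)
  report_p <- run_stage("verification_p", verify_claims(
    claims_p, "process_name", config, registry, log))
  trace$report_p <- report_p

  mod <- run_stage("modification", run_modification(
    gen$p, gen$a, report_p, config$backend, gene_set, config$prompts,
    config$regenerate_narrative, config$evidence_budget, log,
    config$temperature))
  trace$p_modified <- mod$p
  trace$a_modified <- mod$a

  claims_a <- make_claims_from_narrative(gene_set, mod$a, config$prompts)
  report_a <- run_stage("verification_a", verify_claims(
    claims_a, "narrative", config, registry, log))
  trace$report_a <- report_a

  fin <- run_stage("summarization", run_summarization(
    mod$p, mod$a, report_a, config$backend, gene_set, config$prompts,
    config$evidence_budget, log, config$temperature))

  pipeline_result(
    gene_set$set_id,
    gen$p, gen$a, report_p,
    mod$p, mod$a, report_a,
    fin$p, fin$a,
    call_log_frame(log)
  )
}
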