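# Text-generation backend contract and its deterministic implementations.
# A backend is a list(identifier, generate(prompt, temperature)); at
# temperature 0 generate() must be a pure function of the prompt. The
# pipeline only ever calls backends at temperature 0.

#' Create a text-generation backend from a function
#'
#' Wraps any `function(prompt, temperature)` (or `function(prompt)`) as a
#' backend satisfying the pipeline's contract. At temperature 0 the function
#' must be deterministic for a fixed prompt.
#'
#' @param identifier Backend id recorded in call logs.
#' @param fn The generating function; must return a character scalar.
#' @return A `text_backend` object.
#' @export
#' @examples
#' echo <- function_backend("echo", function(prompt, temperature) prompt)
#' backend_generate(echo, "hi")
function_backend <- function(identifier, fn) {
  stopifnot(is.function(fn))
  structure(list(identifier = identifier, fn = fn), class = "text_backend")
}

#' Create a scripted backend from a transcript
#'
#' A transcript is a named list (or JSON file) mapping [prompt_digest()]
#' values to response texts. Replaying a pipeline run through its recorded
#' transcript reproduces it byte for byte; a prompt absent from the
#' transcript yields an empty response, which the pipeline stages degrade
#' on gracefully.
#'
#' @param transcript Named list/character vector of digest -> response, or
#'   the path of a JSON file holding one.
#' @param identifier Backend id recorded in call logs.
#' @return A `text_backend` object.
#' @export
scripted_backend <- function(transcript, identifier = "scripted") {
  if (is.character(transcript) && length(transcript) == 1L &&
      file.exists(transcript)) {
    transcript <- jsonlite::fromJSON(transcript, simplifyVector = FALSE)
  }
  transcript <- lapply(as.list(transcript), as.character)
  function_backend(identifier, function(prompt, temperature = 0) {
    transcript[[prompt_digest(prompt)]] %||% ""
  })
}

#' Invoke a backend
#'
#' @param backend A `text_backend`.
#' @param prompt Fully rendered prompt string.
#' @param temperature Sampling temperature; the pipeline always passes 0 so
#'   runs are reproducible.
#' @return The backend's response text (character scalar).
#' @export
backend_generate <- function(backend, prompt, temperature = 0) {
  stopifnot(inherits(backend, "text_backend"))
  out <- if (length(formals(backend$fn)) >= 2L) {
    backend$fn(prompt, temperature)
  } else {
    backend$fn(prompt)
  }
  if (length(out) != 1L || is.na(out)) out <- ""
  as.character(out)
}

#' Record every prompt/response pair a backend sees
#'
#' Wraps a backend so that each call is appended to an environment-held
#' transcript (digest -> response). Used to freeze rule-based fixture
#' backends into replayable scripted transcripts.
#'
#' @param backend The backend to wrap.
#' @return A list with elements `backend` (the wrapped `text_backend`) and
#'   `transcript()` (a function returning the accumulated named list).
#' @export
recording_backend <- function(backend) {
  store <- new.env(parent = emptyenv())
  wrapped <- function_backend(backend$identifier, function(prompt, temperature = 0) {
    out <- backend_generate(backend, prompt, temperature)
    assign(prompt_digest(prompt), out, envir = store)
    out
  })
  list(
    backend = wrapped,
    transcript = function() {
      keys <- sort(ls(store))
      stats::setNames(lapply(keys, get, envir = store), keys)
    }
  )
}

# --- prompt templates ---------------------------------------------------

# One template per stage. Placeholders in {braces} are filled by
# render_prompt(); rendering fails if any placeholder is left unfilled.
# The two claim templates double as the deterministic claim grammar.
default_prompt_set <- function() {
  list(
    generation = paste0(
      "Task: propose the most prominent biological process name for a gene ",
      "set, then analyze the functions of its genes.\n",
      "Genes: {genes}\n",
      "Answer with the process name on the first line, then a blank line, ",
      "then the analytical narrative."
    ),
    claim_from_process = "{genes} is involved in {process_name}",
    claim_from_narrative = "{genes} is involved in {function_phrase}",
    verification_judgment = paste0(
      "Task: decide whether the claim is supported, partially supported or ",
      "refuted by the evidence from curated databases.\n",
      "Claim: {claim}\n",
      "Evidence:\n{evidence}\n",
      "Answer with the decision word first, then the rationale."
    ),
    modification = paste0(
      "Task: revise or retain the process name for the gene set using the ",
      "verification report.\n",
      "Genes: {genes}\n",
      "Current process name: {process_name}\n",
      "Current narrative:\n{narrative}\n",
      "Verification report:\n{evidence}\n",
      "Answer with the revised process name on the first line, then a blank ",
      "line, then the revised narrative."
    ),
    summarization = paste0(
      "Task: consolidate the verified findings into the final process name ",
      "and analytical narrative.\n",
      "Genes: {genes}\n",
      "Process name: {process_name}\n",
      "Narrative:\n{narrative}\n",
      "Narrative verification report (digest {report_digest}):\n{evidence}\n",
      "Answer with the final process name on the first line, then a blank ",
      "line, then the final narrative."
    )
  )
}

#' Stage prompt templates
#'
#' Returns the default template set, optionally overridden per stage. Each
#' template carries `{placeholder}` slots (gene list, process name,
#' narrative, evidence digest) that must all be filled before dispatch.
#'
#' @param overrides Named list of replacement templates.
#' @return Named list of six stage templates.
#' @export
stage_prompts <- function(overrides = list()) {
  prompts <- default_prompt_set()
  stopifnot(all(names(overrides) %in% names(prompts)))
  modifyList(prompts, overrides)
}

render_prompt <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template,
                     fixed = TRUE)
  }
  left <- regmatches(template, gregexpr("\\{[a-z_]+\\}", template))[[1]]
  if (length(left) > 0L) {
    stop("unfilled prompt placeholders: ", paste(left, collapse = ", "),
         call. = FALSE)
  }
  template
}
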