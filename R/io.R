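# Readers and writers for the community file formats: GMT gene-set files,
# the documented CSV dialect, background term lists, and pipeline reports.

#' Read gene sets from a GMT or CSV file
#'
#' GMT is tab-delimited: set id, description, then one gene per column; a
#' non-empty description becomes the set's ground-truth name. The CSV
#' dialect is: set id, ground-truth name (may be empty), then one gene per
#' remaining field. Rows with no genes are skipped with a warning and
#' counted in the summary message.
#'
#' @param path Input file.
#' @param format `"gmt"` or `"csv"`; default guessed from the extension.
#' @param source Dataset tag applied to every set (drives masking).
#' @param species Species label applied to every set.
#' @return List of [gene_set()] objects.
#' @export
read_gene_sets <- function(path, format = NULL, source = "custom",
                           species = "human") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- format %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "gmt")
  format <- match.arg(format, c("gmt", "csv"))
  sep <- if (format == "gmt") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  skipped <- 0L
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
    id <- if (length(fields) >= 1L) fields[1] else ""
    gt <- if (length(fields) >= 2L) fields[2] else ""
    genes <- if (length(fields) >= 3L) fields[-(1:2)] else character()
    genes <- genes[nzchar(genes)]
    if (!nzchar(id) || length(genes) == 0L) {
      warning("skipping row ", i, " of ", basename(path),
              ": no id or no genes", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    if (tolower(gt) %in% c("", "na", "none")) gt <- NULL
    sets[[length(sets) + 1L]] <- validate_gene_set(list(
      id = id, genes = genes, ground_truth = gt, source = source,
      species = species
    ))
  }
  message(sprintf("read %d gene sets from %s (%d rows skipped)",
                  length(sets), basename(path), skipped))
  sets
}

#' Write gene sets as GMT
#'
#' The description column carries the ground-truth name (or `NA` when the
#' set has none); [read_gene_sets()] round-trips the output.
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$ground_truth %||% "NA", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a background term list
#'
#' Plain text, one candidate term per line; blank lines ignored.
#'
#' @param path Input file.
#' @return A [background_set()].
#' @export
read_background <- function(path) {
  terms <- readLines(path, warn = FALSE)
  background_set(terms[nzchar(trimws(terms))])
}

#' Write a pipeline result (or a list of them) to JSON
#'
#' Stable key order; the file carries both verification reports and the
#' full call log, and re-serialization of a parsed file is byte-identical.
#'
#' @param result A [pipeline_result()] or a list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  objs <- if (inherits(result, "pipeline_result")) {
    to_json_obj(result)
  } else {
    lapply(result, to_json_obj)
  }
  ok <- tryCatch({
    writeLines(as.character(jsonlite::toJSON(
      objs, auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)),
      path)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write report to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read pipeline results back from JSON
#'
#' @param path A file written by [write_report()].
#' @return A [pipeline_result()] or a list of them, mirroring what was
#'   written.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$type)) from_json_obj(obj) else lapply(obj, from_json_obj)
}
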