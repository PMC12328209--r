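# Uniform adapter layer over the knowledge-source families used during
# self-verification: two enrichment services (a g:GOSt-style multi-database
# interface and an Enrichr-style per-database interface), a gene summary /
# literature service, and a gene-centric service with disease, domain, PPI
# and complex interfaces. A descriptor carries a fetch function, so live
# HTTP transports and local JSON fixtures are interchangeable behind the
# same surface; everything shipped here is fixture-backed and offline.

ENRICHMENT_SOURCES <- c("gprofiler", "enrichr")
GENE_CENTRIC_SOURCES <- c("eutils_gene", "eutils_pubmed", "agentapi")

GPROFILER_DATABASES <- c(
  "GO", "KEGG", "Reactome", "WikiPathways", "Transfac", "miRTarBase",
  "CORUM", "HP"
)
ENRICHR_DATABASES <- c(
  "KEGG_2021_Human", "Reactome_2022", "BioPlanet_2019", "MSigDB_Hallmark_2020"
)
AGENTAPI_INTERFACES <- c("disease", "domain", "ppi", "complex")

#' Describe a knowledge source
#'
#' @param source_id One of `"gprofiler"`, `"enrichr"`, `"eutils_gene"`,
#'   `"eutils_pubmed"`, `"agentapi"`.
#' @param databases Backend database names reachable through this source.
#' @param rank_limit Maximum number of retrieved terms per query: 5 for the
#'   enrichment sources, 10 for the gene-centric ones.
#' @param fetch `function(genes, database)` returning a data.frame with
#'   columns `term`, `description`, `score` (ascending p-value order for
#'   enrichment sources). The shipped fetchers read local JSON fixtures.
#' @param endpoint URL or fixture path, recorded for provenance.
#' @return A `source_descriptor` object.
#' @export
source_descriptor <- function(source_id, databases, rank_limit, fetch,
                              endpoint = "fixture") {
  source_id <- match.arg(source_id,
                         c(ENRICHMENT_SOURCES, GENE_CENTRIC_SOURCES))
  if (source_id %in% ENRICHMENT_SOURCES) stopifnot(rank_limit == 5L)
  if (source_id == "agentapi") stopifnot(rank_limit == 10L)
  structure(
    list(source_id = source_id, databases = as.character(databases),
         rank_limit = as.integer(rank_limit), fetch = fetch,
         endpoint = endpoint),
    class = "source_descriptor"
  )
}

canonical_gene_key <- function(genes) {
  paste(sort(tolower(trimws(genes))), collapse = ",")
}

fixture_fetch <- function(kb) {
  force(kb)
  function(genes, database) {
    table <- kb[[database]]
    if (is.null(table)) return(NULL)
    key <- canonical_gene_key(genes)
    records <- table[[key]]
    if (is.null(records)) return(NULL)
    data.frame(
      term = vapply(records, `[[`, character(1), "term"),
      description = vapply(records, function(r)
        r$description %||% NA_character_, character(1)),
      score = vapply(records, function(r) r$p %||% NA_real_, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
}

#' Build a fixture-backed source registry
#'
#' Creates the standard five descriptors (two enrichment, three
#' gene-centric), all answering queries from a local knowledge base: a
#' nested list `database -> canonical gene key -> ranked records`, where a
#' record has fields `term`, optional `description` and optional `p`. The
#' canonical key for a query is the sorted, case-folded, comma-joined gene
#' list (a single symbol for gene-centric databases).
#'
#' @param kb The knowledge base list, or the path of a JSON file holding
#'   one (as written by [write_world()]).
#' @param cache Memoize queries within the registry (default `TRUE`).
#' @return A `source_registry`.
#' @export
fixture_registry <- function(kb, cache = TRUE) {
  if (is.character(kb) && length(kb) == 1L) {
    kb <- jsonlite::fromJSON(kb, simplifyVector = FALSE)
  }
  fetch <- fixture_fetch(kb)
  source_registry(list(
    source_descriptor("gprofiler", GPROFILER_DATABASES, 5L, fetch),
    source_descriptor("enrichr", ENRICHR_DATABASES, 5L, fetch),
    source_descriptor("eutils_gene", "Gene", 10L, fetch),
    source_descriptor("eutils_pubmed", "PubMed", 10L, fetch),
    source_descriptor("agentapi", AGENTAPI_INTERFACES, 10L, fetch)
  ), cache = cache)
}

#' Assemble a source registry
#'
#' @param descriptors List of [source_descriptor()] objects.
#' @param cache Memoize identical queries (keyed by source, database and
#'   canonical gene list) so repeated claims trigger one transport call.
#' @return A `source_registry` holding the descriptors, the cache, and a
#'   transport-call counter.
#' @export
source_registry <- function(descriptors, cache = TRUE) {
  ids <- vapply(descriptors, `[[`, character(1), "source_id")
  stopifnot(!anyDuplicated(ids))
  structure(
    list(
      descriptors = stats::setNames(descriptors, ids),
      cache = if (cache) new.env(parent = emptyenv()) else NULL,
      transport_calls = new.env(parent = emptyenv())
    ),
    class = "source_registry"
  )
}

#' Number of transport calls a registry has made
#'
#' @param registry A `source_registry`.
#' @return Named integer vector of per-key transport-call counts.
#' @export
transport_call_counts <- function(registry) {
  keys <- sort(ls(registry$transport_calls))
  stats::setNames(
    vapply(keys, get, numeric(1), envir = registry$transport_calls),
    keys
  )
}

#' Memoize a retrieval call
#'
#' Returns the cached response when the same key was queried before in this
#' run; otherwise evaluates `fn()`, stores the result, and bumps the
#' transport counter. With a `NULL` cache every call goes to transport.
#'
#' @param key Cache key: built from `(source_id, database, ordered genes)`.
#' @param registry The owning `source_registry`.
#' @param fn Zero-argument function performing the actual retrieval.
#' @return `fn()`'s value (possibly cached).
#' @export
cached <- function(key, registry, fn) {
  if (!is.null(registry$cache) && exists(key, envir = registry$cache,
                                         inherits = FALSE)) {
    return(get(key, envir = registry$cache, inherits = FALSE))
  }
  n <- if (exists(key, envir = registry$transport_calls, inherits = FALSE)) {
    get(key, envir = registry$transport_calls, inherits = FALSE)
  } else 0
  assign(key, n + 1, envir = registry$transport_calls)
  out <- fn()
  if (!is.null(registry$cache)) assign(key, out, envir = registry$cache)
  if (!is.null(registry$run_log)) {
    registry$run_log$add(strsplit(key, "\x1f", fixed = TRUE)[[1]][1],
                         content_digest(key), content_digest(out))
  }
  out
}

registry_fetch <- function(registry, descriptor, genes, database) {
  key <- paste(descriptor$source_id, database, canonical_gene_key(genes),
               sep = "\x1f")
  cached(key, registry, function() descriptor$fetch(genes, database))
}

#' Query an enrichment source
#'
#' Pools the descriptor's databases (or queries the one named database),
#' keeps the backend's significance order, and truncates to the source's
#' rank limit.
#'
#' @param genes Non-empty character vector of gene symbols.
#' @param descriptor An enrichment [source_descriptor()].
#' @param registry The owning `source_registry` (for caching and call
#'   accounting).
#' @param database Restrict the query to one backend database; default
#'   pools all of the descriptor's databases.
#' @return An [evidence_item()].
#' @export
query_enrichment <- function(genes, descriptor, registry,
                             database = NULL) {
  stopifnot(length(genes) >= 1L,
            descriptor$source_id %in% ENRICHMENT_SOURCES)
  dbs <- database %||% descriptor$databases
  frames <- lapply(dbs, function(db) registry_fetch(registry, descriptor,
                                                    genes, db))
  terms <- do.call(rbind, c(list(as_term_frame(NULL)),
                            lapply(frames, as_term_frame)))
  if (nrow(terms) > 0L && !all(is.na(terms$score))) {
    terms <- terms[order(terms$score, na.last = TRUE), , drop = FALSE]
  }
  evidence_item(descriptor$source_id,
                if (length(dbs) == 1L) dbs else paste(dbs, collapse = "+"),
                genes, terms, descriptor$rank_limit)
}

#' Query a gene-centric source for one gene
#'
#' @param gene A single gene symbol.
#' @param descriptor A gene-centric [source_descriptor()].
#' @param registry The owning `source_registry`.
#' @param interface Which interface/database of the source to call (e.g.
#'   `"ppi"` or `"Gene"`); defaults to the descriptor's first database.
#' @return An [evidence_item()] with at most `rank_limit` records; a gene
#'   absent from the backend yields an empty item, not an error.
#' @export
query_gene_centric <- function(gene, descriptor, registry,
                               interface = NULL) {
  stopifnot(length(gene) == 1L,
            descriptor$source_id %in% GENE_CENTRIC_SOURCES)
  interface <- interface %||% descriptor$databases[1]
  stopifnot(interface %in% descriptor$databases)
  terms <- registry_fetch(registry, descriptor, gene, interface)
  evidence_item(descriptor$source_id, interface, gene, terms,
                descriptor$rank_limit)
}

#' Default masking rules
#'
#' No database may verify gene sets drawn from itself: the g:GOSt-style
#' enrichment source is removed entirely for sets from the GO dataset (it
#' can derive their ground truth directly from the GO database), and the
#' `MSigDB_Hallmark_2020` database is masked inside the Enrichr-style
#' source for sets from MSigDB. Sets tagged NeST or custom receive no mask.
#'
#' @return Named list: dataset tag -> list of `(source_id, database)` masks
#'   (`database = NULL` masks the whole source).
#' @export
default_mask_rules <- function() {
  list(
    GO = list(list(source_id = "gprofiler", database = NULL)),
    MSigDB = list(list(source_id = "enrichr",
                       database = "MSigDB_Hallmark_2020"))
  )
}

#' Mask-filter a registry for a gene set
#'
#' @param registry A `source_registry`.
#' @param gene_set The [gene_set()] about to be verified; its `source` tag
#'   selects the applicable rules.
#' @param rules Masking rules as from [default_mask_rules()].
#' @return A filtered `source_registry` sharing the original's cache.
#' @export
#' @examples
#' reg <- fixture_registry(list())
#' names(apply_mask(reg, gene_set("s", "TP53", source = "GO"))$descriptors)
apply_mask <- function(registry, gene_set, rules = default_mask_rules()) {
  masks <- rules[[gene_set$source]] %||% list()
  descriptors <- registry$descriptors
  for (m in masks) {
    d <- descriptors[[m$source_id]]
    if (is.null(d)) next
    if (is.null(m$database)) {
      descriptors[[m$source_id]] <- NULL
    } else {
      d$databases <- setdiff(d$databases, m$database)
      if (length(d$databases) == 0L) descriptors[[m$source_id]] <- NULL
      else descriptors[[m$source_id]] <- d
    }
  }
  out <- registry
  out$descriptors <- descriptors
  out
}

#' Significant enrichment terms for a gene set
#'
#' Runs over-representation analysis through an enrichment source and keeps
#' the terms significant at `alpha`, sorted by ascending p-value. These
#' serve as the ground truth of the enrichment-term exact-match test.
#'
#' @param gene_set A [gene_set()].
#' @param registry A `source_registry` with a `"gprofiler"`-style
#'   descriptor (or the source named by `source_id`).
#' @param alpha Significance threshold on the p-value (default 0.05).
#' @param source_id Which enrichment source performs the analysis.
#' @return A `significant_term_set`: list with `gene_set_id`, `terms`
#'   (data.frame `term`, `p_value`), and `alpha`.
#' @export
significant_terms <- function(gene_set, registry, alpha = 0.05,
                              source_id = "gprofiler") {
  descriptor <- registry$descriptors[[source_id]]
  if (is.null(descriptor)) {
    stop("registry has no source '", source_id, "'", call. = FALSE)
  }
  frames <- lapply(descriptor$databases, function(db)
    registry_fetch(registry, descriptor, gene_set$genes, db))
  terms <- do.call(rbind, c(list(as_term_frame(NULL)),
                            lapply(frames, as_term_frame)))
  keep <- !is.na(terms$score) & terms$score <= alpha
  terms <- terms[keep, , drop = FALSE]
  terms <- terms[order(terms$score), , drop = FALSE]
  structure(
    list(gene_set_id = gene_set$set_id,
         terms = data.frame(term = terms$term, p_value = terms$score,
                            stringsAsFactors = FALSE),
         alpha = alpha),
    class = "significant_term_set"
  )
}
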