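# OBO ingestion and hop-bounded ancestor queries. The graph is a typed
# parent-directed DAG over five relation types: is_a, part_of, regulates,
# negatively_regulates, positively_regulates. One hop is one edge of any of
# these types; ancestors are reached along child -> parent edges as encoded
# in OBO (is_a / relationship targets are parents).

ONTOLOGY_RELATIONS <- c(
  "is_a", "part_of", "regulates", "negatively_regulates",
  "positively_regulates"
)

#' Construct an ontology graph
#'
#' @param nodes Named character vector: term id -> term name.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (each relation one of the five supported types).
#' @param obsolete Character vector of obsolete term ids (excluded from
#'   traversal).
#' @return An `ontology_graph` object. Fails if edges reference unknown
#'   nodes or the graph has a cycle.
#' @export
ontology_graph <- function(nodes, edges, obsolete = character()) {
  stopifnot(is.character(nodes), !is.null(names(nodes)))
  if (nrow(edges) > 0L) {
    stopifnot(all(edges$relation %in% ONTOLOGY_RELATIONS))
    missing <- setdiff(unique(c(edges$child, edges$parent)), names(nodes))
    if (length(missing) > 0L) {
      stop("edges reference unknown terms: ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
    }
  }
  active <- setdiff(names(nodes), obsolete)
  act_edges <- edges[edges$child %in% active & edges$parent %in% active, ,
                     drop = FALSE]
  if (has_cycle(active, act_edges)) {
    stop("ontology contains a cycle over the five relation types",
         call. = FALSE)
  }
  parents <- split(
    seq_len(nrow(act_edges)),
    factor(act_edges$child, levels = active)
  )
  structure(
    list(nodes = nodes, edges = edges, obsolete = obsolete,
         active_edges = act_edges, parent_index = parents),
    class = "ontology_graph"
  )
}

has_cycle <- function(node_ids, edges) {
  if (nrow(edges) == 0L) return(FALSE)
  indeg <- table(factor(edges$parent, levels = node_ids))
  indeg <- stats::setNames(as.integer(indeg), node_ids)
  out_by_child <- split(edges$parent, factor(edges$child, levels = node_ids))
  queue <- node_ids[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (p in out_by_child[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  seen < length(node_ids)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d terms (%d obsolete), %d typed edges\n",
              length(x$nodes), length(x$obsolete), nrow(x$edges)))
  invisible(x)
}

#' Load an ontology from an OBO file
#'
#' Parses `[Term]` stanzas of the OBO 1.2/1.4 dialect: `id`, `name`,
#' `is_a`, `relationship` (the four non-is_a relation types) and
#' `is_obsolete`. Obsolete terms are kept in the node table but excluded
#' from traversal. Relations outside the five supported types are ignored.
#'
#' @param path Path to the OBO file.
#' @return An [ontology_graph()].
#' @export
load_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  names_ <- character()
  obsolete <- character()
  edges <- list()
  cur <- NULL
  in_term <- FALSE
  stanza_line <- 0L

  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      if (length(cur) > 0L) {
        stop("OBO [Term] stanza starting at line ", stanza_line,
             " has no id", call. = FALSE)
      }
      return()
    }
    ids <<- c(ids, cur$id)
    names_ <<- c(names_, cur$name %||% cur$id)
    if (isTRUE(cur$obsolete)) obsolete <<- c(obsolete, cur$id)
    for (e in cur$parents) {
      edges[[length(edges) + 1L]] <<- list(child = cur$id, parent = e$parent,
                                           relation = e$relation)
    }
  }

  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      flush()
      in_term <- identical(line, "[Term]")
      cur <- if (in_term) list() else NULL
      stanza_line <- i
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) == 0L) {
      stop("malformed OBO stanza line ", i, ": '", lines[i], "'",
           call. = FALSE)
    }
    key <- m[2]
    value <- trimws(m[3])
    if (key == "id") cur$id <- value
    else if (key == "name") cur$name <- value
    else if (key == "is_obsolete") cur$obsolete <- identical(value, "true")
    else if (key == "is_a") {
      cur$parents <- c(cur$parents, list(list(parent = value,
                                              relation = "is_a")))
    } else if (key == "relationship") {
      parts <- strsplit(value, "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop("malformed relationship at OBO line ", i, call. = FALSE)
      }
      if (parts[1] %in% ONTOLOGY_RELATIONS) {
        cur$parents <- c(cur$parents, list(list(parent = parts[2],
                                                relation = parts[1])))
      }
    }
  }
  flush()

  edge_df <- if (length(edges) == 0L) {
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      child = vapply(edges, `[[`, character(1), "child"),
      parent = vapply(edges, `[[`, character(1), "parent"),
      relation = vapply(edges, `[[`, character(1), "relation"),
      stringsAsFactors = FALSE
    )
  }
  ontology_graph(stats::setNames(names_, ids), edge_df, obsolete)
}

#' Write an ontology graph to an OBO file
#'
#' Minimal OBO 1.2 emitter used to serialize synthetic fixture ontologies;
#' [load_obo()] round-trips its output.
#'
#' @param graph An [ontology_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in names(graph$nodes)) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", graph$nodes[[id]]), con)
    if (id %in% graph$obsolete) writeLines("is_obsolete: true", con)
    sub <- graph$edges[graph$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      if (sub$relation[j] == "is_a") {
        writeLines(paste0("is_a: ", sub$parent[j]), con)
      } else {
        writeLines(paste0("relationship: ", sub$relation[j], " ",
                          sub$parent[j]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Ancestors of a term within a hop bound
#'
#' Breadth-first search along child -> parent edges of all five relation
#' types. Distances are minimal hop counts; the term itself is excluded;
#' obsolete terms are never visited.
#'
#' @param graph An [ontology_graph()].
#' @param term_id A term id present in the graph.
#' @param k Maximum number of hops (`Inf` for the full ancestor closure).
#' @return data.frame with columns `term_id` and `distance`, ordered by
#'   distance then id; zero rows for a root or `k = 0`.
#' @export
#' @examples
#' g <- ontology_graph(
#'   c(a = "leaf", b = "mid", c = "root"),
#'   data.frame(child = c("a", "b"), parent = c("b", "c"),
#'              relation = "is_a")
#' )
#' ancestors_within_hops(g, "a", 3)
ancestors_within_hops <- function(graph, term_id, k) {
  stopifnot(inherits(graph, "ontology_graph"), k >= 0)
  if (!term_id %in% names(graph$nodes)) {
    stop("unknown term: ", term_id, call. = FALSE)
  }
  dist <- c(stats::setNames(0L, term_id))
  frontier <- term_id
  hop <- 0L
  while (length(frontier) > 0L && hop < k) {
    hop <- hop + 1L
    nxt <- character()
    for (v in frontier) {
      idx <- graph$parent_index[[v]]
      if (is.null(idx)) next
      for (p in graph$active_edges$parent[idx]) {
        if (!p %in% names(dist)) {
          dist[[p]] <- hop
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist <- dist[names(dist) != term_id]
  out <- data.frame(term_id = names(dist), distance = as.integer(dist),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve a term name to its id
#'
#' Exact, case-insensitive match on term names; used to map ground-truth
#' names onto ontology ids. Ambiguous names resolve to the first id in node
#' order.
#'
#' @param graph An [ontology_graph()].
#' @param name Term name.
#' @return The term id, or `NA_character_` when unmatched.
#' @export
resolve_term <- function(graph, name) {
  hit <- which(tolower(graph$nodes) == tolower(trimws(name)))
  if (length(hit) == 0L) return(NA_character_)
  names(graph$nodes)[hit[1]]
}
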