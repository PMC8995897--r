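#' Parse a Gene Ontology graph from an OBO file
#'
#' Reads the `[Term]` stanzas of an OBO 1.2/1.4 flat file into a `go_graph`
#' object. Only `is_a` and `relationship: part_of` edges are retained (the
#' two relation types the Wang similarity measure assigns weights to); all
#' other relationship types are dropped and counted. Obsolete terms are
#' excluded entirely, parents included.
#'
#' @param path Path to an OBO file.
#' @return A `go_graph` object: a list with components
#'   \describe{
#'     \item{terms}{data.frame with columns `id`, `name`, `namespace`.}
#'     \item{parents}{named list; `parents[[id]]` is a data.frame with
#'       columns `parent` and `relation` (`"is_a"` or `"part_of"`).}
#'     \item{children}{the reverse adjacency, columns `child`, `relation`.}
#'     \item{roots}{named character vector, namespace -> root term id.}
#'     \item{n_dropped_relations}{count of non-is_a/part_of edges dropped.}
#'   }
#' @details The graph is validated on construction: edges may not cross
#'   namespaces, every non-root term must reach its namespace root, and the
#'   graph must be acyclic (checked with [igraph::is_dag()]).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  terms <- list()
  cur <- NULL
  cur_line <- 0L
  in_term <- FALSE
  n_dropped <- 0L

  flush_term <- function(cur) {
    if (is.null(cur$id)) stop("OBO [Term] stanza ending before line ", cur_line,
                              " has no id")
    cur
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      if (in_term && !is.null(cur)) terms[[length(terms) + 1L]] <- flush_term(cur)
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(id = NULL, name = NA_character_,
                               namespace = NA_character_, obsolete = FALSE,
                               parents = list()) else NULL
      next
    }
    if (!in_term) next
    cur_line <- i
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("Malformed OBO line ", i, ": ", ln)
    key <- m[[2]]; val <- m[[3]]
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    if (key == "id") {
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "namespace") {
      cur$namespace <- val
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(val, "true")
    } else if (key == "is_a") {
      cur$parents[[length(cur$parents) + 1L]] <- c(val, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(parts) < 2L) stop("Malformed relationship on OBO line ", i)
      if (parts[[1]] == "part_of") {
        cur$parents[[length(cur$parents) + 1L]] <- c(parts[[2]], "part_of")
      } else {
        n_dropped <- n_dropped + 1L
      }
    }
    # all other keys (def, synonym, xref, ...) ignored
  }
  if (in_term && !is.null(cur)) terms[[length(terms) + 1L]] <- flush_term(cur)

  terms <- Filter(function(t) !t$obsolete, terms)
  if (length(terms) == 0L) stop("OBO file contains no non-obsolete [Term] stanzas")

  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("Duplicate term ids in OBO: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- ids[!grepl("^GO:[0-9]{7}$", ids)]
  if (length(bad)) stop("Term ids not matching GO accession pattern: ",
                        paste(utils::head(bad, 5), collapse = ", "))

  term_df <- data.frame(
    id = ids,
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    stringsAsFactors = FALSE
  )
  known <- ids
  parents <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_along(terms)) {
    pl <- terms[[k]]$parents
    if (length(pl) == 0L) {
      parents[[ids[[k]]]] <- data.frame(parent = character(0),
                                        relation = character(0),
                                        stringsAsFactors = FALSE)
      next
    }
    pm <- do.call(rbind, pl)
    df <- data.frame(parent = pm[, 1], relation = pm[, 2],
                     stringsAsFactors = FALSE)
    # edges pointing at obsolete/unknown terms are dropped
    df <- df[df$parent %in% known, , drop = FALSE]
    df <- df[!duplicated(df), , drop = FALSE]
    parents[[ids[[k]]]] <- df
  }

  new_go_graph(term_df, parents, n_dropped_relations = n_dropped)
}

# Construct + validate a go_graph from its pieces.
new_go_graph <- function(term_df, parents, n_dropped_relations = 0L) {
  # namespace check on edges
  ns <- stats::setNames(term_df$namespace, term_df$id)
  for (id in term_df$id) {
    p <- parents[[id]]
    if (nrow(p) && any(ns[p$parent] != ns[[id]])) {
      stop("Edge crossing namespaces at term ", id)
    }
  }

  edges <- edge_table(parents)
  if (nrow(edges)) {
    ig <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                        directed = TRUE,
                                        vertices = term_df$id)
    if (!igraph::is_dag(ig)) stop("Ontology graph contains a cycle")
  }

  children <- stats::setNames(
    rep(list(data.frame(child = character(0), relation = character(0),
                        stringsAsFactors = FALSE)), nrow(term_df)),
    term_df$id)
  if (nrow(edges)) {
    sp <- split(edges[, c("child", "relation")], edges$parent)
    for (p in names(sp)) children[[p]] <- sp[[p]]
  }

  has_parent <- vapply(parents, nrow, integer(1)) > 0L
  roots_df <- term_df[!has_parent, , drop = FALSE]
  if (anyDuplicated(roots_df$namespace)) {
    stop("Multiple roots within one namespace: ",
         paste(roots_df$id[duplicated(roots_df$namespace) |
                           duplicated(roots_df$namespace, fromLast = TRUE)],
               collapse = ", "))
  }
  if (!all(term_df$namespace %in% roots_df$namespace)) {
    stop("Namespace without a root term")
  }
  roots <- stats::setNames(roots_df$id, roots_df$namespace)

  g <- structure(list(terms = term_df, parents = parents, children = children,
                      roots = roots,
                      n_dropped_relations = n_dropped_relations,
                      cache = new.env(parent = emptyenv())),
                 class = "go_graph")
  # reachability: every term must reach its namespace root
  anc <- go_ancestor_sets(g)
  for (id in term_df$id) {
    if (!(roots[[ns_of(g, id)]] %in% anc[[id]])) {
      stop("Term ", id, " does not reach its namespace root")
    }
  }
  g
}

#' @export
print.go_graph <- function(x, ...) {
  cat("go_graph:", nrow(x$terms), "terms,",
      sum(vapply(x$parents, nrow, integer(1))), "edges,",
      length(x$roots), "namespace(s)\n")
  cat("roots:", paste(names(x$roots), x$roots, sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

ns_of <- function(g, t) g$terms$namespace[match(t, g$terms$id)]

check_term <- function(g, t) {
  if (!t %in% g$terms$id) stop("Unknown term: ", t)
  invisible(t)
}

edge_table <- function(parents) {
  keep <- vapply(parents, nrow, integer(1)) > 0L
  if (!any(keep)) {
    return(data.frame(child = character(0), parent = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(parents)[keep], function(id) {
    p <- parents[[id]]
    data.frame(child = id, parent = p$parent, relation = p$relation,
               stringsAsFactors = FALSE)
  }))
}

#' Edge list of a GO graph
#'
#' @param g A `go_graph`.
#' @return data.frame with columns `child`, `parent`, `relation`, sorted by
#'   child then parent.
#' @export
go_edges <- function(g) {
  e <- edge_table(g$parents)
  e <- e[order(e$child, e$parent), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Ancestors of a term (transitive closure, self included)
#'
#' @param g A `go_graph`.
#' @param t A term id present in `g`.
#' @return Character vector of term ids: `t` and every term reachable from
#'   it via parent edges.
#' @export
go_ancestors <- function(g, t) {
  check_term(g, t)
  seen <- character(0)
  queue <- t
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, g$parents[[cur]]$parent)
  }
  seen
}

# All ancestor sets at once (memoised sweep in topological order).
go_ancestor_sets <- function(g) {
  ord <- topo_order(g)  # parents before children
  anc <- stats::setNames(vector("list", nrow(g$terms)), g$terms$id)
  for (id in ord) {
    ps <- g$parents[[id]]$parent
    anc[[id]] <- unique(c(id, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Descendants of a term (transitive closure, self included)
#'
#' @inheritParams go_ancestors
#' @return Character vector of term ids.
#' @export
go_descendants <- function(g, t) {
  check_term(g, t)
  seen <- character(0)
  queue <- t
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, g$children[[cur]]$child)
  }
  seen
}

# Topological order with parents before children.
topo_order <- function(g) {
  indeg <- vapply(g$parents, nrow, integer(1))
  ready <- names(indeg)[indeg == 0L]
  ord <- character(0)
  indeg_left <- indeg
  while (length(ready)) {
    cur <- ready[[1]]; ready <- ready[-1]
    ord <- c(ord, cur)
    for (ch in g$children[[cur]]$child) {
      indeg_left[[ch]] <- indeg_left[[ch]] - 1L
      if (indeg_left[[ch]] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(ord) != nrow(g$terms)) stop("Ontology graph contains a cycle")
  ord
}

#' Depth of a term: longest path from the namespace root
#'
#' Edge-based similarity measures on GO count path lengths; the convention
#' here (and in the Pekar measure) is the \emph{longest} path from the root,
#' with the root at depth 0.
#'
#' @inheritParams go_ancestors
#' @return Non-negative integer depth.
#' @export
go_depth <- function(g, t) {
  check_term(g, t)
  go_depths(g)[[t]]
}

# Longest-path depths for every term, one DP sweep.
go_depths <- function(g) {
  ord <- topo_order(g)
  d <- stats::setNames(integer(nrow(g$terms)), g$terms$id)
  for (id in ord) {
    ps <- g$parents[[id]]$parent
    d[[id]] <- if (length(ps)) max(d[ps]) + 1L else 0L
  }
  d
}

# Longest path length from ancestor `a` down to term `t`; NA if no path.
# Used by the Pekar measure.
longest_path_down <- function(g, a, t, anc = NULL) {
  if (a == t) return(0L)
  if (is.null(anc)) anc <- go_ancestors(g, t)
  if (!a %in% anc) return(NA_integer_)
  # DP restricted to the ancestor set of t
  best <- -Inf
  for (ch in g$children[[a]]$child) {
    if (!ch %in% anc) next
    sub <- longest_path_down(g, ch, t, anc)
    if (!is.na(sub)) best <- max(best, sub + 1L)
  }
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}
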