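#' Annotation-frequency information content
#'
#' Computes the standard Resnik-style information content for every GO term
#' with at least one annotation in its descendant closure:
#' `ic[t] = -ln( freq[t] / freq[root] )`, where `freq[t]` counts the
#' distinct (protein, term') annotation pairs with term' a descendant of
#' `t` or `t` itself, and the root is the namespace root of `t`. Annotation
#' weights do not enter the frequency: a duplicated annotation is still one
#' (protein, term) pair.
#'
#' Terms with zero annotation frequency have no defined IC and are omitted
#' from the table; similarity measures that need their IC raise an error
#' rather than silently returning 0, so corpus/ontology mismatches surface.
#'
#' @param g A `go_graph`.
#' @param annotations A `pgaa` object (see [build_pgaa()]).
#' @return An `ic_table` object: list with `ic` (named numeric, nats) and
#'   `term_freq` (named integer).
#' @export
compute_ic <- function(g, annotations) {
  stopifnot(inherits(g, "go_graph"), inherits(annotations, "pgaa"))
  ax <- annotations$axioms
  if (length(ax) == 0L) stop("Annotation set is empty; IC undefined")

  # distinct (protein, term) pairs -> direct count per term
  direct <- integer(0)
  for (p in names(ax)) {
    terms <- unique(ax[[p]]$term_id)
    terms <- terms[terms %in% g$terms$id]
    for (t in terms) direct[[t]] <- (if (t %in% names(direct)) direct[[t]] else 0L) + 1L
  }
  if (length(direct) == 0L) {
    stop("No annotated term appears in the ontology; IC undefined")
  }

  # propagate counts up: freq[t] = sum of direct counts over descendants-or-self
  ord <- rev(topo_order(g))  # children before parents
  freq <- stats::setNames(numeric(nrow(g$terms)), g$terms$id)
  # accumulate by summing each term's *direct* count into all its ancestors;
  # done via the ancestor closure to avoid double counting along diamonds
  anc <- go_ancestor_sets(g)
  for (t in names(direct)) {
    for (a in anc[[t]]) freq[[a]] <- freq[[a]] + direct[[t]]
  }

  root_freq <- stats::setNames(freq[g$roots], names(g$roots))
  ns <- stats::setNames(g$terms$namespace, g$terms$id)
  keep <- names(freq)[freq > 0]
  ic <- vapply(keep, function(t) {
    -log(freq[[t]] / root_freq[[ns[[t]]]])
  }, numeric(1))
  # guard against -0
  ic[ic == 0] <- 0

  structure(list(ic = ic, term_freq = stats::setNames(as.integer(freq[keep]), keep)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table:", length(x$ic), "terms with defined IC; max IC =",
      format(max(x$ic), digits = 4), "nats\n")
  invisible(x)
}

ic_of <- function(ic, t) {
  if (!t %in% names(ic$ic)) {
    stop("Term ", t, " has no defined IC (zero annotation frequency)")
  }
  ic$ic[[t]]
}
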