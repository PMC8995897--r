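# GO-structure semantic-similarity baselines.
#
# Term-level measures: Resnik and Lin (node-based, via the most informative
# common ancestor), Pekar (edge-based, longest paths) and Wang (hybrid,
# relation-weighted S-values). Protein-level aggregation: AVG, Max and
# best-match average (BMA).

# Precomputed graph structures shared across many similarity calls;
# memoised on the graph's cache environment (graphs are immutable).
baseline_context <- function(g) {
  if (!is.null(g$cache) && !is.null(g$cache$ctx)) return(g$cache$ctx)
  ctx <- list(anc = go_ancestor_sets(g),
              depths = go_depths(g),
              ns = stats::setNames(g$terms$namespace, g$terms$id))
  if (!is.null(g$cache)) g$cache$ctx <- ctx
  ctx
}

check_same_namespace <- function(pre, t1, t2) {
  if (pre$ns[[t1]] != pre$ns[[t2]]) {
    stop("Terms ", t1, " and ", t2, " are in different namespaces; ",
         "similarity undefined")
  }
}

#' Resnik term similarity: IC of the most informative common ancestor
#'
#' @param g A `go_graph`.
#' @param ic An `ic_table` from [compute_ic()].
#' @param t1,t2 Term ids in the same namespace, both with defined IC.
#' @return Non-negative MICA information content (nats); 0 when the root is
#'   the only shared ancestor.
#' @export
sim_resnik <- function(g, ic, t1, t2) {
  check_term(g, t1); check_term(g, t2)
  pre <- baseline_context(g)
  sim_term(g, ic, t1, t2, measure = "resnik", pre = pre)
}

#' Lin term similarity
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))`, in `[0, 1]`.
#'
#' @inheritParams sim_resnik
#' @export
sim_lin <- function(g, ic, t1, t2) {
  check_term(g, t1); check_term(g, t2)
  pre <- baseline_context(g)
  sim_term(g, ic, t1, t2, measure = "lin", pre = pre)
}

#' Pekar edge-based term similarity
#'
#' For a common ancestor c of t1 and t2, the score
#' `d(root, c) / (d(root, c) + l(c, t1) + l(c, t2))` relates the depth of c
#' (longest path from the root) to the longest paths from c down to each
#' term; the measure takes the common ancestor maximizing this ratio.
#' Value in `[0, 1]`; 1 for identical non-root terms, 0 when the root is
#' the only common ancestor.
#'
#' @inheritParams sim_resnik
#' @export
sim_pekar <- function(g, t1, t2) {
  check_term(g, t1); check_term(g, t2)
  pre <- baseline_context(g)
  sim_term(g, NULL, t1, t2, measure = "pekar", pre = pre)
}

#' Wang relation-weighted term similarity
#'
#' Wang's semantic-value method: the S-value of term t at itself is 1 and
#' decays multiplicatively along parent edges (`is_a` weight 0.8, `part_of`
#' weight 0.6, max over paths); the similarity of t1, t2 sums the S-values
#' of their common ancestors from both sides, normalized by the two total
#' semantic values. Value in (0, 1] within one namespace.
#'
#' @inheritParams sim_resnik
#' @param w_is_a,w_part_of Edge contribution factors.
#' @export
sim_wang <- function(g, t1, t2, w_is_a = 0.8, w_part_of = 0.6) {
  check_term(g, t1); check_term(g, t2)
  pre <- baseline_context(g)
  sim_term(g, NULL, t1, t2, measure = "wang", pre = pre,
           w_is_a = w_is_a, w_part_of = w_part_of)
}

# Internal dispatcher working from a precomputed context. cross_na = TRUE
# turns the cross-namespace error into NA (used by the aggregator, which
# skips such pairs and renormalizes).
sim_term <- function(g, ic, t1, t2, measure, pre, cross_na = FALSE,
                     w_is_a = 0.8, w_part_of = 0.6) {
  if (pre$ns[[t1]] != pre$ns[[t2]]) {
    if (cross_na) return(NA_real_)
    check_same_namespace(pre, t1, t2)
  }
  switch(measure,
    resnik = {
      ic_of(ic, t1); ic_of(ic, t2)  # raise on undefined IC
      common <- intersect(pre$anc[[t1]], pre$anc[[t2]])
      max(vapply(common, function(a) ic_of(ic, a), numeric(1)))
    },
    lin = {
      ic1 <- ic_of(ic, t1); ic2 <- ic_of(ic, t2)
      if (ic1 + ic2 <= 0) {
        stop("Lin similarity undefined: both terms have zero IC")
      }
      common <- intersect(pre$anc[[t1]], pre$anc[[t2]])
      mica <- max(vapply(common, function(a) ic_of(ic, a), numeric(1)))
      2 * mica / (ic1 + ic2)
    },
    pekar = {
      common <- intersect(pre$anc[[t1]], pre$anc[[t2]])
      l1 <- longest_paths_to(g, t1, pre)
      l2 <- longest_paths_to(g, t2, pre)
      ratios <- vapply(common, function(a) {
        d <- pre$depths[[a]]
        denom <- d + l1[[a]] + l2[[a]]
        if (denom == 0) 0 else d / denom
      }, numeric(1))
      max(ratios)
    },
    wang = {
      s1 <- wang_svalues(g, t1, pre, w_is_a, w_part_of)
      s2 <- wang_svalues(g, t2, pre, w_is_a, w_part_of)
      common <- intersect(names(s1), names(s2))
      (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
    },
    stop("Unknown measure: ", measure)
  )
}

# Longest path length from each ancestor of t down to t (named vector over
# ancestors-or-self of t), by DP in decreasing-depth order.
longest_paths_to <- function(g, t, pre) {
  A <- pre$anc[[t]]
  A <- A[order(pre$depths[A], decreasing = TRUE)]
  l <- stats::setNames(rep(-Inf, length(A)), A)
  l[[t]] <- 0
  for (a in A) {
    if (a == t) next
    kids <- g$children[[a]]$child
    kids <- kids[kids %in% A]
    if (length(kids)) l[[a]] <- max(l[kids] + 1)
  }
  l
}

# Wang S-values of term t over its ancestor closure.
wang_svalues <- function(g, t, pre, w_is_a = 0.8, w_part_of = 0.6) {
  w <- c(is_a = w_is_a, part_of = w_part_of)
  A <- pre$anc[[t]]
  A <- A[order(pre$depths[A], decreasing = TRUE)]
  s <- stats::setNames(numeric(length(A)), A)
  s[[t]] <- 1
  for (a in A) {
    if (a == t) next
    ch <- g$children[[a]]
    ch <- ch[ch$child %in% A, , drop = FALSE]
    s[[a]] <- max(w[ch$relation] * s[ch$child])
  }
  s
}

#' Aggregate term-level similarities to a protein-level score
#'
#' Given the two proteins' term sets, computes the all-pairs similarity
#' matrix with `simfn` and reduces it: `avg` is the grand mean, `max` the
#' maximum, `bma` the best-match average (mean of row maxima and mean of
#' column maxima, averaged — each term is matched to its best counterpart).
#' `bma_literal` is the uncorrected textbook-variant average
#' `(mean over t1 of all pairs + mean over t2 of all pairs) / 2`, which
#' collapses to a reweighted AVG; it is provided for fidelity comparisons
#' only, `bma` is the canonical aggregator.
#'
#' `NA` similarities (cross-namespace term pairs) are skipped and the
#' remaining entries renormalized; an all-`NA` matrix is an error.
#'
#' @param simfn Function of two term ids returning a similarity or `NA`.
#' @param T1,T2 Non-empty character vectors of term ids.
#' @param mode One of `"avg"`, `"max"`, `"bma"`, `"bma_literal"`.
#' @return A single numeric score.
#' @export
aggregate_similarity <- function(simfn, T1, T2,
                                 mode = c("bma", "avg", "max", "bma_literal")) {
  mode <- match.arg(mode)
  if (length(T1) == 0L || length(T2) == 0L) {
    stop("Cannot aggregate over an empty term set")
  }
  M <- matrix(NA_real_, nrow = length(T1), ncol = length(T2))
  for (i in seq_along(T1)) {
    for (j in seq_along(T2)) {
      M[i, j] <- simfn(T1[[i]], T2[[j]])
    }
  }
  if (all(is.na(M))) stop("All term pairs are cross-namespace; no score")
  switch(mode,
    avg = mean(M, na.rm = TRUE),
    max = max(M, na.rm = TRUE),
    bma = {
      rmax <- apply(M, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
      cmax <- apply(M, 2, function(cc) if (all(is.na(cc))) NA_real_ else max(cc, na.rm = TRUE))
      (mean(rmax, na.rm = TRUE) + mean(cmax, na.rm = TRUE)) / 2
    },
    bma_literal = {
      # the uncorrected variant: half of (all-pair sum / |T1| + all-pair
      # sum / |T2|), i.e. AVG rescaled by (|T1|+|T2|)/2
      S <- sum(M, na.rm = TRUE)
      (S / length(T1) + S / length(T2)) / 2
    }
  )
}

#' Score protein pairs with a structural similarity baseline
#'
#' For each pair, aggregates the chosen term-level measure over the two
#' proteins' annotated term sets (axiom weights are ignored — the
#' structural baselines are unweighted). Term-pair similarities are
#' memoised across pairs.
#'
#' @param pairs data.frame with `protein_a`, `protein_b`.
#' @param pgaa A `pgaa` object covering every protein in `pairs`.
#' @param g A `go_graph`.
#' @param ic An `ic_table` (required for `resnik` and `lin`).
#' @param measure One of `"resnik"`, `"lin"`, `"pekar"`, `"wang"`.
#' @param mode Aggregation mode, see [aggregate_similarity()].
#' @return `pairs` with a `score` column appended.
#' @export
score_pairs <- function(pairs, pgaa, g, ic = NULL,
                        measure = c("resnik", "lin", "pekar", "wang"),
                        mode = c("bma", "avg", "max", "bma_literal")) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  stopifnot(inherits(pgaa, "pgaa"), inherits(g, "go_graph"))
  if (measure %in% c("resnik", "lin") && !inherits(ic, "ic_table")) {
    stop("Measure ", measure, " needs an ic_table")
  }
  pre <- baseline_context(g)
  cache <- new.env(parent = emptyenv())
  simfn <- function(t1, t2) {
    key <- if (t1 <= t2) paste(t1, t2) else paste(t2, t1)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- sim_term(g, ic, t1, t2, measure = measure, pre = pre, cross_na = TRUE)
    cache[[key]] <- v
    v
  }
  term_set <- function(p) {
    ax <- pgaa$axioms[[p]]
    if (is.null(ax) || nrow(ax) == 0L) {
      stop("Protein ", p, " has no annotations; cannot score")
    }
    unique(ax$term_id)
  }
  out <- pairs
  out$score <- vapply(seq_len(nrow(pairs)), function(i) {
    aggregate_similarity(simfn, term_set(pairs$protein_a[[i]]),
                         term_set(pairs$protein_b[[i]]), mode = mode)
  }, numeric(1))
  out
}
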