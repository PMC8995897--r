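# Independent brute-force oracles. These work from the raw edge list only
# and never share code paths with the package implementations they check.
# All take an optional precomputed edge table `e` so sweeps over many term
# pairs on one graph do not re-derive it.

oracle_edges <- function(g) go_edges(g)[, c("child", "parent", "relation")]

# transitive closure by iterated expansion over the edge list
oracle_ancestors <- function(g, t, e = oracle_edges(g)) {
  anc <- t
  repeat {
    new <- unique(c(anc, e$parent[e$child %in% anc]))
    if (length(new) == length(anc)) return(sort(anc))
    anc <- new
  }
}

# all directed paths from `from` down to `to` (following parent->child),
# returned as a vector of path lengths; empty if unreachable
oracle_path_lengths <- function(g, from, to, e = oracle_edges(g)) {
  out <- integer(0)
  walk <- function(node, len) {
    if (node == to) {
      out[[length(out) + 1L]] <<- len
      return(invisible())
    }
    for (ch in e$child[e$parent == node]) walk(ch, len + 1L)
  }
  walk(from, 0L)
  out
}

oracle_depth <- function(g, t, e = oracle_edges(g)) {
  root <- g$roots[[1]]
  if (t == root) return(0L)
  max(oracle_path_lengths(g, root, t, e))
}

oracle_resnik <- function(g, ic, t1, t2, e = oracle_edges(g)) {
  common <- intersect(oracle_ancestors(g, t1, e), oracle_ancestors(g, t2, e))
  max(ic$ic[common])
}

oracle_lin <- function(g, ic, t1, t2, e = oracle_edges(g)) {
  2 * oracle_resnik(g, ic, t1, t2, e) / (ic$ic[[t1]] + ic$ic[[t2]])
}

oracle_pekar <- function(g, t1, t2, e = oracle_edges(g)) {
  common <- intersect(oracle_ancestors(g, t1, e), oracle_ancestors(g, t2, e))
  best <- 0
  for (cc in common) {
    d <- oracle_depth(g, cc, e)
    l1 <- if (cc == t1) 0L else max(oracle_path_lengths(g, cc, t1, e))
    l2 <- if (cc == t2) 0L else max(oracle_path_lengths(g, cc, t2, e))
    denom <- d + l1 + l2
    r <- if (denom == 0) 0 else d / denom
    best <- max(best, r)
  }
  best
}

# Wang S-value by direct recursion over the edge list
oracle_wang_s <- function(g, t, w = c(is_a = 0.8, part_of = 0.6),
                          e = oracle_edges(g)) {
  anc <- oracle_ancestors(g, t, e)
  svalue <- function(a) {
    if (a == t) return(1)
    rows <- e[e$parent == a & e$child %in% anc, , drop = FALSE]
    max(vapply(seq_len(nrow(rows)), function(i) {
      w[[rows$relation[[i]]]] * svalue(rows$child[[i]])
    }, numeric(1)))
  }
  stats::setNames(vapply(anc, svalue, numeric(1)), anc)
}

oracle_wang <- function(g, t1, t2, w = c(is_a = 0.8, part_of = 0.6),
                        e = oracle_edges(g)) {
  s1 <- oracle_wang_s(g, t1, w, e)
  s2 <- oracle_wang_s(g, t2, w, e)
  common <- intersect(names(s1), names(s2))
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

oracle_aggregate <- function(M, mode) {
  switch(mode,
    avg = mean(M),
    max = max(M),
    bma = (mean(apply(M, 1, max)) + mean(apply(M, 2, max))) / 2)
}

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(labels, scores) {
  sp <- scores[labels == 1L]
  sn <- scores[labels == 0L]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# PR area recomputed threshold by threshold (step interpolation)
oracle_aupr <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1L)
  prev_r <- 0
  area <- 0
  for (s in th) {
    pred <- scores >= s
    tp <- sum(pred & labels == 1L)
    r <- tp / n_pos
    p <- tp / sum(pred)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}
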