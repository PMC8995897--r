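#' Axiom sentence corpus from a GO graph
#'
#' Turns every parent edge of the ontology into one three-token axiom
#' sentence `child relation parent` (relation is `is_a` or `part_of`).
#' A skip-gram model trained on this corpus learns term vectors that encode
#' the graph neighbourhood of each term: terms sharing parents or lying on
#' the same path end up with similar vectors.
#'
#' @param g A `go_graph`.
#' @return List of character vectors, one per edge, in deterministic order
#'   (sorted by child then parent).
#' @export
axiom_corpus <- function(g) {
  stopifnot(inherits(g, "go_graph"))
  e <- go_edges(g)
  if (nrow(e) == 0L) return(list())
  lapply(seq_len(nrow(e)), function(i) c(e$child[[i]], e$relation[[i]], e$parent[[i]]))
}

#' Train GO-term vectors with skip-gram negative sampling
#'
#' A compact word2vec (skip-gram, negative sampling) trainer over axiom
#' sentences. Runs single-threaded and fully seeded, so identical corpus +
#' seed gives bitwise-identical vectors. Minimum token count is 1 (axiom
#' corpora are tiny; every token matters) and only GO accessions are
#' exported — relation keywords participate in training as context but are
#' not term vectors.
#'
#' @param corpus List of token vectors from [axiom_corpus()].
#' @param dim Embedding dimensionality (default 200).
#' @param window Context window half-width (default 5; axiom sentences have
#'   3 tokens, so the default makes every in-sentence pair a training pair).
#' @param epochs Passes over the corpus (default 100; small corpora need
#'   many passes).
#' @param negative Negative samples per positive pair (default 5).
#' @param lr Initial learning rate, decayed linearly to `lr/100`.
#' @param seed RNG seed.
#' @return A `term_vectors` object: list with `dim`, `seed` and `vectors`
#'   (matrix, one row per GO term, rownames = term ids).
#' @export
train_term_vectors <- function(corpus, dim = 200L, window = 5L, epochs = 100L,
                               negative = 5L, lr = 0.025, seed = 1L) {
  if (length(corpus) == 0L) stop("Axiom corpus is empty; nothing to train on")
  stopifnot(dim >= 2L, window >= 1L, epochs >= 1L)

  tokens <- unlist(corpus, use.names = FALSE)
  vocab <- sort(unique(tokens))
  vidx <- stats::setNames(seq_along(vocab), vocab)
  counts <- table(factor(tokens, levels = vocab))
  sent_idx <- lapply(corpus, function(s) unname(vidx[s]))

  # unigram^0.75 negative-sampling distribution
  neg_prob <- as.numeric(counts)^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  V <- length(vocab)
  n_pairs_per_epoch <- sum(vapply(sent_idx, function(s) {
    sum(vapply(seq_along(s), function(i) {
      length(max(1L, i - window):min(length(s), i + window)) - 1L
    }, integer(1)))
  }, integer(1)))
  total_pairs <- n_pairs_per_epoch * epochs

  with_seed(seed, {
    W_in <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), nrow = V)
    W_out <- matrix(0, nrow = V, ncol = dim)
    pair_no <- 0
    for (ep in seq_len(epochs)) {
      for (s in sent_idx) {
        L <- length(s)
        for (i in seq_len(L)) {
          ctx <- s[max(1L, i - window):min(L, i + window)]
          ctx <- ctx[-(i - max(1L, i - window) + 1L)]
          centre <- s[[i]]
          for (o in ctx) {
            pair_no <- pair_no + 1
            alpha <- max(lr * (1 - pair_no / total_pairs), lr / 100)
            negs <- sample.int(V, negative, replace = TRUE, prob = neg_prob)
            targets <- c(o, negs[negs != o])
            labels <- c(1, numeric(length(targets) - 1L))
            z <- W_in[centre, ]
            e <- numeric(dim)
            for (k in seq_along(targets)) {
              t_k <- targets[[k]]
              f <- 1 / (1 + exp(-sum(z * W_out[t_k, ])))
              gphi <- (labels[[k]] - f) * alpha
              e <- e + gphi * W_out[t_k, ]
              W_out[t_k, ] <- W_out[t_k, ] + gphi * z
            }
            W_in[centre, ] <- W_in[centre, ] + e
          }
        }
      }
    }
  })

  keep <- grepl("^GO:", vocab)
  vecs <- W_in[keep, , drop = FALSE]
  rownames(vecs) <- vocab[keep]
  structure(list(dim = as.integer(dim), seed = as.integer(seed), vectors = vecs),
            class = "term_vectors")
}

#' @export
print.term_vectors <- function(x, ...) {
  cat("term_vectors:", nrow(x$vectors), "terms x", x$dim,
      "dims (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Look up a term vector, zero vector for out-of-vocabulary terms
#'
#' @param vectors A `term_vectors` object.
#' @param term_id GO accession.
#' @param warn Warn on out-of-vocabulary lookup?
#' @return Numeric vector of length `vectors$dim`.
#' @export
term_vector <- function(vectors, term_id, warn = TRUE) {
  stopifnot(inherits(vectors, "term_vectors"))
  if (term_id %in% rownames(vectors$vectors)) {
    vectors$vectors[term_id, ]
  } else {
    if (warn) warning("Term ", term_id,
                      " has no trained vector; using zero vector")
    numeric(vectors$dim)
  }
}

#' Write / read term vectors in the word2vec text format
#'
#' Header line `<count> <dim>`, then one `term v1 ... vdim` line per term.
#'
#' @param x A `term_vectors` object.
#' @param path File path.
#' @export
write_term_vectors <- function(x, path) {
  stopifnot(inherits(x, "term_vectors"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(x$vectors), x$dim), con)
  apply_rows <- vapply(seq_len(nrow(x$vectors)), function(i) {
    paste(rownames(x$vectors)[[i]],
          paste(sprintf("%.17g", x$vectors[i, ]), collapse = " "))
  }, character(1))
  writeLines(apply_rows, con)
  invisible(path)
}

#' @rdname write_term_vectors
#' @param seed Seed recorded on the read object (provenance only).
#' @export
read_term_vectors <- function(path, seed = NA_integer_) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[[1]], " ", fixed = TRUE)[[1]])
  n <- hdr[[1]]; d <- hdr[[2]]
  if (n == 0L) {
    vecs <- matrix(numeric(0), nrow = 0, ncol = d)
  } else {
    parts <- strsplit(trimws(lines[1L + seq_len(n)]), " +")
    ids <- vapply(parts, `[[`, character(1), 1L)
    vecs <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
    rownames(vecs) <- ids
  }
  structure(list(dim = d, seed = as.integer(seed), vectors = vecs),
            class = "term_vectors")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
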