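#' Read / write PPI pair lists
#'
#' Pairs are tab-separated `protein_a <tab> protein_b [<tab> label]`, label
#' 0/1, no header.
#'
#' @param path File path.
#' @return data.frame with columns `protein_a`, `protein_b` and, when
#'   present in the file, integer `label`.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (!all(nc %in% c(2L, 3L)) || length(unique(nc)) != 1L) {
    stop("Pair file must have uniformly 2 or 3 tab-separated columns")
  }
  df <- data.frame(protein_a = vapply(parts, `[[`, character(1), 1L),
                   protein_b = vapply(parts, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  if (nc[[1]] == 3L) df$label <- as.integer(vapply(parts, `[[`, character(1), 3L))
  df
}

#' @rdname read_pairs
#' @param pairs data.frame of pairs.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("protein_a", "protein_b", intersect("label", names(pairs)))
  lines <- do.call(paste, c(unname(pairs[cols]), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column protein ID map
#'
#' Maps source database identifiers to the accessions used in the GAF.
#' Format: `source_id <tab> accession`, no header.
#'
#' @param path File path.
#' @return Named character vector, `source_id -> accession`.
#' @export
read_id_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(parts) == 2L))
  stats::setNames(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Screen PPI pairs for mappable, annotated endpoints
#'
#' Keeps pairs whose both endpoints (a) map through `id_map` and (b) have
#' at least one annotation axiom after evidence filtering, so both proteins
#' can be represented as GO-term sentences. Mapped accessions replace the
#' original identifiers in the output. Order is preserved.
#'
#' @param pairs data.frame from [read_pairs()].
#' @param pgaa A `pgaa` object.
#' @param id_map Named character vector (source id -> accession), or `NULL`
#'   when pair identifiers already are GAF accessions.
#' @return The screened pairs data.frame, identifiers mapped.
#' @export
screen_pairs <- function(pairs, pgaa, id_map = NULL) {
  stopifnot(inherits(pgaa, "pgaa"))
  a <- pairs$protein_a
  b <- pairs$protein_b
  if (!is.null(id_map)) {
    a <- unname(id_map[a])
    b <- unname(id_map[b])
  }
  annotated <- names(pgaa$axioms)
  keep <- !is.na(a) & !is.na(b) & a %in% annotated & b %in% annotated
  out <- pairs[keep, , drop = FALSE]
  out$protein_a <- a[keep]
  out$protein_b <- b[keep]
  rownames(out) <- NULL
  out
}

#' Balance positive and negative pairs
#'
#' Downsamples the majority class (without replacement, seeded) so both
#' classes have `n = min(class counts)` pairs. When the input has no
#' negatives at all (positive-only interaction databases), negatives are
#' generated by seeded random pairing of the annotated proteins, avoiding
#' any pair (in either orientation) present in the positive set and any
#' self-pair.
#'
#' @param pairs data.frame with `protein_a`, `protein_b`, `label`.
#' @param seed RNG seed.
#' @param proteins Optional character vector of candidate proteins for
#'   negative generation; defaults to the proteins of the positive pairs.
#' @return Balanced pairs data.frame (positives first, then negatives).
#' @export
balance_pairs <- function(pairs, seed = 1L, proteins = NULL) {
  stopifnot(all(c("protein_a", "protein_b", "label") %in% names(pairs)))
  pos <- pairs[pairs$label == 1L, , drop = FALSE]
  neg <- pairs[pairs$label == 0L, , drop = FALSE]
  if (nrow(pos) == 0L) stop("No positive pairs; cannot balance")

  if (nrow(neg) == 0L) {
    cand <- proteins %||% sort(unique(c(pos$protein_a, pos$protein_b)))
    if (length(cand) < 2L) stop("Not enough proteins to generate negatives")
    pos_keys <- c(paste(pos$protein_a, pos$protein_b, sep = "\r"),
                  paste(pos$protein_b, pos$protein_a, sep = "\r"))
    neg <- with_seed(seed, {
      out_a <- character(0); out_b <- character(0)
      seen <- character(0)
      guard <- 0L
      while (length(out_a) < nrow(pos)) {
        guard <- guard + 1L
        if (guard > 1000L * nrow(pos)) {
          stop("Unable to generate enough non-positive pairs")
        }
        ij <- sample(cand, 2L)
        key <- paste(ij[[1]], ij[[2]], sep = "\r")
        rkey <- paste(ij[[2]], ij[[1]], sep = "\r")
        if (key %in% pos_keys || key %in% seen || rkey %in% seen) next
        seen <- c(seen, key)
        out_a <- c(out_a, ij[[1]]); out_b <- c(out_b, ij[[2]])
      }
      data.frame(protein_a = out_a, protein_b = out_b, label = 0L,
                 stringsAsFactors = FALSE)
    })
  }

  n <- min(nrow(pos), nrow(neg))
  with_seed(seed, {
    if (nrow(pos) > n) pos <- pos[sort(sample.int(nrow(pos), n)), , drop = FALSE]
    if (nrow(neg) > n) neg <- neg[sort(sample.int(nrow(neg), n)), , drop = FALSE]
  })
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Build a protein sentence
#'
#' A protein is a sentence whose words are its annotated GO terms; the
#' sentence matrix stacks the corresponding term vectors. In weighted mode
#' each term is repeated `min(weight, weight_cap)` times, so the sentence
#' encoder sees reliability as token frequency; in unweighted mode each
#' term appears once. Token order is canonical (sorted by term id) —
#' GO-term words carry no meaningful order, and a fixed order keeps runs
#' reproducible.
#'
#' @param protein Protein accession with at least one axiom in `pgaa`.
#' @param pgaa A `pgaa` object.
#' @param vectors A `term_vectors` object.
#' @param weighted Repeat terms by their axiom weight?
#' @param weight_cap Maximum repetitions per term (bounds sentence length).
#' @return A `protein_sentence`: list with `protein_id`, `term_ids`
#'   (character, with repetitions) and `matrix` (length(term_ids) x dim).
#' @export
build_sentence <- function(protein, pgaa, vectors, weighted = pgaa$weighted,
                           weight_cap = 10L) {
  stopifnot(inherits(pgaa, "pgaa"), inherits(vectors, "term_vectors"))
  ax <- pgaa$axioms[[protein]]
  if (is.null(ax) || nrow(ax) == 0L) {
    stop("Protein ", protein, " has no annotation axioms; cannot build sentence")
  }
  ax <- ax[order(ax$term_id), , drop = FALSE]
  reps <- if (weighted) pmin(ax$weight, weight_cap) else rep(1L, nrow(ax))
  term_ids <- rep(ax$term_id, reps)
  mat <- do.call(rbind, lapply(term_ids, function(t) term_vector(vectors, t)))
  structure(list(protein_id = protein, term_ids = term_ids, matrix = mat),
            class = "protein_sentence")
}

#' @export
print.protein_sentence <- function(x, ...) {
  cat("protein_sentence:", x$protein_id, "-", length(x$term_ids), "tokens (",
    length(unique(x$term_ids)), "distinct terms ), dim", ncol(x$matrix), "\n")
  invisible(x)
}

# Sentences for every distinct protein in a pair table, built once.
build_sentence_table <- function(pairs, pgaa, vectors, weighted = pgaa$weighted,
                                 weight_cap = 10L) {
  prots <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  stats::setNames(lapply(prots, build_sentence, pgaa = pgaa, vectors = vectors,
                         weighted = weighted, weight_cap = weight_cap), prots)
}

#' Stratified train/test split of a pair corpus
#'
#' Seeded shuffle followed by a split at `train_fraction`, stratified by
#' label so both partitions keep the class balance. The conventional
#' evaluation protocol holds out 10\% of the corpus, hence the default.
#'
#' @param pairs Labelled pairs data.frame.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.9).
#' @param seed RNG seed.
#' @return List with data.frames `train` and `test` (disjoint, union =
#'   input).
#' @export
split_pairs <- function(pairs, train_fraction = 0.9, seed = 1L) {
  stopifnot(nrow(pairs) >= 2L, train_fraction > 0, train_fraction < 1)
  if (!"label" %in% names(pairs)) stop("split_pairs needs labelled pairs")
  by_class <- split(seq_len(nrow(pairs)), pairs$label)
  # per-class training quotas by largest remainder, so the overall split
  # hits round(n * fraction) while staying stratified
  quota <- vapply(by_class, length, integer(1)) * train_fraction
  n_tr <- floor(quota)
  short <- round(nrow(pairs) * train_fraction) - sum(n_tr)
  if (short > 0) {
    bump <- order(quota - n_tr, decreasing = TRUE)[seq_len(short)]
    n_tr[bump] <- n_tr[bump] + 1L
  }
  idx_tr <- with_seed(seed, {
    unlist(lapply(seq_along(by_class), function(k) {
      ix <- by_class[[k]]
      if (n_tr[[k]] == 0L) return(integer(0))
      sample(ix)[seq_len(n_tr[[k]])]
    }), use.names = FALSE)
  })
  train <- pairs[sort(idx_tr), , drop = FALSE]
  test <- pairs[setdiff(seq_len(nrow(pairs)), idx_tr), , drop = FALSE]
  rownames(train) <- NULL; rownames(test) <- NULL
  list(train = train, test = test)
}
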