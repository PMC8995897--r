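#' Configuration for the synthetic benchmark generator
#'
#' The generator emits a complete, self-consistent desk-scale fixture set:
#' a random rooted GO-like DAG (one namespace, mixed `is_a`/`part_of`
#' edges), a GAF 2.2 annotation file with mixed evidence codes and
#' duplicated records, and a balanced labelled PPI pair list with planted
#' co-annotation signal. Proteins are assigned to branches ("subtrees")
#' of the ontology; with probability `signal_strength` an interacting pair
#' is drawn from one branch and a non-interacting pair from two different
#' branches, so co-annotation is exactly the signal every method in the
#' package can in principle detect. At `signal_strength = 0` both classes
#' are drawn identically and the labels carry no information.
#'
#' @param n_terms Number of ontology terms (>= 5).
#' @param max_depth Maximum term depth (root = 0).
#' @param branching Probability a term gets a second parent.
#' @param n_proteins Number of annotated proteins.
#' @param terms_per_protein Integer range `c(min, max)` of true terms per
#'   protein.
#' @param n_pos_pairs Positive pairs to emit (negatives match the count).
#' @param signal_strength Probability in `[0, 1]` that a pair respects the
#'   branch structure (same branch for positives, different branches for
#'   negatives).
#' @param frac_iea,frac_nd Fractions of annotation records stamped with
#'   the unreliable evidence codes IEA / ND.
#' @param dup_rate Mean extra duplicate records (distinct references) per
#'   reliable true annotation; duplication emulates independently
#'   re-asserted, hence more trustworthy, annotations.
#' @param noise_terms_per_protein Spurious uniformly-drawn terms added per
#'   protein as reliable-code singleton records (never duplicated);
#'   with `dup_rate > 0` duplication count then correlates with
#'   annotation correctness.
#' @param seed Master seed; all stages derive from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_terms = 50L, max_depth = 6L, branching = 0.3,
                         n_proteins = 120L, terms_per_protein = c(3L, 8L),
                         n_pos_pairs = 100L, signal_strength = 1.0,
                         frac_iea = 0.2, frac_nd = 0.05, dup_rate = 1.0,
                         noise_terms_per_protein = 0L, seed = 1L) {
  stopifnot(n_terms >= 5L, max_depth >= 2L, branching >= 0, branching <= 1,
            n_proteins >= 2L, length(terms_per_protein) == 2L,
            terms_per_protein[[1]] >= 1L,
            terms_per_protein[[2]] >= terms_per_protein[[1]],
            n_pos_pairs >= 1L, signal_strength >= 0, signal_strength <= 1,
            frac_iea >= 0, frac_nd >= 0, frac_iea + frac_nd < 1,
            dup_rate >= 0, noise_terms_per_protein >= 0L)
  structure(list(n_terms = as.integer(n_terms), max_depth = as.integer(max_depth),
                 branching = branching, n_proteins = as.integer(n_proteins),
                 terms_per_protein = as.integer(terms_per_protein),
                 n_pos_pairs = as.integer(n_pos_pairs),
                 signal_strength = signal_strength, frac_iea = frac_iea,
                 frac_nd = frac_nd, dup_rate = dup_rate,
                 noise_terms_per_protein = as.integer(noise_terms_per_protein),
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_term_id <- function(i) sprintf("GO:%07d", i)

#' Generate a random rooted ontology DAG
#'
#' Single namespace (`biological_process`), acyclic by construction (each
#' term's parents are earlier terms), depth-capped, with a mixture of
#' `is_a` (70\%) and `part_of` (30\%) edges.
#'
#' @param cfg A [synth_config()].
#' @return A `go_graph`.
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_terms
    ids <- synth_term_id(seq_len(n))
    depth <- integer(n); depth[[1]] <- 0L
    parents <- stats::setNames(vector("list", n), ids)
    parents[[1]] <- data.frame(parent = character(0), relation = character(0),
                               stringsAsFactors = FALSE)
    for (i in 2:n) {
      eligible <- which(depth[seq_len(i - 1L)] < cfg$max_depth)
      p1 <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      rel1 <- sample(c("is_a", "part_of"), 1L, prob = c(0.7, 0.3))
      pdf <- data.frame(parent = ids[[p1]], relation = rel1,
                        stringsAsFactors = FALSE)
      if (stats::runif(1) < cfg$branching) {
        others <- setdiff(eligible, p1)
        if (length(others)) {
          p2 <- if (length(others) == 1L) others else sample(others, 1L)
          rel2 <- sample(c("is_a", "part_of"), 1L, prob = c(0.7, 0.3))
          pdf <- rbind(pdf, data.frame(parent = ids[[p2]], relation = rel2,
                                       stringsAsFactors = FALSE))
        }
      }
      parents[[i]] <- pdf
      depth[[i]] <- max(depth[match(pdf$parent, ids)]) + 1L
    }
    term_df <- data.frame(id = ids,
                          name = sprintf("synthetic term %d", seq_len(n)),
                          namespace = "biological_process",
                          stringsAsFactors = FALSE)
    new_go_graph(term_df, parents)
  })
}

#' Serialize a GO graph as an OBO 1.2 file
#'
#' Deterministic: same graph, byte-identical file. Round-trips through
#' [parse_obo()] without loss.
#'
#' @param g A `go_graph`.
#' @param path Output path.
#' @export
write_obo <- function(g, path) {
  stopifnot(inherits(g, "go_graph"))
  out <- c("format-version: 1.2", "ontology: synthetic-go", "")
  for (i in seq_len(nrow(g$terms))) {
    id <- g$terms$id[[i]]
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", g$terms$name[[i]]),
                paste0("namespace: ", g$terms$namespace[[i]]))
    p <- g$parents[[id]]
    if (nrow(p)) {
      p <- p[order(p$parent), , drop = FALSE]
      for (j in seq_len(nrow(p))) {
        stanza <- c(stanza, if (p$relation[[j]] == "is_a") {
          paste0("is_a: ", p$parent[[j]])
        } else {
          paste0("relationship: part_of ", p$parent[[j]])
        })
      }
    }
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

synth_protein_id <- function(i) sprintf("P%05d", i)

#' Generate synthetic GAF annotations with evidence and duplication structure
#'
#' Each protein is assigned to a branch of the ontology (a depth-1 subtree)
#' and draws its true terms from that branch. Every record gets an
#' evidence code (reliable EXP/IDA vs IEA vs ND at the configured
#' fractions); reliable true annotations receive `Poisson(dup_rate)` extra
#' duplicate records with distinct references. Optional noise terms are
#' drawn uniformly from the whole graph and emitted once, always with a
#' reliable code, so duplication count tracks correctness.
#'
#' @param cfg A [synth_config()].
#' @param g The graph from [generate_ontology()].
#' @return List with `records` (data.frame of 17-column GAF fields, one
#'   row per record) and `ledger` (ground truth: per-code counts, true
#'   (protein, term) duplication counts, per-protein branch anchors and
#'   noise terms).
#' @export
generate_annotations <- function(cfg, g) {
  stopifnot(inherits(cfg, "synth_config"), inherits(g, "go_graph"))
  root <- g$roots[[1]]
  anchors <- g$children[[root]]$child
  if (length(anchors) < 2L) {
    stop("Synthetic graph has fewer than 2 branches; increase n_terms")
  }
  subtrees <- lapply(anchors, function(a) go_descendants(g, a))
  names(subtrees) <- anchors

  with_seed(cfg$seed + 1L, {
    prot <- synth_protein_id(seq_len(cfg$n_proteins))
    anchor_of <- stats::setNames(sample(anchors, cfg$n_proteins, replace = TRUE),
                                 prot)
    rec_protein <- character(0); rec_term <- character(0)
    rec_code <- character(0); rec_ref <- character(0)
    dup_counts <- list()
    noise_of <- stats::setNames(vector("list", cfg$n_proteins), prot)
    ref_no <- 0L
    next_ref <- function() {
      ref_no <<- ref_no + 1L
      sprintf("PMID:%07d", ref_no)
    }
    codes_rel <- c("EXP", "IDA")
    for (p in prot) {
      pool <- subtrees[[anchor_of[[p]]]]
      k <- sample(cfg$terms_per_protein[[1]]:cfg$terms_per_protein[[2]], 1L)
      terms <- if (length(pool) <= k) pool else sample(pool, k)
      for (t in terms) {
        u <- stats::runif(1)
        if (u < cfg$frac_iea) {
          code <- "IEA"; ndup <- 0L
        } else if (u < cfg$frac_iea + cfg$frac_nd) {
          code <- "ND"; ndup <- 0L
        } else {
          code <- sample(codes_rel, 1L)
          ndup <- stats::rpois(1L, cfg$dup_rate)
        }
        ncopies <- 1L + ndup
        for (cc in seq_len(ncopies)) {
          rec_protein <- c(rec_protein, p); rec_term <- c(rec_term, t)
          rec_code <- c(rec_code, code); rec_ref <- c(rec_ref, next_ref())
        }
        if (!code %in% c("IEA", "ND")) {
          dup_counts[[paste(p, t, sep = "\r")]] <- ncopies
        }
      }
      if (cfg$noise_terms_per_protein > 0L) {
        cand <- setdiff(g$terms$id, c(terms, root))
        nn <- min(cfg$noise_terms_per_protein, length(cand))
        noise <- if (nn > 0L) sample(cand, nn) else character(0)
        noise_of[[p]] <- noise
        for (t in noise) {
          rec_protein <- c(rec_protein, p); rec_term <- c(rec_term, t)
          rec_code <- c(rec_code, sample(codes_rel, 1L))
          rec_ref <- c(rec_ref, next_ref())
          dup_counts[[paste(p, t, sep = "\r")]] <- 1L
        }
      }
    }

    records <- data.frame(
      db = "UniProtKB", protein_id = rec_protein, symbol = rec_protein,
      qualifier = "enables", term_id = rec_term, reference = rec_ref,
      evidence_code = rec_code, with_from = "", aspect = "P",
      name = "synthetic protein", synonym = "", type = "protein",
      taxon = "taxon:4932", date = "20220101", assigned_by = "SYN",
      extension = "", form_id = "", stringsAsFactors = FALSE)

    ledger <- list(
      n_records = nrow(records),
      code_counts = as.list(table(records$evidence_code)),
      n_unreliable = sum(records$evidence_code %in% c("IEA", "ND")),
      dup_counts = dup_counts,
      anchor_of = as.list(anchor_of),
      noise_of = noise_of)
    list(records = records, ledger = ledger)
  })
}

#' Write synthetic annotation records as a GAF 2.2 file
#'
#' @param records The `records` data.frame from [generate_annotations()].
#' @param path Output path.
#' @export
write_gaf <- function(records, path) {
  hdr <- c("!gaf-version: 2.2", "!generated-by: ppisent synthetic generator")
  lines <- do.call(paste, c(unname(records), sep = "\t"))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Generate balanced labelled PPI pairs with planted co-annotation signal
#'
#' Positive pairs come (with probability `signal_strength`) from one
#' branch of the ontology; negative pairs (with the same probability) from
#' two different branches. The remainder of either class is drawn
#' uniformly, so `signal_strength = 0` makes the two classes
#' indistinguishable. No pair is emitted twice in any orientation and no
#' negative collides with a positive.
#'
#' @param cfg A [synth_config()].
#' @param g The synthetic `go_graph`.
#' @param annotations Result of [generate_annotations()].
#' @return data.frame `protein_a`, `protein_b`, `label` with
#'   `2 * n_pos_pairs` rows, positives first.
#' @export
generate_pairs <- function(cfg, g, annotations) {
  stopifnot(inherits(cfg, "synth_config"))
  anchor_of <- unlist(annotations$ledger$anchor_of)
  prots <- names(anchor_of)
  by_anchor <- split(prots, anchor_of)
  by_anchor <- by_anchor[lengths(by_anchor) >= 2L]
  if (length(by_anchor) == 0L) stop("No branch holds two proteins; cannot plant signal")

  with_seed(cfg$seed + 2L, {
    seen <- new.env(parent = emptyenv())
    key2 <- function(a, b) if (a < b) paste(a, b) else paste(b, a)
    draw_pair <- function(want_same) {
      for (tries in seq_len(10000L)) {
        if (is.na(want_same)) {
          ab <- sample(prots, 2L)
        } else if (want_same) {
          grp <- by_anchor[[sample.int(length(by_anchor), 1L)]]
          ab <- sample(grp, 2L)
        } else {
          a <- sample(prots, 1L)
          others <- prots[anchor_of != anchor_of[[a]]]
          if (!length(others)) next
          ab <- c(a, sample(others, 1L))
        }
        k <- key2(ab[[1]], ab[[2]])
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          return(ab)
        }
      }
      stop("Could not draw enough distinct pairs; enlarge the protein set")
    }
    pos <- t(vapply(seq_len(cfg$n_pos_pairs), function(i) {
      draw_pair(if (stats::runif(1) < cfg$signal_strength) TRUE else NA)
    }, character(2)))
    neg <- t(vapply(seq_len(cfg$n_pos_pairs), function(i) {
      draw_pair(if (stats::runif(1) < cfg$signal_strength) FALSE else NA)
    }, character(2)))
    data.frame(protein_a = c(pos[, 1], neg[, 1]),
               protein_b = c(pos[, 2], neg[, 2]),
               label = rep(c(1L, 0L), each = cfg$n_pos_pairs),
               stringsAsFactors = FALSE)
  })
}

#' Emit a complete synthetic benchmark to a directory
#'
#' Writes `ontology.obo`, `annotations.gaf`, `pairs.tsv` (external ids),
#' `id_map.tsv` and `ledger.json` under `dir`, all derived
#' deterministically from the config seed.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory objects (`graph`,
#'   `annotations`, `pairs`) and the file `paths`.
#' @export
simulate_benchmark <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- generate_ontology(cfg)
  ann <- generate_annotations(cfg, g)
  pairs <- generate_pairs(cfg, g, ann)

  prots <- sort(unique(c(pairs$protein_a, pairs$protein_b,
                         ann$records$protein_id)))
  ext <- paste0("EXT_", prots)
  id_map_lines <- paste(ext, prots, sep = "\t")
  pairs_ext <- data.frame(protein_a = paste0("EXT_", pairs$protein_a),
                          protein_b = paste0("EXT_", pairs$protein_b),
                          label = pairs$label, stringsAsFactors = FALSE)

  paths <- list(obo = file.path(dir, "ontology.obo"),
                gaf = file.path(dir, "annotations.gaf"),
                pairs = file.path(dir, "pairs.tsv"),
                id_map = file.path(dir, "id_map.tsv"),
                ledger = file.path(dir, "ledger.json"))
  write_obo(g, paths$obo)
  write_gaf(ann$records, paths$gaf)
  write_pairs(pairs_ext, paths$pairs)
  writeLines(id_map_lines, paths$id_map)
  jsonlite::write_json(ann$ledger, paths$ledger, auto_unbox = TRUE, digits = NA)
  invisible(list(graph = g, annotations = ann, pairs = pairs, paths = paths))
}
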