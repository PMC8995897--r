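# Shared in-code fixtures: tiny OBO documents and annotation tables.

obo_lines <- function(...) paste(c("format-version: 1.2", "", ...), collapse = "\n")

write_tmp <- function(text, ext = ".obo") {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}

# A -> B (is_a), A -> C (part_of); A is root.
obo_three_terms <- function() {
  obo_lines(
    "[Term]", "id: GO:0000001", "name: alpha", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: beta", "namespace: biological_process",
    "is_a: GO:0000001 ! alpha", "",
    "[Term]", "id: GO:0000003", "name: gamma", "namespace: biological_process",
    "relationship: part_of GO:0000001", "")
}

# chain root -> A -> B -> C, all is_a
obo_chain4 <- function() {
  obo_lines(
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: a", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: b", "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: c", "namespace: biological_process",
    "is_a: GO:0000003", "")
}

# diamond: D -> B -> A, D -> C -> A
obo_diamond <- function() {
  obo_lines(
    "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: d", "namespace: biological_process",
    "is_a: GO:0000002", "is_a: GO:0000003", "")
}

parse_obo_text <- function(text) parse_obo(write_tmp(text))

# Random small DAG via the package generator (oracles below are the
# independent check on whatever it produces).
random_graph <- function(n_terms, seed, branching = 0.4) {
  generate_ontology(synth_config(n_terms = max(n_terms, 5L), branching = branching,
                                 max_depth = 8L, seed = seed))
}

# pgaa built directly from a (protein, term, weight) table
pgaa_from_df <- function(df, weighted = TRUE) {
  recs <- df[rep(seq_len(nrow(df)), df$weight), c("protein_id", "term_id")]
  recs$evidence_code <- "EXP"
  recs$aspect <- "P"
  recs$reference <- paste0("PMID:", seq_len(nrow(recs)))
  build_pgaa(recs, weighted = weighted)
}

# GAF line with the given core fields, other columns valid placeholders
gaf_line <- function(protein, term, code = "EXP", qualifier = "enables",
                     ref = "PMID:1") {
  paste("UniProtKB", protein, protein, qualifier, term, ref, code, "", "P",
        "name", "", "protein", "taxon:4932", "20220101", "SYN", "", "",
        sep = "\t")
}

# run code under a fixed seed, restoring global RNG state afterwards
with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  code
}

# deterministic toy term vectors: orthogonal-ish unit rows
toy_vectors <- function(term_ids, dim = 8L, seed = 42L) {
  n <- length(term_ids)
  m <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  m <- matrix(stats::rnorm(n * dim), nrow = n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  m <- m / sqrt(rowSums(m^2))
  rownames(m) <- term_ids
  structure(list(dim = as.integer(dim), seed = as.integer(seed), vectors = m),
            class = "term_vectors")
}
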