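# An IC table over the 4-term chain, built from a hand-planned annotation
# layout: frequencies root=6, a=3, b=2, c=1.
chain_fixture <- function() {
  g <- parse_obo_text(obo_chain4())
  pg <- pgaa_from_df(data.frame(
    protein_id = paste0("P", 1:6),
    term_id = c("GO:0000001", "GO:0000001", "GO:0000001",
                "GO:0000002", "GO:0000003", "GO:0000004"),
    weight = 1L))
  list(g = g, ic = compute_ic(g, pg))
}

test_that("Resnik similarity is the MICA information content", {
  fx <- chain_fixture()
  t <- "GO:0000003"
  expect_equal(sim_resnik(fx$g, fx$ic, t, t), fx$ic$ic[[t]])
  # two depth-1 siblings share only the root
  g3 <- parse_obo_text(obo_three_terms())
  pg3 <- pgaa_from_df(data.frame(protein_id = paste0("P", 1:2),
                                 term_id = c("GO:0000002", "GO:0000003"),
                                 weight = 1L))
  ic3 <- compute_ic(g3, pg3)
  expect_equal(sim_resnik(g3, ic3, "GO:0000002", "GO:0000003"), 0)
  # mid-chain pair: MICA is the shallower term
  expect_equal(sim_resnik(fx$g, fx$ic, "GO:0000003", "GO:0000004"),
               fx$ic$ic[["GO:0000003"]])
})

test_that("Lin similarity normalizes the MICA IC", {
  fx <- chain_fixture()
  expect_equal(sim_lin(fx$g, fx$ic, "GO:0000003", "GO:0000003"), 1)
  g3 <- parse_obo_text(obo_three_terms())
  pg3 <- pgaa_from_df(data.frame(protein_id = paste0("P", 1:2),
                                 term_id = c("GO:0000002", "GO:0000003"),
                                 weight = 1L))
  ic3 <- compute_ic(g3, pg3)
  expect_equal(sim_lin(g3, ic3, "GO:0000002", "GO:0000003"), 0)  # MICA = root
  expect_error(sim_lin(fx$g, fx$ic, "GO:0000001", "GO:0000001"), "zero IC")
  v <- sim_lin(fx$g, fx$ic, "GO:0000003", "GO:0000004")
  expect_equal(v, 2 * fx$ic$ic[["GO:0000003"]] /
                  (fx$ic$ic[["GO:0000003"]] + fx$ic$ic[["GO:0000004"]]))
})

test_that("Pekar similarity follows longest-path ratios", {
  g <- parse_obo_text(obo_chain4())
  expect_equal(sim_pekar(g, "GO:0000003", "GO:0000003"), 1)  # non-root self
  expect_equal(sim_pekar(g, "GO:0000003", "GO:0000004"), 2 / 3)  # c = B
  g3 <- parse_obo_text(obo_three_terms())
  expect_equal(sim_pekar(g3, "GO:0000002", "GO:0000003"), 0)  # c = root
})

test_that("Wang similarity reproduces the hand-computed chain S-values", {
  g <- parse_obo_text(obo_chain4())  # root -> A -> B (use first three)
  sB <- ppisent:::wang_svalues(g, "GO:0000003",
                               ppisent:::baseline_context(g))
  expect_equal(sort(unname(sB), decreasing = TRUE), c(1, 0.8, 0.64))
  expect_equal(sum(sB), 2.44)
  expect_equal(sim_wang(g, "GO:0000003", "GO:0000002"), 3.24 / 4.24)
  expect_equal(sim_wang(g, "GO:0000003", "GO:0000003"), 1)
  # part_of edges weigh 0.6
  g3 <- parse_obo_text(obo_three_terms())
  expect_equal(sim_wang(g3, "GO:0000002", "GO:0000003"),
               (0.8 + 0.6) / (1.8 + 1.6))
})

test_that("term measures are symmetric and properly bounded", {
  for (seed in c(2, 8)) {
    g <- random_graph(12, seed = seed)
    pg <- pgaa_from_df(data.frame(
      protein_id = paste0("P", 1:10),
      term_id = with_seed_helper(seed, sample(g$terms$id, 10, replace = TRUE)),
      weight = 1L))
    ic <- compute_ic(g, pg)
    ids <- names(ic$ic)
    combos <- utils::combn(ids, 2)
    for (k in seq_len(ncol(combos))) {
      t1 <- combos[1, k]; t2 <- combos[2, k]
      r12 <- sim_resnik(g, ic, t1, t2)
      expect_equal(r12, sim_resnik(g, ic, t2, t1))
      expect_gte(r12, 0)
      p12 <- sim_pekar(g, t1, t2)
      expect_equal(p12, sim_pekar(g, t2, t1))
      expect_true(p12 >= 0 && p12 <= 1)
      w12 <- sim_wang(g, t1, t2)
      expect_equal(w12, sim_wang(g, t2, t1))
      expect_true(w12 > 0 && w12 <= 1)
    }
  }
})

test_that("all four measures match the brute-force oracles on random DAGs", {
  for (seed in 1:6) {
    g <- random_graph(sample(6:12, 1), seed = 300 + seed)
    pg <- pgaa_from_df(data.frame(
      protein_id = paste0("P", 1:12),
      term_id = with_seed_helper(seed, sample(g$terms$id, 12, replace = TRUE)),
      weight = 1L))
    ic <- compute_ic(g, pg)
    ids <- g$terms$id
    ic_ids <- names(ic$ic)[ic$ic > 0]  # IC defined and nonzero
    pick <- with_seed_helper(seed * 7, {
      cbind(sample(ids, 8, replace = TRUE), sample(ids, 8, replace = TRUE),
            sample(ic_ids, 8, replace = TRUE), sample(ic_ids, 8, replace = TRUE))
    })
    for (k in seq_len(nrow(pick))) {
      t1 <- pick[k, 1]; t2 <- pick[k, 2]
      i1 <- pick[k, 3]; i2 <- pick[k, 4]
      expect_equal(sim_resnik(g, ic, i1, i2), oracle_resnik(g, ic, i1, i2),
                   tolerance = 1e-12)
      expect_equal(sim_lin(g, ic, i1, i2), oracle_lin(g, ic, i1, i2),
                   tolerance = 1e-12)
      expect_equal(sim_pekar(g, t1, t2), oracle_pekar(g, t1, t2),
                   tolerance = 1e-12)
      expect_equal(sim_wang(g, t1, t2), oracle_wang(g, t1, t2),
                   tolerance = 1e-12)
    }
  }
})

test_that("aggregation reduces the pair matrix as AVG / Max / BMA", {
  fx <- chain_fixture()
  simfn <- function(a, b) sim_lin(fx$g, fx$ic, a, b)
  t1 <- "GO:0000003"; t2 <- "GO:0000004"
  for (mode in c("avg", "max", "bma")) {
    expect_equal(aggregate_similarity(simfn, t1, t2, mode), simfn(t1, t2))
  }
  T12 <- c("GO:0000003", "GO:0000004")
  expect_equal(aggregate_similarity(simfn, T12, T12, "bma"), 1)

  # brute force on random sets
  for (seed in c(4, 9)) {
    g <- random_graph(12, seed = 400 + seed)
    ids <- g$terms$id
    wfn <- function(a, b) sim_wang(g, a, b)
    sets <- with_seed_helper(seed, list(sample(ids, 4), sample(ids, 3)))
    M <- outer(sets[[1]], sets[[2]], Vectorize(wfn))
    for (mode in c("avg", "max", "bma")) {
      expect_equal(aggregate_similarity(wfn, sets[[1]], sets[[2]], mode),
                   oracle_aggregate(M, mode), tolerance = 1e-12)
    }
  }
  expect_error(aggregate_similarity(simfn, character(0), t2), "empty")
})

test_that("the literal uncorrected aggregation collapses to rescaled AVG", {
  g <- random_graph(10, seed = 13)
  ids <- g$terms$id
  wfn <- function(a, b) sim_wang(g, a, b)
  T1 <- ids[2:4]; T2 <- ids[5:6]
  S <- sum(outer(T1, T2, Vectorize(wfn)))
  expect_equal(aggregate_similarity(wfn, T1, T2, "bma_literal"),
               (S / 3 + S / 2) / 2, tolerance = 1e-12)
})

test_that("protein pair scores are symmetric and separate planted classes", {
  dir <- file.path(tempdir(), "baseline-fixture")
  fix <- simulate_benchmark(synth_config(n_proteins = 40L, n_pos_pairs = 20L,
                                         seed = 6L), dir)
  pg <- build_pgaa(filter_by_evidence(parse_gaf(fix$paths$gaf)), weighted = FALSE)
  pairs <- screen_pairs(fix$pairs, pg, NULL)
  ic <- compute_ic(fix$graph, pg)
  for (measure in c("resnik", "lin", "pekar", "wang")) {
    sc <- score_pairs(pairs, pg, fix$graph, ic, measure = measure, mode = "bma")
    swapped <- pairs
    names(swapped)[1:2] <- c("protein_b", "protein_a")
    sc2 <- score_pairs(swapped, pg, fix$graph, ic, measure = measure, mode = "bma")
    expect_equal(sc$score, sc2$score, tolerance = 1e-12)
    expect_gt(mean(sc$score[sc$label == 1L]), mean(sc$score[sc$label == 0L]))
  }
  # identical annotation sets score 1 under lin/bma
  p <- names(pg$axioms)[[1]]
  self_pair <- data.frame(protein_a = p, protein_b = p, stringsAsFactors = FALSE)
  expect_equal(score_pairs(self_pair, pg, fix$graph, ic, "lin", "bma")$score, 1)
  # per-pair recomputation oracle
  sc <- score_pairs(pairs[1:10, ], pg, fix$graph, ic, "lin", "bma")
  for (i in 1:10) {
    T1 <- unique(pg$axioms[[pairs$protein_a[[i]]]]$term_id)
    T2 <- unique(pg$axioms[[pairs$protein_b[[i]]]]$term_id)
    M <- outer(T1, T2, Vectorize(function(a, b) oracle_lin(fix$graph, ic, a, b)))
    expect_equal(sc$score[[i]], oracle_aggregate(M, "bma"), tolerance = 1e-12)
  }
})
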