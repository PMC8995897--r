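# A small linearly separable pair corpus: four "profile couples" of
# proteins with identical term sets. A pair is positive iff its two
# proteins share a profile, negative across profiles.
toy_pair_corpus <- function() {
  terms <- sprintf("GO:%07d", 1:8)
  vec <- toy_vectors(terms, dim = 8)
  profile <- list(A = terms[1:2], B = terms[3:4], C = terms[5:6], D = terms[7:8])
  prot_profile <- rep(names(profile), each = 2)  # P1..P8
  df <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(protein_id = paste0("P", i),
               term_id = profile[[prot_profile[[i]]]], weight = 1L,
               stringsAsFactors = FALSE)
  }))
  pg <- pgaa_from_df(df)
  pairs <- data.frame(
    protein_a = c("P1", "P3", "P5", "P7", "P1", "P2", "P4", "P6"),
    protein_b = c("P2", "P4", "P6", "P8", "P3", "P5", "P7", "P8"),
    label     = c(1L,  1L,  1L,  1L,  0L,  0L,  0L,  0L),
    stringsAsFactors = FALSE)
  list(pg = pg, vec = vec, pairs = pairs)
}

small_config <- function(...) {
  ppisent_config(embed_dim = 8L, conv_channels = c(8L, 8L), hidden_dim = 16L,
                 batch_size = 2L, ...)
}

test_that("sentence embeddings have fixed size regardless of sentence length", {
  fx <- toy_pair_corpus()
  model <- ppisent(fx$pairs, fx$pg, fx$vec, config = small_config(epochs = 2L))
  pg_long <- pgaa_from_df(data.frame(protein_id = "PL",
                                     term_id = sprintf("GO:%07d", 1:8),
                                     weight = 5L))
  s1 <- build_sentence("P1", fx$pg, fx$vec)          # short sentence
  s40 <- build_sentence("PL", pg_long, fx$vec)       # 40 tokens
  e1 <- encode_sentence(model, s1)
  e40 <- encode_sentence(model, s40)
  expect_length(e1, 16L)
  expect_length(e40, 16L)
  expect_identical(encode_sentence(model, s1), e1)   # deterministic
})

test_that("kernel-1 encoding is invariant to token permutation", {
  fx <- toy_pair_corpus()
  model <- ppisent(fx$pairs, fx$pg, fx$vec,
                   config = small_config(epochs = 2L, kernel_size = 1L))
  s <- build_sentence("PL", pgaa_from_df(
    data.frame(protein_id = "PL", term_id = sprintf("GO:%07d", 1:8),
               weight = 2L)), fx$vec)
  perm <- rev(seq_along(s$term_ids))
  s_perm <- s
  s_perm$term_ids <- s$term_ids[perm]
  s_perm$matrix <- s$matrix[perm, , drop = FALSE]
  expect_equal(encode_sentence(model, s_perm), encode_sentence(model, s),
               tolerance = 1e-12)
})

test_that("pair features follow the [u, v, |u-v|, u*v] composition", {
  expect_equal(combine_features(c(1, 0), c(0, 1)),
               c(1, 0, 0, 1, 1, 1, 0, 0))
  u <- c(0.3, -0.2, 5)
  expect_equal(combine_features(u, u)[7:9], c(0, 0, 0))  # |u-v| block
  expect_length(combine_features(u, u), 12L)
  expect_error(combine_features(1:2, 1:3), "length")
})

test_that("training separates a planted toy corpus and is deterministic", {
  fx <- toy_pair_corpus()
  cfg <- small_config(epochs = 200L, seed = 3L)
  model <- ppisent(fx$pairs, fx$pg, fx$vec, config = cfg)
  preds <- predict(model, fx$pairs, fx$pg, fx$vec)
  expect_equal(as.integer(preds$label == "positive"), fx$pairs$label)
  expect_lte(utils::tail(model$loss_history, 1), model$loss_history[[1]])

  model2 <- ppisent(fx$pairs, fx$pg, fx$vec, config = cfg)
  expect_identical(model$params, model2$params)
  expect_identical(model$loss_history, model2$loss_history)

  one_class <- fx$pairs
  one_class$label <- 1L
  expect_error(ppisent(one_class, fx$pg, fx$vec, config = cfg), "single class")
})

test_that("predictions are normalized probabilities with the strict decision rule", {
  fx <- toy_pair_corpus()
  model <- ppisent(fx$pairs, fx$pg, fx$vec, config = small_config(epochs = 30L))
  preds <- predict(model, fx$pairs, fx$pg, fx$vec)
  expect_true(all(abs(preds$p_positive + preds$p_negative - 1) < 1e-6))
  expect_equal(preds$label == "positive", preds$p_positive > 0.5)

  # degenerate model with all-zero output weights ties at exactly 0.5:
  # the strict rule calls it negative
  tied <- model
  tied$params$Wo[] <- 0
  tied$params$bo[] <- 0
  ptied <- predict(tied, fx$pairs[1, ], fx$pg, fx$vec)
  expect_identical(ptied$p_positive, 0.5)
  expect_identical(ptied$label, "negative")
})

test_that("label-shuffled training yields chance-level held-out AUC", {
  dir <- file.path(tempdir(), "shuffle-fixture")
  fix <- simulate_benchmark(synth_config(n_proteins = 60L, n_pos_pairs = 40L,
                                         seed = 5L), dir)
  rec <- filter_by_evidence(parse_gaf(fix$paths$gaf))
  pg <- build_pgaa(rec, weighted = TRUE)
  vec <- train_term_vectors(axiom_corpus(fix$graph), dim = 16, epochs = 60,
                            seed = 5)
  screened <- screen_pairs(fix$pairs, pg, NULL)
  aucs <- vapply(1:5, function(seed) {
    sh <- screened
    sh$label <- with_seed_helper(seed, sample(sh$label))
    sp <- split_pairs(sh, 0.8, seed = seed)
    m <- ppisent(sp$train, pg, vec,
                 config = ppisent_config(embed_dim = 16L,
                                         conv_channels = c(16L, 16L),
                                         hidden_dim = 32L, epochs = 15L,
                                         batch_size = 4L, seed = seed))
    pr <- predict(m, sp$test, pg, vec)
    roc_curve(sp$test$label, pr$p_positive)$auc
  }, numeric(1))
  expect_gte(stats::median(aucs), 0.35)
  expect_lte(stats::median(aucs), 0.65)
})

test_that("model checkpoints round-trip through JSON", {
  fx <- toy_pair_corpus()
  model <- ppisent(fx$pairs, fx$pg, fx$vec, config = small_config(epochs = 5L))
  f <- tempfile(fileext = ".json")
  save_ppisent(model, f)
  m2 <- load_ppisent(f)
  expect_equal(m2$params, model$params, tolerance = 1e-12)
  p1 <- predict(model, fx$pairs, fx$pg, fx$vec)
  p2 <- predict(m2, fx$pairs, fx$pg, fx$vec)
  expect_equal(p2$p_positive, p1$p_positive, tolerance = 1e-12)
})
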