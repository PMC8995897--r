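make_screen_fixture <- function() {
  pg <- pgaa_from_df(data.frame(
    protein_id = c("P1", "P2", "P3"),
    term_id = sprintf("GO:%07d", c(1, 2, 3)), weight = 1))
  idm <- c(X1 = "P1", X2 = "P2", X3 = "P3", X4 = "P4")  # P4 unannotated
  list(pg = pg, idm = idm)
}

test_that("screening keeps only mappable, annotated endpoints", {
  fx <- make_screen_fixture()
  pairs <- data.frame(protein_a = c("X1", "X1", "X2", "X9"),
                      protein_b = c("X2", "X4", "X3", "X1"),
                      label = c(1L, 1L, 0L, 0L), stringsAsFactors = FALSE)
  out <- screen_pairs(pairs, fx$pg, fx$idm)
  expect_equal(nrow(out), 2L)               # X4 unannotated, X9 unmappable
  expect_equal(out$protein_a, c("P1", "P2"))  # mapped + order preserved
  expect_equal(out$label, c(1L, 0L))
  # survivors all have buildable sentences
  vec <- toy_vectors(sprintf("GO:%07d", 1:3))
  for (p in unique(c(out$protein_a, out$protein_b))) {
    expect_s3_class(build_sentence(p, fx$pg, vec), "protein_sentence")
  }
})

test_that("screening count matches an independent membership recount", {
  set.seed(9)
  prots <- paste0("P", 1:40)
  annotated <- prots[1:20]
  pg <- pgaa_from_df(data.frame(protein_id = annotated,
                                term_id = "GO:0000001", weight = 1))
  pairs <- data.frame(protein_a = sample(prots, 100, replace = TRUE),
                      protein_b = sample(prots, 100, replace = TRUE),
                      label = rep(c(1L, 0L), 50), stringsAsFactors = FALSE)
  out <- screen_pairs(pairs, pg, NULL)
  expect_equal(nrow(out),
               sum(pairs$protein_a %in% annotated & pairs$protein_b %in% annotated))
})

test_that("balancing equalizes class counts and can generate negatives", {
  pos <- data.frame(protein_a = paste0("A", 1:10), protein_b = paste0("B", 1:10),
                    label = 1L, stringsAsFactors = FALSE)
  neg <- data.frame(protein_a = paste0("C", 1:4), protein_b = paste0("D", 1:4),
                    label = 0L, stringsAsFactors = FALSE)
  out <- balance_pairs(rbind(pos, neg), seed = 1)
  expect_equal(as.integer(table(out$label)), c(4L, 4L))

  already <- rbind(pos[1:4, ], neg)
  expect_equal(as.integer(table(balance_pairs(already, seed = 2)$label)), c(4L, 4L))

  # positives only: seeded negative generation avoiding the positive set
  set.seed(11)
  prots <- paste0("P", 1:30)
  pos50 <- unique(t(replicate(80, sample(prots, 2))))[1:50, ]
  pos50 <- data.frame(protein_a = pos50[, 1], protein_b = pos50[, 2],
                      label = 1L, stringsAsFactors = FALSE)
  out2 <- balance_pairs(pos50, seed = 3, proteins = prots)
  expect_equal(as.integer(table(out2$label)), c(50L, 50L))
  gen <- out2[out2$label == 0L, ]
  pos_keys <- c(paste(pos50$protein_a, pos50$protein_b),
                paste(pos50$protein_b, pos50$protein_a))
  expect_false(any(paste(gen$protein_a, gen$protein_b) %in% pos_keys))
  expect_false(any(gen$protein_a == gen$protein_b))

  expect_error(balance_pairs(neg, seed = 1), "No positive")
})

test_that("weighted sentences repeat terms up to the cap, unweighted do not", {
  pg <- pgaa_from_df(data.frame(protein_id = "P1",
                                term_id = c("GO:0000010", "GO:0000020"),
                                weight = c(3L, 1L)))
  vec <- toy_vectors(c("GO:0000010", "GO:0000020"))
  s <- build_sentence("P1", pg, vec, weighted = TRUE, weight_cap = 10L)
  expect_equal(s$term_ids, c(rep("GO:0000010", 3), "GO:0000020"))
  expect_equal(nrow(s$matrix), 4L)
  expect_equal(s$matrix[1, ], unname(vec$vectors["GO:0000010", ]))

  s0 <- build_sentence("P1", pg, vec, weighted = FALSE)
  expect_equal(s0$term_ids, c("GO:0000010", "GO:0000020"))

  pg50 <- pgaa_from_df(data.frame(protein_id = "P1", term_id = "GO:0000010",
                                  weight = 50L))
  s50 <- build_sentence("P1", pg50, vec, weighted = TRUE, weight_cap = 10L)
  expect_equal(length(s50$term_ids), 10L)

  expect_error(build_sentence("P9", pg, vec), "no annotation axioms")
})

test_that("sentence length equals the capped weight sum", {
  set.seed(21)
  df <- data.frame(protein_id = "P1",
                   term_id = sprintf("GO:%07d", 1:6),
                   weight = sample(1:15, 6, replace = TRUE))
  pg <- pgaa_from_df(df)
  vec <- toy_vectors(df$term_id)
  s <- build_sentence("P1", pg, vec, weighted = TRUE, weight_cap = 10L)
  expect_equal(length(s$term_ids), sum(pmin(df$weight, 10L)))
})

test_that("stratified splitting is deterministic, disjoint and balanced", {
  pairs <- data.frame(protein_a = paste0("A", 1:100), protein_b = paste0("B", 1:100),
                      label = rep(c(1L, 0L), each = 50), stringsAsFactors = FALSE)
  sp <- split_pairs(pairs, train_fraction = 0.9, seed = 4)
  expect_equal(nrow(sp$train), 90L)
  expect_equal(nrow(sp$test), 10L)
  expect_equal(sum(sp$train$label), 45L)
  expect_equal(sum(sp$test$label), 5L)
  key <- function(d) paste(d$protein_a, d$protein_b)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)

  sp2 <- split_pairs(pairs, train_fraction = 0.9, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- split_pairs(pairs, train_fraction = 0.9, seed = 5)
  expect_false(identical(sp$train, sp3$train))

  two <- pairs[c(1, 2), ]
  sp50 <- split_pairs(two, train_fraction = 0.5, seed = 1)
  expect_equal(nrow(sp50$train), 1L)
  expect_equal(nrow(sp50$test), 1L)
})
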