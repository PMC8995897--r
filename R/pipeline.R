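#' Run the full interaction-prediction pipeline end to end
#'
#' Orchestrates every stage: parse the ontology and annotations, filter by
#' evidence reliability, build (optionally weighted) annotation axioms,
#' screen and balance the pair list, train skip-gram term vectors on the
#' ontology axiom corpus, fit the sentence-pair CNN on a stratified
#' train split, and evaluate held-out pairs. All randomness derives from
#' `seed`; identical inputs + seed give identical outputs.
#'
#' @param obo,gaf,pairs,id_map Input file paths (`id_map` optional).
#' @param outdir Optional output directory; when given, the PGAA table,
#'   term vectors, model checkpoint, test predictions and a metrics JSON
#'   are written there.
#' @param mode `"weighted"` (duplication-weighted sentences) or
#'   `"noweight"`.
#' @param weight_cap Maximum token repetitions per term.
#' @param embed_dim,embed_epochs,window Term-vector training settings.
#' @param conv_channels,kernel_size,hidden_dim,dropout,lr,batch_size,epochs
#'   Model settings, see [ppisent_config()].
#' @param train_fraction Training fraction of the stratified split.
#' @param seed Master seed.
#' @param quiet Suppress stage logging?
#' @return List with `graph`, `pgaa`, `vectors`, `model`, `split`,
#'   `predictions` (held-out pairs with probabilities), `metrics` and
#'   `counts` (records in/out at each filter stage).
#' @export
run_pipeline <- function(obo, gaf, pairs, id_map = NULL, outdir = NULL,
                         mode = c("weighted", "noweight"), weight_cap = 10L,
                         embed_dim = 32L, embed_epochs = 100L, window = 5L,
                         conv_channels = c(32L, 32L), kernel_size = 3L,
                         hidden_dim = 64L, dropout = 0, lr = 1e-3,
                         batch_size = 2L, epochs = 60L,
                         train_fraction = 0.9, seed = 1L, quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message(...)

  g <- parse_obo(obo)
  say("ontology: ", nrow(g$terms), " terms, ", nrow(go_edges(g)), " edges")

  records <- parse_gaf(gaf)
  filtered <- filter_by_evidence(records)
  say("annotations: ", nrow(records), " records in, ", nrow(filtered),
      " after IEA/ND filter")
  pgaa <- build_pgaa(filtered, weighted = mode == "weighted")

  pr <- read_pairs(pairs)
  idm <- if (!is.null(id_map)) read_id_map(id_map) else NULL
  screened <- screen_pairs(pr, pgaa, idm)
  say("pairs: ", nrow(pr), " in, ", nrow(screened), " after screening")
  balanced <- balance_pairs(screened, seed = seed)
  say("pairs: ", nrow(balanced), " after balancing (",
      sum(balanced$label == 1L), " per class)")

  corpus <- axiom_corpus(g)
  vectors <- train_term_vectors(corpus, dim = embed_dim, window = window,
                                epochs = embed_epochs, seed = seed)
  say("term vectors: ", nrow(vectors$vectors), " terms x ", embed_dim)

  sp <- split_pairs(balanced, train_fraction = train_fraction, seed = seed)
  say("split: ", nrow(sp$train), " train / ", nrow(sp$test), " test")

  cfg <- ppisent_config(embed_dim = embed_dim, conv_channels = conv_channels,
                        kernel_size = kernel_size, hidden_dim = hidden_dim,
                        dropout = dropout, lr = lr, batch_size = batch_size,
                        epochs = epochs, seed = seed)
  model <- ppisent(sp$train, pgaa, vectors, config = cfg,
                   weighted = mode == "weighted", weight_cap = weight_cap)
  say("model trained: final loss ",
      format(utils::tail(model$loss_history, 1), digits = 4))

  preds <- predict(model, sp$test, pgaa, vectors)
  metrics <- evaluate_scores(sp$test$label, preds$p_positive, threshold = 0.5)
  say("held-out accuracy ", format(metrics$accuracy, digits = 4),
      ", AUC_ROC ", format(metrics$auc_roc, digits = 4))

  counts <- list(gaf_records = nrow(records), gaf_filtered = nrow(filtered),
                 pairs_in = nrow(pr), pairs_screened = nrow(screened),
                 pairs_balanced = nrow(balanced),
                 n_train = nrow(sp$train), n_test = nrow(sp$test))

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_pgaa(pgaa, file.path(outdir, "pgaa.tsv"))
    write_term_vectors(vectors, file.path(outdir, "term_vectors.txt"))
    save_ppisent(model, file.path(outdir, "model.json"))
    utils::write.table(preds, file.path(outdir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(c(metrics, counts, list(mode = mode, seed = seed)),
                         file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(graph = g, pgaa = pgaa, vectors = vectors, model = model, split = sp,
       predictions = preds, metrics = metrics, counts = counts)
}
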