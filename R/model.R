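#' Configuration for the sentence-pair CNN model
#'
#' The encoder is a stack of 1-D convolutions over the token axis with
#' ReLU, each followed by max-over-time pooling; the pooled features of
#' every layer are concatenated into a fixed-length sentence embedding
#' (hierarchical ConvNet style). The default kernel size is 3: with
#' max-over-time pooling a kernel of 1 collapses the encoder into a pure
#' set encoder that cannot see token repetition — and repetition is how
#' duplication-weighted sentences carry annotation reliability. A width-3
#' kernel makes runs of a repeated term produce distinct convolution
#' windows, so weighting becomes visible, while order sensitivity stays
#' minimal because tokens are canonically sorted. Set `kernel_size = 1`
#' for a strictly permutation-invariant set encoder.
#'
#' @param embed_dim Input term-vector dimensionality.
#' @param conv_channels Integer vector of output channels per conv layer.
#' @param kernel_size Convolution width along the token axis (odd).
#' @param hidden_dim Classifier hidden width.
#' @param dropout Dropout probability on the pair-feature and hidden
#'   layers during training (0 disables).
#' @param lr Adam learning rate.
#' @param batch_size Examples per gradient step. Small batches (1-2) work
#'   well on these corpora; the default is 2.
#' @param epochs Training epochs.
#' @param seed Seed governing initialization, shuffling and dropout.
#' @return A `ppisent_config` list.
#' @export
ppisent_config <- function(embed_dim, conv_channels = c(64L, 64L),
                           kernel_size = 3L, hidden_dim = 128L, dropout = 0,
                           lr = 1e-3, batch_size = 2L, epochs = 30L,
                           seed = 1L) {
  stopifnot(embed_dim >= 1L, length(conv_channels) >= 1L, all(conv_channels >= 1L),
            kernel_size >= 1L, kernel_size %% 2L == 1L,
            hidden_dim >= 1L, dropout >= 0, dropout < 1,
            lr > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(embed_dim = as.integer(embed_dim),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "ppisent_config")
}

# Glorot-uniform matrix draw (consumes RNG).
glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nrow = nin)
}

init_params <- function(cfg) {
  cin <- c(cfg$embed_dim, cfg$conv_channels)
  conv <- lapply(seq_along(cfg$conv_channels), function(l) {
    list(W = glorot(cfg$kernel_size * cin[[l]], cfg$conv_channels[[l]]),
         b = numeric(cfg$conv_channels[[l]]))
  })
  S <- sum(cfg$conv_channels)
  list(conv = conv,
       Wh = glorot(4L * S, cfg$hidden_dim), bh = numeric(cfg$hidden_dim),
       Wo = glorot(cfg$hidden_dim, 2L), bo = numeric(2L))
}

# im2col over the token axis with zero 'same' padding.
im2col <- function(X, k) {
  if (k == 1L) return(X)
  L <- nrow(X); C <- ncol(X)
  pad <- (k - 1L) %/% 2L
  Xp <- rbind(matrix(0, pad, C), X, matrix(0, k - 1L - pad, C))
  out <- matrix(0, L, k * C)
  for (j in seq_len(k)) {
    out[, ((j - 1L) * C + 1L):(j * C)] <- Xp[j:(j + L - 1L), , drop = FALSE]
  }
  out
}

# Forward pass of the encoder; returns embedding + caches for backprop.
encode_forward <- function(params, cfg, X) {
  stopifnot(ncol(X) == cfg$embed_dim, nrow(X) >= 1L)
  caches <- vector("list", length(params$conv))
  H <- X
  pools <- vector("list", length(params$conv))
  for (l in seq_along(params$conv)) {
    Xc <- im2col(H, cfg$kernel_size)
    pre <- sweep(Xc %*% params$conv[[l]]$W, 2L, params$conv[[l]]$b, `+`)
    Hl <- pre * (pre > 0)
    am <- max.col(t(Hl), ties.method = "first")  # argmax row per channel
    pools[[l]] <- Hl[cbind(am, seq_len(ncol(Hl)))]
    caches[[l]] <- list(Xc = Xc, H = Hl, argmax = am)
    H <- Hl
  }
  list(u = unlist(pools, use.names = FALSE), caches = caches)
}

# Backward pass of the encoder given the gradient of the pooled embedding.
encode_backward <- function(params, cfg, caches, du, grads) {
  nl <- length(params$conv)
  sizes <- cfg$conv_channels
  offs <- cumsum(c(0L, sizes))
  dpool <- lapply(seq_len(nl), function(l) du[(offs[[l]] + 1L):offs[[l + 1L]]])
  dSeq <- NULL  # gradient w.r.t. the output sequence of the current layer
  for (l in nl:1) {
    ca <- caches[[l]]
    L <- nrow(ca$H)
    if (is.null(dSeq)) dSeq <- matrix(0, L, ncol(ca$H))
    # add the pooled path: route each channel's gradient to its argmax row
    dSeq[cbind(ca$argmax, seq_len(ncol(ca$H)))] <-
      dSeq[cbind(ca$argmax, seq_len(ncol(ca$H)))] + dpool[[l]]
    dpre <- dSeq * (ca$H > 0)
    grads$conv[[l]]$W <- grads$conv[[l]]$W + crossprod(ca$Xc, dpre)
    grads$conv[[l]]$b <- grads$conv[[l]]$b + colSums(dpre)
    dXc <- dpre %*% t(params$conv[[l]]$W)
    # un-im2col back onto the previous layer's output sequence
    if (l > 1L) {
      Cprev <- ncol(caches[[l - 1L]]$H)
      dSeq <- col2im(dXc, cfg$kernel_size, L, Cprev)
    }
  }
  grads
}

col2im <- function(dXc, k, L, C) {
  if (k == 1L) return(dXc)
  pad <- (k - 1L) %/% 2L
  dXp <- matrix(0, L + k - 1L, C)
  for (j in seq_len(k)) {
    dXp[j:(j + L - 1L), ] <- dXp[j:(j + L - 1L), ] +
      dXc[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dXp[(pad + 1L):(pad + L), , drop = FALSE]
}

#' Combine two sentence embeddings into pair features
#'
#' The standard supervised sentence-pair composition: concatenation of the
#' two embeddings, their elementwise absolute difference and their
#' elementwise product, `[u, v, |u - v|, u * v]`, length `4 * length(u)`.
#'
#' @param u,v Numeric sentence embeddings of equal length.
#' @return Numeric vector of length `4 * length(u)`.
#' @export
combine_features <- function(u, v) {
  if (length(u) != length(v)) stop("Embeddings have different lengths")
  c(u, v, abs(u - v), u * v)
}

softmax2 <- function(logits) {
  m <- max(logits)
  e <- exp(logits - m)
  e / sum(e)
}

# Full forward + backward for one pair; returns loss and accumulates grads.
pair_step <- function(params, cfg, Xi, Xj, y, grads, drop_mask = NULL) {
  fi <- encode_forward(params, cfg, Xi)
  fj <- encode_forward(params, cfg, Xj)
  u <- fi$u; v <- fj$u
  z <- combine_features(u, v)
  if (!is.null(drop_mask)) z <- z * drop_mask$z
  hpre <- drop(z %*% params$Wh) + params$bh
  h <- hpre * (hpre > 0)
  if (!is.null(drop_mask)) h <- h * drop_mask$h
  logits <- drop(h %*% params$Wo) + params$bo
  p <- softmax2(logits)
  loss <- -log(max(p[[y]], 1e-12))

  dlogits <- p
  dlogits[[y]] <- dlogits[[y]] - 1
  grads$Wo <- grads$Wo + outer(h, dlogits)
  grads$bo <- grads$bo + dlogits
  dh <- drop(params$Wo %*% dlogits)
  if (!is.null(drop_mask)) dh <- dh * drop_mask$h
  dhpre <- dh * (hpre > 0)
  grads$Wh <- grads$Wh + outer(z, dhpre)
  grads$bh <- grads$bh + dhpre
  dz <- drop(params$Wh %*% dhpre)
  if (!is.null(drop_mask)) dz <- dz * drop_mask$z
  S <- length(u)
  d1 <- dz[1:S]; d2 <- dz[(S + 1):(2 * S)]
  d3 <- dz[(2 * S + 1):(3 * S)]; d4 <- dz[(3 * S + 1):(4 * S)]
  sg <- sign(u - v)
  du <- d1 + sg * d3 + v * d4
  dv <- d2 - sg * d3 + u * d4
  grads <- encode_backward(params, cfg, fi$caches, du, grads)
  grads <- encode_backward(params, cfg, fj$caches, dv, grads)
  list(loss = loss, grads = grads)
}

zero_grads <- function(params) {
  g <- params
  g$conv <- lapply(params$conv, function(pl) {
    list(W = pl$W * 0, b = pl$b * 0)
  })
  g$Wh <- params$Wh * 0; g$bh <- params$bh * 0
  g$Wo <- params$Wo * 0; g$bo <- params$bo * 0
  g
}

# Flatten/unflatten parameter lists for the Adam update.
param_names <- function(params) {
  c(unlist(lapply(seq_along(params$conv), function(l) {
    paste0("conv", l, c("W", "b"))
  })), "Wh", "bh", "Wo", "bo")
}

get_param <- function(params, nm) {
  if (grepl("^conv", nm)) {
    l <- as.integer(sub("^conv([0-9]+)[Wb]$", "\\1", nm))
    params$conv[[l]][[substr(nm, nchar(nm), nchar(nm))]]
  } else params[[nm]]
}

set_param <- function(params, nm, value) {
  if (grepl("^conv", nm)) {
    l <- as.integer(sub("^conv([0-9]+)[Wb]$", "\\1", nm))
    params$conv[[l]][[substr(nm, nchar(nm), nchar(nm))]] <- value
  } else params[[nm]] <- value
  params
}

#' Fit the sentence-pair interaction model
#'
#' Trains the convolutional sentence-encoder pair classifier on labelled
#' protein pairs. Each protein is expanded into its GO-term sentence (see
#' [build_sentence()]); the two sentence embeddings are combined as
#' `[u, v, |u - v|, u * v]` and classified into positive / negative with a
#' softmax output, minimizing two-class cross-entropy with Adam. Training
#' is single-threaded and fully seeded: identical data + config give
#' identical parameters.
#'
#' @param pairs data.frame with `protein_a`, `protein_b`, `label` (0/1);
#'   both classes must be present.
#' @param pgaa A `pgaa` object annotating every protein in `pairs`.
#' @param vectors A `term_vectors` object.
#' @param config A [ppisent_config()]; its `embed_dim` must equal
#'   `vectors$dim`.
#' @param weighted Expand sentences with duplication weights? Defaults to
#'   the pgaa's own flag.
#' @param weight_cap Maximum token repetitions per term.
#' @return A fitted `ppisent` object with components `config`, `params`,
#'   `loss_history` (mean training loss per epoch), `classes`,
#'   `weighted`, `weight_cap` and `n_train`.
#' @seealso [predict.ppisent()], [encode_sentence()]
#' @export
ppisent <- function(pairs, pgaa, vectors,
                    config = ppisent_config(embed_dim = vectors$dim),
                    weighted = pgaa$weighted, weight_cap = 10L) {
  stopifnot(inherits(pgaa, "pgaa"), inherits(vectors, "term_vectors"),
            inherits(config, "ppisent_config"))
  if (config$embed_dim != vectors$dim) {
    stop("config$embed_dim (", config$embed_dim, ") != term-vector dim (",
         vectors$dim, ")")
  }
  if (!"label" %in% names(pairs)) stop("Training pairs must be labelled")
  if (nrow(pairs) < 2L) stop("Need at least 2 training pairs")
  if (length(unique(pairs$label)) < 2L) {
    stop("Training corpus contains a single class; need both")
  }

  sent <- build_sentence_table(pairs, pgaa, vectors, weighted = weighted,
                               weight_cap = weight_cap)
  Xa <- lapply(pairs$protein_a, function(p) sent[[p]]$matrix)
  Xb <- lapply(pairs$protein_b, function(p) sent[[p]]$matrix)
  y <- ifelse(pairs$label == 1L, 1L, 2L)  # output unit 1 = positive

  n <- nrow(pairs)
  cfg <- config
  loss_history <- numeric(cfg$epochs)

  params <- NULL
  with_seed(cfg$seed, {
    params <- init_params(cfg)
    nms <- param_names(params)
    m_state <- lapply(nms, function(nm) get_param(params, nm) * 0)
    v_state <- lapply(nms, function(nm) get_param(params, nm) * 0)
    names(m_state) <- nms; names(v_state) <- nms
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    tstep <- 0L
    S4 <- 4L * sum(cfg$conv_channels)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        grads <- zero_grads(params)
        bl <- 0
        for (i in idx) {
          dm <- NULL
          if (cfg$dropout > 0) {
            keep <- 1 - cfg$dropout
            dm <- list(z = (stats::runif(S4) < keep) / keep,
                       h = (stats::runif(cfg$hidden_dim) < keep) / keep)
          }
          st <- pair_step(params, cfg, Xa[[i]], Xb[[i]], y[[i]], grads, dm)
          grads <- st$grads
          bl <- bl + st$loss
        }
        ep_loss <- ep_loss + bl
        tstep <- tstep + 1L
        scale <- 1 / length(idx)
        for (nm in nms) {
          gmat <- get_param(grads, nm) * scale
          m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * gmat
          v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * gmat^2
          mhat <- m_state[[nm]] / (1 - beta1^tstep)
          vhat <- v_state[[nm]] / (1 - beta2^tstep)
          params <- set_param(params, nm,
                              get_param(params, nm) - cfg$lr * mhat / (sqrt(vhat) + eps))
        }
      }
      loss_history[[ep]] <- ep_loss / n
    }
  })

  structure(list(config = cfg, params = params, loss_history = loss_history,
                 classes = c("positive", "negative"), weighted = weighted,
                 weight_cap = as.integer(weight_cap), n_train = n),
            class = "ppisent")
}

#' Encode a protein sentence into its fixed-length embedding
#'
#' @param model A fitted `ppisent` object.
#' @param sentence A `protein_sentence` (see [build_sentence()]).
#' @return Numeric embedding of length `sum(conv_channels)`, independent
#'   of sentence length.
#' @export
encode_sentence <- function(model, sentence) {
  stopifnot(inherits(model, "ppisent"), inherits(sentence, "protein_sentence"))
  if (ncol(sentence$matrix) != model$config$embed_dim) {
    stop("Sentence matrix has ", ncol(sentence$matrix),
         " columns; model expects ", model$config$embed_dim)
  }
  encode_forward(model$params, model$config, sentence$matrix)$u
}

#' Predict interaction probabilities for protein pairs
#'
#' Scores each pair with the trained model. The decision rule is the
#' strict comparison `p_positive > p_negative` (a tie at exactly 0.5 is
#' called negative). With `symmetric = TRUE` the probabilities are
#' averaged over both argument orders.
#'
#' @param object A fitted `ppisent` model.
#' @param pairs data.frame with `protein_a`, `protein_b`.
#' @param pgaa,vectors Annotation axioms and term vectors covering the
#'   prediction proteins (may come from a different species than
#'   training).
#' @param symmetric Average scores over (i, j) and (j, i)?
#' @param ... Unused.
#' @return `pairs` with columns `p_positive`, `p_negative`, `label`
#'   (`"positive"`/`"negative"`) appended.
#' @export
predict.ppisent <- function(object, pairs, pgaa, vectors,
                            symmetric = FALSE, ...) {
  stopifnot(inherits(pgaa, "pgaa"), inherits(vectors, "term_vectors"))
  sent <- build_sentence_table(pairs, pgaa, vectors,
                               weighted = object$weighted,
                               weight_cap = object$weight_cap)
  emb <- lapply(sent, function(s) encode_forward(object$params, object$config,
                                                 s$matrix)$u)
  score_one <- function(u, v) {
    z <- combine_features(u, v)
    h <- drop(z %*% object$params$Wh) + object$params$bh
    h <- h * (h > 0)
    softmax2(drop(h %*% object$params$Wo) + object$params$bo)
  }
  probs <- vapply(seq_len(nrow(pairs)), function(i) {
    u <- emb[[pairs$protein_a[[i]]]]
    v <- emb[[pairs$protein_b[[i]]]]
    p <- score_one(u, v)
    if (symmetric) p <- (p + score_one(v, u)) / 2
    p
  }, numeric(2))
  out <- pairs
  out$p_positive <- probs[1, ]
  out$p_negative <- probs[2, ]
  out$label <- ifelse(out$p_positive > out$p_negative, "positive", "negative")
  out
}

#' @export
print.ppisent <- function(x, ...) {
  cfg <- x$config
  cat("Sentence-pair CNN interaction model (ppisent)\n")
  cat("  encoder: ", length(cfg$conv_channels), " conv layer(s), channels ",
      paste(cfg$conv_channels, collapse = "/"), ", kernel ", cfg$kernel_size,
      ", embedding dim ", sum(cfg$conv_channels), "\n", sep = "")
  cat("  trained on", x$n_train, "pairs,", cfg$epochs, "epochs, batch",
      cfg$batch_size, if (x$weighted) "(weighted sentences)" else "(unweighted sentences)", "\n")
  cat("  final training loss:", format(utils::tail(x$loss_history, 1), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.ppisent <- function(object, ...) {
  print(object)
  cat("  loss trajectory:", paste(format(object$loss_history[
    unique(round(seq(1, length(object$loss_history), length.out = 5)))],
    digits = 3), collapse = " -> "), "\n")
  invisible(object)
}

#' @export
coef.ppisent <- function(object, ...) object$params

#' Plot the training loss curve
#'
#' @param x A fitted `ppisent` model.
#' @param ... Passed to [plot()].
#' @export
plot.ppisent <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}

#' Save / load a fitted model as a JSON checkpoint
#'
#' The checkpoint stores the config and all weights as plain JSON at full
#' double precision.
#'
#' @param model A fitted `ppisent` model.
#' @param path Output path.
#' @export
save_ppisent <- function(model, path) {
  stopifnot(inherits(model, "ppisent"))
  ser <- list(
    config = unclass(model$config),
    weighted = model$weighted, weight_cap = model$weight_cap,
    n_train = model$n_train, loss_history = model$loss_history,
    params = list(
      conv = lapply(model$params$conv, function(pl) {
        list(W = as.vector(pl$W), W_nrow = nrow(pl$W), b = pl$b)
      }),
      Wh = as.vector(model$params$Wh), Wh_nrow = nrow(model$params$Wh),
      bh = model$params$bh,
      Wo = as.vector(model$params$Wo), Wo_nrow = nrow(model$params$Wo),
      bo = model$params$bo))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ppisent
#' @export
load_ppisent <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(ppisent_config, as.list(ser$config))
  remat <- function(v, nr) matrix(v, nrow = nr)
  conv <- lapply(seq_along(cfg$conv_channels), function(l) {
    pl <- if (is.data.frame(ser$params$conv)) {
      as.list(ser$params$conv[l, ])
    } else ser$params$conv[[l]]
    list(W = remat(unlist(pl$W), unlist(pl$W_nrow)), b = unlist(pl$b))
  })
  params <- list(conv = conv,
                 Wh = remat(ser$params$Wh, ser$params$Wh_nrow), bh = ser$params$bh,
                 Wo = remat(ser$params$Wo, ser$params$Wo_nrow), bo = ser$params$bo)
  structure(list(config = cfg, params = params,
                 loss_history = ser$loss_history,
                 classes = c("positive", "negative"),
                 weighted = ser$weighted, weight_cap = as.integer(ser$weight_cap),
                 n_train = ser$n_train),
            class = "ppisent")
}
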