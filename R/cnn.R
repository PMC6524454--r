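# Convolutional sentence classifier: embedding lookup, windowed convolution
# with ReLU activation, max-over-time pooling, a fully connected layer and a
# 2-class softmax. Forward and backward passes are written against the model
# equations directly (vectorized per sentence); embeddings are frozen by
# default. All randomness (init, shuffling, dropout) flows from one seed and
# execution is single-threaded, so training is bit-reproducible.

#' Construct an embedding table
#'
#' @param tokens Character vector of vocabulary tokens.
#' @param vectors Numeric matrix, one row per token, `d` columns.
#' @return A list of class `embedding_table` with `vocab` (token -> row
#'   index), `vectors` (including a zero out-of-vocabulary sentinel row
#'   `"<oov>"`), and `d`.
#' @export
embedding_table <- function(tokens, vectors) {
  vectors <- as.matrix(vectors)
  stopifnot(length(tokens) == nrow(vectors), ncol(vectors) > 0)
  if (anyDuplicated(tokens)) stop_fmt("duplicate tokens in embedding table")
  if (!"<oov>" %in% tokens) {
    tokens <- c(tokens, "<oov>")
    vectors <- rbind(vectors, 0)
  }
  dimnames(vectors) <- NULL
  structure(list(vocab = stats::setNames(seq_along(tokens), tokens),
                 vectors = vectors, d = ncol(vectors)),
            class = "embedding_table")
}

#' Read/write word vectors in the standard text format
#'
#' First line `"<V> <d>"`, then one token and `d` floats per line.
#'
#' @param path File path.
#' @param table An `embedding_table`.
#' @export
write_embedding_table <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  toks <- names(table$vocab)
  writeLines(sprintf("%d %d", length(toks), table$d), con)
  for (i in seq_along(toks)) {
    writeLines(paste(toks[[i]], paste(sprintf("%.17g", table$vectors[i, ]),
                                      collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[[1]], "\\s+")[[1]])
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  toks <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[[2]])))
  embedding_table(toks, vecs)
}

#' Embed a token sequence
#'
#' Row-wise embedding lookup; unknown tokens map to the out-of-vocabulary
#' sentinel row and sentences shorter than `pad_to` are padded with zero
#' rows so every convolution window size fits.
#'
#' @param tokens Non-empty character vector.
#' @param table An [embedding_table()].
#' @param pad_to Minimum number of rows (default 1 = no padding).
#' @return A list of class `embedded_sentence` with `tokens` and the
#'   `n x d` `matrix`.
#' @export
embed_sentence <- function(tokens, table, pad_to = 1L) {
  if (!length(tokens)) stop_fmt("cannot embed an empty token list")
  idx <- table$vocab[tokens]
  idx[is.na(idx)] <- table$vocab[["<oov>"]]
  mat <- table$vectors[idx, , drop = FALSE]
  if (nrow(mat) < pad_to) {
    mat <- rbind(mat, matrix(0, pad_to - nrow(mat), table$d))
  }
  rownames(mat) <- NULL
  structure(list(tokens = tokens, matrix = mat), class = "embedded_sentence")
}

#' Default CNN hyperparameters
#'
#' Window sizes \{3, 4, 5\} with 100 filters each, dropout 0.5 on the pooled
#' feature vector, 10 epochs of Adam at learning rate 1e-3 with batch size
#' 32 — the standard configuration for this architecture family. All values
#' can be overridden.
#'
#' @param windows Integer vector of convolution window sizes.
#' @param n_filters Filters per window size.
#' @param dropout Dropout probability on the pooled vector (training only).
#' @param epochs,batch_size,learning_rate Optimization settings.
#' @param fine_tune_embeddings If `TRUE`, embedding vectors receive
#'   gradients; frozen by default.
#' @return A named list.
#' @export
cnn_hyper <- function(windows = c(3L, 4L, 5L), n_filters = 100L, dropout = 0.5,
                      epochs = 10L, batch_size = 32L, learning_rate = 1e-3,
                      fine_tune_embeddings = FALSE) {
  list(windows = as.integer(windows), n_filters = as.integer(n_filters),
       dropout = dropout, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), learning_rate = learning_rate,
       fine_tune_embeddings = isTRUE(fine_tune_embeddings))
}

#' Initialize CNN parameters
#'
#' @param d Embedding dimensionality.
#' @param hyper Hyperparameters from [cnn_hyper()].
#' @param seed Integer seed.
#' @param zero If `TRUE`, all weights and biases start at zero (useful for
#'   analytic checks: symmetric logits give probabilities (0.5, 0.5)).
#' @return A list of class `cnn_parameters`: per-window weight matrices
#'   `W[[k]]` of shape `(k*d) x n_filters` and biases `b[[k]]`, output
#'   weights `Wout` of shape `(|windows|*n_filters) x 2` and bias `bout`.
#' @export
cnn_init <- function(d, hyper = cnn_hyper(), seed = 1L, zero = FALSE) {
  ks <- hyper$windows; nf <- hyper$n_filters
  params <- with_seed(seed, {
    W <- list(); b <- list()
    for (k in ks) {
      key <- as.character(k)
      if (zero) {
        W[[key]] <- matrix(0, k * d, nf)
      } else {
        sc <- sqrt(2 / (k * d + nf))
        W[[key]] <- matrix(rnorm(k * d * nf, sd = sc), k * d, nf)
      }
      b[[key]] <- numeric(nf)
    }
    pooled_len <- length(ks) * nf
    Wout <- if (zero) matrix(0, pooled_len, 2) else
      matrix(rnorm(pooled_len * 2, sd = sqrt(2 / (pooled_len + 2))), pooled_len, 2)
    list(W = W, b = b, Wout = Wout, bout = numeric(2))
  })
  params$d <- d; params$hyper <- hyper; params$seed <- as.integer(seed)
  class(params) <- "cnn_parameters"
  params
}

# Stack sliding windows of the n x d matrix X into an (n-k+1) x (k*d)
# matrix whose row i is the concatenation of rows i..i+k-1 of X.
window_matrix <- function(X, k) {
  n <- nrow(X); d <- ncol(X)
  nw <- n - k + 1L
  Y <- t(X) # d x n
  idx <- unlist(lapply(seq_len(nw), function(i) i:(i + k - 1L)))
  matrix(Y[, idx], nrow = nw, ncol = k * d, byrow = TRUE)
}

softmax <- function(o) {
  e <- exp(o - max(o))
  e / sum(e)
}

#' CNN forward pass
#'
#' For each window size `k` and filter, `con_i = ReLU(w_k . x_{i:i+k-1} +
#' b_k)` over all window positions, then max-over-time pooling `m_k = max_i
#' con_i`; the pooled features pass through the fully connected layer `O =
#' w m + b` and a softmax yields the class probabilities.
#'
#' @param embedded An [embed_sentence()] result (or a bare `n x d` matrix).
#' @param params [cnn_init()] parameters.
#' @param keep_cache If `TRUE`, intermediate quantities needed for the
#'   backward pass are attached.
#' @return Named probability vector `c(other = ..., target = ...)`; with
#'   `keep_cache`, a list with `probs` and `cache`.
#' @export
cnn_forward <- function(embedded, params, keep_cache = FALSE) {
  X <- if (inherits(embedded, "embedded_sentence")) embedded$matrix else as.matrix(embedded)
  if (ncol(X) != params$d) {
    stop_fmt("embedding dimensionality %d does not match model d=%d",
             ncol(X), params$d)
  }
  ks <- params$hyper$windows
  if (nrow(X) < max(ks)) {
    X <- rbind(X, matrix(0, max(ks) - nrow(X), ncol(X)))
  }
  pooled <- numeric(0)
  cache <- list(X = X, A = list(), Z = list(), argmax = list())
  for (k in ks) {
    key <- as.character(k)
    A <- window_matrix(X, k)
    Z <- sweep(A %*% params$W[[key]], 2, params$b[[key]], `+`)
    C <- pmax(Z, 0)
    am <- max.col(t(C), ties.method = "first") # argmax row per filter
    mk <- C[cbind(am, seq_len(ncol(C)))]
    pooled <- c(pooled, mk)
    if (keep_cache) {
      cache$A[[key]] <- A; cache$Z[[key]] <- Z; cache$argmax[[key]] <- am
    }
  }
  o <- drop(crossprod(params$Wout, pooled)) + params$bout
  p <- softmax(o)
  names(p) <- c("other", "target")
  if (!keep_cache) return(p)
  cache$pooled <- pooled
  list(probs = p, cache = cache)
}

# Backward pass for one sentence. dout = dL/dO (length 2). mask/keep apply
# inverted dropout to the pooled vector. Returns gradients mirroring the
# parameter layout (plus dX when fine-tuning embeddings).
cnn_backward <- function(params, cache, dout, mask = NULL, want_dX = FALSE) {
  ks <- params$hyper$windows; nf <- params$hyper$n_filters
  pooled_eff <- if (is.null(mask)) cache$pooled else cache$pooled * mask
  dWout <- outer(pooled_eff, dout)
  dbout <- dout
  dpooled <- drop(params$Wout %*% dout)
  if (!is.null(mask)) dpooled <- dpooled * mask
  grads <- list(W = list(), b = list(), Wout = dWout, bout = dbout)
  dX <- if (want_dX) matrix(0, nrow(cache$X), ncol(cache$X)) else NULL
  off <- 0L
  for (k in ks) {
    key <- as.character(k)
    dm <- dpooled[off + seq_len(nf)]; off <- off + nf
    Z <- cache$Z[[key]]; am <- cache$argmax[[key]]
    dZ <- matrix(0, nrow(Z), ncol(Z))
    sel <- cbind(am, seq_len(nf))
    relu_open <- Z[sel] > 0
    dZ[sel] <- dm * relu_open
    grads$W[[key]] <- crossprod(cache$A[[key]], dZ)
    grads$b[[key]] <- colSums(dZ)
    if (want_dX) {
      dA <- dZ %*% t(params$W[[key]]) # nw x (k*d)
      d <- ncol(cache$X)
      for (i in seq_len(nrow(dA))) {
        if (all(dA[i, ] == 0)) next
        blk <- matrix(dA[i, ], nrow = k, byrow = TRUE)
        rows <- i:(i + k - 1L)
        dX[rows, ] <- dX[rows, ] + blk
      }
    }
  }
  grads$dX <- dX
  grads
}

adam_state <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params[c("W", "b", "Wout", "bout")]),
       v = zero_like(params[c("W", "b", "Wout", "bout")]), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (key in names(params$W)) {
    r <- upd(params$W[[key]], grads$W[[key]], state$m$W[[key]], state$v$W[[key]])
    params$W[[key]] <- r$p; state$m$W[[key]] <- r$m; state$v$W[[key]] <- r$v
    r <- upd(params$b[[key]], grads$b[[key]], state$m$b[[key]], state$v$b[[key]])
    params$b[[key]] <- r$p; state$m$b[[key]] <- r$m; state$v$b[[key]] <- r$v
  }
  r <- upd(params$Wout, grads$Wout, state$m$Wout, state$v$Wout)
  params$Wout <- r$p; state$m$Wout <- r$m; state$v$Wout <- r$v
  r <- upd(params$bout, grads$bout, state$m$bout, state$v$bout)
  params$bout <- r$p; state$m$bout <- r$m; state$v$bout <- r$v
  list(params = params, state = state)
}

#' Train the CNN sentence classifier
#'
#' Minimizes cross-entropy with Adam over mini-batches; model selection
#' keeps the parameters with the best dev-set accuracy across epochs.
#' Identical seed and inputs reproduce the training trajectory exactly.
#'
#' @param train,dev Lists with elements `tokens` (list of token vectors)
#'   and `labels` (0/1 integer vector, 1 = target class).
#' @param table An [embedding_table()].
#' @param hyper Hyperparameters from [cnn_hyper()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch dev accuracy.
#' @return `cnn_parameters` with attributes `dev_accuracy` (per epoch) and
#'   `best_epoch`.
#' @export
train_cnn <- function(train, dev, table, hyper = cnn_hyper(), seed = 1L,
                      verbose = FALSE) {
  y <- as.integer(train$labels)
  if (length(unique(y)) < 2L) stop_fmt("training data must contain both classes")
  stopifnot(length(train$tokens) == length(y))
  pad <- max(hyper$windows)
  Xs <- lapply(train$tokens, function(t) embed_sentence(t, table, pad)$matrix)
  dev_Xs <- lapply(dev$tokens, function(t) embed_sentence(t, table, pad)$matrix)
  dev_y <- as.integer(dev$labels)
  keep <- 1 - hyper$dropout
  n <- length(Xs)
  pooled_len <- length(hyper$windows) * hyper$n_filters

  params <- cnn_init(table$d, hyper, seed = seed)
  state <- adam_state(params)
  best <- list(acc = -1, params = params, epoch = 0L)
  traj <- numeric(hyper$epochs)

  with_seed(seed + 1L, {
    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      for (bstart in seq(1L, n, by = hyper$batch_size)) {
        batch <- ord[bstart:min(bstart + hyper$batch_size - 1L, n)]
        acc_g <- NULL
        for (s in batch) {
          X <- if (hyper$fine_tune_embeddings) {
            embed_sentence(train$tokens[[s]], table, pad)$matrix
          } else Xs[[s]]
          fwd <- cnn_forward(X, params, keep_cache = TRUE)
          mask <- if (hyper$dropout > 0) {
            (runif(pooled_len) < keep) / keep
          } else NULL
          # recompute logits under the dropout mask actually applied
          pooled_eff <- if (is.null(mask)) fwd$cache$pooled else fwd$cache$pooled * mask
          o <- drop(crossprod(params$Wout, pooled_eff)) + params$bout
          p <- softmax(o)
          target <- c(1 - y[[s]], y[[s]])
          dout <- p - target
          g <- cnn_backward(params, fwd$cache, dout, mask = mask,
                            want_dX = hyper$fine_tune_embeddings)
          acc_g <- if (is.null(acc_g)) g else accumulate_grads(acc_g, g)
          if (hyper$fine_tune_embeddings && !is.null(g$dX)) {
            rows <- seq_len(min(length(train$tokens[[s]]), nrow(g$dX)))
            idx <- table$vocab[train$tokens[[s]][rows]]
            idx[is.na(idx)] <- table$vocab[["<oov>"]]
            lr_e <- hyper$learning_rate / length(batch)
            for (r in seq_along(rows)) {
              table$vectors[idx[[r]], ] <- table$vectors[idx[[r]], ] -
                lr_e * g$dX[rows[[r]], ]
            }
          }
        }
        acc_g <- scale_grads(acc_g, 1 / length(batch))
        st <- adam_step(params, acc_g, state, hyper$learning_rate)
        params <- st$params; state <- st$state
      }
      if (hyper$fine_tune_embeddings) {
        dev_Xs <- lapply(dev$tokens, function(t) embed_sentence(t, table, pad)$matrix)
      }
      preds <- vapply(dev_Xs, function(X) {
        unname(cnn_forward(X, params)[["target"]] >= 0.5)
      }, TRUE)
      acc <- mean(as.integer(preds) == dev_y)
      traj[[epoch]] <- acc
      if (verbose) message(sprintf("epoch %d: dev accuracy %.3f", epoch, acc))
      if (acc > best$acc) best <- list(acc = acc, params = params, epoch = epoch)
    }
  })
  out <- best$params
  attr(out, "dev_accuracy") <- traj
  attr(out, "best_epoch") <- best$epoch
  if (hyper$fine_tune_embeddings) attr(out, "embedding_table") <- table
  out
}

accumulate_grads <- function(a, g) {
  for (key in names(a$W)) {
    a$W[[key]] <- a$W[[key]] + g$W[[key]]
    a$b[[key]] <- a$b[[key]] + g$b[[key]]
  }
  a$Wout <- a$Wout + g$Wout; a$bout <- a$bout + g$bout
  a
}

scale_grads <- function(g, s) {
  for (key in names(g$W)) {
    g$W[[key]] <- g$W[[key]] * s; g$b[[key]] <- g$b[[key]] * s
  }
  g$Wout <- g$Wout * s; g$bout <- g$bout * s
  g
}

#' Sentence-level target-class probabilities
#'
#' @param model A trained `cnn_parameters` or `baseline_model`.
#' @param tokens_list List of token vectors.
#' @param table The [embedding_table()] used in training.
#' @param ... Passed to methods.
#' @return Numeric vector of positive-class probabilities.
#' @export
sentence_probs <- function(model, tokens_list, table, ...) {
  UseMethod("sentence_probs")
}

#' @export
sentence_probs.cnn_parameters <- function(model, tokens_list, table, ...) {
  pad <- max(model$hyper$windows)
  vapply(tokens_list, function(t) {
    unname(cnn_forward(embed_sentence(t, table, pad), model)[["target"]])
  }, 0)
}

#' Aggregate sentence predictions into a document label
#'
#' A document is labeled positive when any of its sentences has
#' target-class probability at or above `tau_pos` (max aggregation);
#' otherwise negative. The sentence classifier is binary, so the
#' indeterminate label is never produced on this path.
#'
#' @param model A trained sentence classifier.
#' @param sentences_tokens List of token vectors, one per sentence of the
#'   report.
#' @param table The [embedding_table()] used in training.
#' @param tau_pos Decision threshold (default 0.5).
#' @return `"positive"` or `"negative"`.
#' @export
classify_document <- function(model, sentences_tokens, table, tau_pos = 0.5) {
  if (!length(sentences_tokens)) return("negative")
  p <- sentence_probs(model, sentences_tokens, table)
  if (max(p) >= tau_pos) "positive" else "negative"
}
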