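# Traditional sentence classifiers over word-vector representations:
# L2-regularized logistic regression (via glmnet), a linear SVM trained by
# Pegasos-style subgradient descent, and a CART random forest (compiled).
# Sentences become fixed-length inputs by mean-pooling their embedding rows
# (default) or by bag-of-words counts over the training vocabulary.

#' Featurize a sentence
#'
#' `mean_pool` averages the embedding rows of the tokens (out-of-vocabulary
#' tokens use the sentinel row), so a one-token sentence maps to that
#' token's embedding and token order is irrelevant. `bow` counts tokens over
#' a fixed vocabulary.
#'
#' @param tokens Non-empty character vector.
#' @param table An [embedding_table()] (`mean_pool` mode).
#' @param mode `"mean_pool"` or `"bow"`.
#' @param vocab Character vector of vocabulary tokens (`bow` mode).
#' @return A numeric feature vector.
#' @export
featurize <- function(tokens, table = NULL, mode = c("mean_pool", "bow"),
                      vocab = NULL) {
  mode <- match.arg(mode)
  if (!length(tokens)) stop_fmt("cannot featurize an empty token list")
  if (mode == "mean_pool") {
    stopifnot(inherits(table, "embedding_table"))
    colMeans(embed_sentence(tokens, table)$matrix)
  } else {
    if (is.null(vocab)) stop_fmt("bow mode requires a vocabulary")
    tab <- table(factor(tokens, levels = vocab))
    as.numeric(tab)
  }
}

#' Featurize a list of sentences into a matrix
#'
#' @param tokens_list List of token vectors.
#' @inheritParams featurize
#' @return A numeric matrix, one row per sentence.
#' @export
featurize_matrix <- function(tokens_list, table = NULL,
                             mode = c("mean_pool", "bow"), vocab = NULL) {
  mode <- match.arg(mode)
  t(vapply(tokens_list, featurize, table = table, mode = mode, vocab = vocab,
           FUN.VALUE = numeric(if (mode == "mean_pool") table$d else length(vocab))))
}

#' Train a traditional baseline classifier
#'
#' @param kind `"logreg"` (ridge logistic regression, C = 1), `"svm"`
#'   (linear soft-margin SVM, C = 1, Pegasos subgradient descent with
#'   weight averaging) or `"rf"` (random forest, 500 trees,
#'   `mtry = floor(sqrt(p))`).
#' @param features Numeric feature matrix (rows = sentences).
#' @param labels 0/1 integer vector.
#' @param seed Integer seed; identical seeds give identical models.
#' @param cost Soft-margin / inverse-regularization constant C.
#' @param ntree,mtry Random-forest settings.
#' @param mode,vocab Featurization metadata stored on the model so
#'   [sentence_probs()] can featurize new sentences consistently.
#' @return A list of class `baseline_model`.
#' @export
train_baseline <- function(kind = c("logreg", "svm", "rf"), features, labels,
                           seed = 1L, cost = 1, ntree = 500L, mtry = NULL,
                           mode = "mean_pool", vocab = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop_fmt("training data must contain both classes")
  n <- nrow(X)
  fit <- switch(kind,
    logreg = {
      lam <- 1 / (n * cost)
      glmnet::glmnet(X, factor(y, levels = 0:1), family = "binomial",
                     alpha = 0, lambda = lam, standardize = FALSE)
    },
    svm = svm_pegasos(X, y, cost = cost, seed = seed),
    rf = {
      m <- mtry %||% max(1L, floor(sqrt(ncol(X))))
      rf_fit_cpp(X, y, as.integer(ntree), as.integer(m), 5L, as.integer(seed))
    }
  )
  structure(list(kind = kind, fit = fit, p = ncol(X), mode = mode,
                 vocab = vocab, seed = as.integer(seed)),
            class = "baseline_model")
}

# Pegasos: minimizes lambda/2 ||w||^2 + mean hinge loss, lambda = 1/(n*C).
# The bias is carried as an augmented constant feature (so it is lightly
# regularized too) and the returned solution averages the iterates of the
# second half of training for stability.
svm_pegasos <- function(X, y, cost = 1, epochs = 50L, seed = 1L) {
  Xa <- cbind(X, 1)
  n <- nrow(Xa); p <- ncol(Xa)
  lambda <- 1 / (n * cost)
  ys <- ifelse(y == 1L, 1, -1)
  w <- numeric(p)
  w_avg <- numeric(p); navg <- 0L
  with_seed(seed, {
    t <- 0L
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1L
        eta <- 1 / (lambda * (t + n)) # shifted schedule avoids huge first steps
        margin <- ys[[i]] * sum(w * Xa[i, ])
        w <- (1 - eta * lambda) * w
        if (margin < 1) w <- w + eta * ys[[i]] * Xa[i, ]
        if (ep > epochs / 2) {
          w_avg <- w_avg + w; navg <- navg + 1L
        }
      }
    }
  })
  w_avg <- w_avg / navg
  list(w = w_avg[-p], b = w_avg[[p]], lambda = lambda)
}

#' Predict positive-class scores from a baseline model
#'
#' @param model A `baseline_model`.
#' @param features Feature matrix in the layout used at training time.
#' @return Positive-class probabilities (logreg, rf) or a logistic squash
#'   of the decision margin (svm), in `[0, 1]`.
#' @export
predict_baseline <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != model$p) stop_fmt("feature width %d != training width %d",
                                   ncol(X), model$p)
  switch(model$kind,
    logreg = as.numeric(predict(model$fit, newx = X, type = "response")),
    svm = plogis(as.numeric(X %*% model$fit$w + model$fit$b)),
    rf = as.numeric(rf_predict_cpp(model$fit, X))
  )
}

#' @export
sentence_probs.baseline_model <- function(model, tokens_list, table, ...) {
  X <- featurize_matrix(tokens_list, table = table, mode = model$mode,
                        vocab = model$vocab)
  predict_baseline(model, X)
}
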