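# Pointwise mutual information between n-grams and document labels.
# Used to prototype and audit the concept lexicons: terms with high PMI
# against a label are candidate keywords for expert curation.

#' Tokenize text for statistical modules
#'
#' Lower-cases and splits on non-alphanumeric characters. Shared by the PMI,
#' embedding and classifier modules so vocabularies line up.
#'
#' @param text Character vector.
#' @return A list of character vectors of tokens.
#' @export
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

ngrams_of <- function(tokens, ngram_max) {
  out <- character(0)
  for (k in seq_len(ngram_max)) {
    if (length(tokens) < k) break
    idx <- seq_len(length(tokens) - k + 1L)
    out <- c(out, vapply(idx, function(i) {
      paste(tokens[i:(i + k - 1L)], collapse = " ")
    }, ""))
  }
  unique(out)
}

#' PMI ranking of n-grams against labels
#'
#' Computes base-2 pointwise mutual information between n-gram presence and
#' sentence label over a labeled sentence collection:
#' `pmi = log2( p(ngram, label) / (p(ngram) * p(label)) )`,
#' with counts taken at the sentence level (an n-gram counts once per
#' sentence). With `smooth = "laplace"` (the default) one pseudo-count is
#' added to each cell of the per-pair 2x2 contingency table so that n-grams
#' never co-occurring with a label score a finite negative value rather than
#' `-Inf`; `smooth = "none"` uses raw counts.
#'
#' @param tokens A list of token vectors (one per sentence), e.g. from
#'   [tokenize()].
#' @param labels Character vector of sentence labels (>= 2 distinct values).
#' @param ngram_max Longest n-gram to score (default 3).
#' @param min_count Minimum number of sentences an n-gram must occur in.
#' @param smooth `"laplace"` or `"none"`.
#' @return A `data.frame` with columns `ngram`, `label`, `pmi`,
#'   `count_joint`, `count_token`, `count_label`, `n_total`, sorted within
#'   label by decreasing PMI, ties broken lexicographically.
#' @export
compute_pmi <- function(tokens, labels, ngram_max = 3L, min_count = 1L,
                        smooth = c("laplace", "none")) {
  smooth <- match.arg(smooth)
  stopifnot(length(tokens) == length(labels), min_count >= 1L)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop_fmt("compute_pmi needs at least 2 distinct labels, got %d",
             length(unique(labels)))
  }
  n <- length(tokens)
  grams <- lapply(tokens, ngrams_of, ngram_max = ngram_max)
  token_count <- table(unlist(grams))
  keep <- names(token_count)[token_count >= min_count]
  label_count <- table(labels)

  rows <- list()
  for (lab in sort(names(label_count))) {
    in_lab <- labels == lab
    joint <- table(unlist(grams[in_lab]))
    for (g in keep) {
      cj <- if (g %in% names(joint)) as.integer(joint[[g]]) else 0L
      ct <- as.integer(token_count[[g]])
      cl <- as.integer(label_count[[lab]])
      if (smooth == "laplace") {
        # add one to every cell of the 2x2 (ngram x label) table
        a <- cj + 1L; b <- (ct - cj) + 1L; cc <- (cl - cj) + 1L
        d <- (n - ct - cl + cj) + 1L
        nn <- a + b + cc + d
        pmi <- log2((a * nn) / ((a + b) * (a + cc)))
      } else {
        pmi <- if (cj == 0L) -Inf else log2((cj * n) / (ct * cl))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ngram = g, label = lab, pmi = pmi, count_joint = cj,
        count_token = ct, count_label = cl, n_total = n,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$label, -res$pmi, res$ngram), , drop = FALSE]
  rownames(res) <- NULL
  res
}
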