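# Shared fixtures: all built in code, no files on disk.

# Small deterministic embedding table over a toy vocabulary.
tiny_table <- function(d = 8L, vocab = c("aaa", "bbb", "ccc", "ddd", "sig"),
                       seed = 1L) {
  build_embedding_table(list(vocab), d = d, mode = "seeded_random", seed = seed)
}

# Linearly separable sentence data: positives contain the `signal` token.
separable_sentences <- function(n_pos, n_neg, len = 6L,
                                vocab = c("aaa", "bbb", "ccc", "ddd"),
                                signal = "sig", seed = 1L) {
  set.seed(seed)
  mk <- function(n, pos) lapply(seq_len(n), function(i) {
    s <- sample(vocab, len, replace = TRUE)
    if (pos) s[[sample.int(len, 1L)]] <- signal
    s
  })
  list(tokens = c(mk(n_pos, TRUE), mk(n_neg, FALSE)),
       labels = c(rep(1L, n_pos), rep(0L, n_neg)))
}

# Minimal well-formed report data.frame.
toy_reports <- function(texts, site = "site_b", scan = "mri") {
  data.frame(report_id = sprintf("r%03d", seq_along(texts)), site = site,
             scan_type = scan, text = texts, stringsAsFactors = FALSE)
}

write_jsonl <- function(lines, path) writeLines(lines, path, useBytes = TRUE)
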