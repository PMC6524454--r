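test_that("generation is byte-identical under a fixed seed", {
  c1 <- generate_corpus(generator_config(n_reports = 40, seed = 123))
  c2 <- generate_corpus(generator_config(n_reports = 40, seed = 123))
  expect_identical(c1$reports, c2$reports)
  expect_identical(c1$gold, c2$gold)
  expect_identical(c1$sentences, c2$sentences)
  c3 <- generate_corpus(generator_config(n_reports = 40, seed = 124))
  expect_false(identical(c1$reports$text, c3$reports$text))
})

test_that("realized prevalences sit within binomial sampling error", {
  corp <- generate_corpus(generator_config(n_reports = 1000, seed = 6))
  sbi_carrier <- mean(corp$gold$sbi != "negative")
  wmd_carrier <- mean(corp$gold$wmd != "negative")
  expect_lt(abs(sbi_carrier - 0.12), 0.03) # 3 sigma ~ 0.031
  expect_lt(abs(wmd_carrier - 0.60), 0.05)
  expect_setequal(unique(corp$reports$site), c("site_a", "site_b"))
})

test_that("gold labels are consistent with the rule-engine semantics", {
  corp <- generate_corpus(generator_config(n_reports = 150, coreference_rate = 0,
                                           seed = 31))
  pred <- classify_corpus(corp$reports)
  # with no coreference splits every positive document carries a sentence
  # the engine qualifies, so agreement is complete by construction
  expect_equal(mean(pred$sbi == corp$gold$sbi), 1.0)
  expect_equal(mean(pred$wmd == corp$gold$wmd), 1.0)
})

test_that("coreference-split positives defeat the single-sentence engine", {
  corp <- generate_corpus(generator_config(n_reports = 300, coreference_rate = 1,
                                           hedge_rate = 0, seed = 41))
  pred <- classify_corpus(corp$reports)
  pos <- corp$gold$sbi == "positive"
  expect_gt(sum(pos), 10)
  # every definite positive is expressed as a split pair: engine recall 0
  expect_true(all(pred$sbi[pos] == "negative"))
  # engine sensitivity strictly decreases as the coreference rate rises
  sens_at <- function(rate) {
    corp <- generate_corpus(generator_config(n_reports = 400,
                                             coreference_rate = rate,
                                             hedge_rate = 0, seed = 52))
    pred <- classify_corpus(corp$reports)
    g <- binarize_labels(corp$gold$sbi)
    p <- binarize_labels(pred$sbi)
    confusion_metrics(g, p)$sensitivity
  }
  expect_gt(sens_at(0), sens_at(0.5))
})

test_that("location-only confounder reports never fool the rule engine", {
  corp <- generate_corpus(generator_config(n_reports = 200, confounder_rate = 1,
                                           coreference_rate = 0, seed = 61))
  has_conf <- tapply(corp$sentences$template == "confounder",
                     corp$sentences$report_id, any)
  pred <- classify_corpus(corp$reports)
  neg_ids <- corp$gold$report_id[corp$gold$sbi == "negative"]
  conf_neg <- intersect(names(which(has_conf)), neg_ids)
  expect_gt(length(conf_neg), 50)
  expect_true(all(pred$sbi[match(conf_neg, pred$report_id)] == "negative"))
})

test_that("negation phrasing pools honour the site richness contrast", {
  corp <- generate_corpus(generator_config(n_reports = 2000, seed = 71))
  neg_sents <- corp$sentences[grepl("^neg_infarct", corp$sentences$template), ]
  site <- corp$reports$site[match(neg_sents$report_id, corp$reports$report_id)]
  n_a <- length(unique(neg_sents$text[site == "site_a"]))
  n_b <- length(unique(neg_sents$text[site == "site_b"]))
  expect_lte(n_b, 12L)
  expect_gt(n_a, 100L)   # draws from a 212-phrase pool
  expect_lte(n_a, 212L)
})

test_that("seeded-random embeddings are deterministic, unit-norm, covering", {
  corp <- generate_corpus(generator_config(n_reports = 30, seed = 81))
  toks <- tokenize(corp$sentences$text)
  t1 <- build_embedding_table(toks, d = 16, mode = "seeded_random", seed = 4)
  t2 <- build_embedding_table(toks, d = 16, mode = "seeded_random", seed = 4)
  expect_identical(t1$vectors, t2$vectors)
  expect_true(all(unique(unlist(toks)) %in% names(t1$vocab)))
  norms <- sqrt(rowSums(t1$vectors^2))
  expect_equal(unname(norms[-length(norms)]), rep(1, nrow(t1$vectors) - 1L),
               tolerance = 1e-12) # all but the OOV row
  # vectors depend on the token, not on vocabulary order
  t3 <- build_embedding_table(rev(toks), d = 16, mode = "seeded_random", seed = 4)
  expect_equal(t3$vectors[t3$vocab[["infarct"]], ],
               t1$vectors[t1$vocab[["infarct"]], ])
})

test_that("skip-gram embeddings place co-templated finding terms together", {
  finding_terms <- c("infarcts", "infarction", "infarctions", "lacune", "lacunes")
  hits <- 0L
  for (s in 1:5) {
    corp <- generate_corpus(generator_config(n_reports = 150, seed = 300 + s))
    toks <- tokenize(corp$sentences$text)
    tab <- build_embedding_table(toks, d = 30, mode = "skipgram", seed = s)
    cand <- setdiff(names(tab$vocab), c("infarct", "<oov>"))
    v <- tab$vectors[tab$vocab[["infarct"]], ]
    sims <- vapply(cand, function(tok) {
      u <- tab$vectors[tab$vocab[[tok]], ]
      sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    }, 0)
    nn <- names(which.max(sims))
    if (nn %in% c(finding_terms, "lacunar")) hits <- hits + 1L
  }
  # chance level would be ~6 / |vocab| (~130); require a clear majority
  expect_gte(hits, 3L)
})

test_that("oversampling balances by duplication without fabrication", {
  data <- list(tokens = c(lapply(1:10, function(i) c("pos", as.character(i))),
                          lapply(1:90, function(i) c("neg", as.character(i)))),
               labels = c(rep(1L, 10), rep(0L, 90)))
  over <- oversample(data, target_ratio = 0.5, seed = 3)
  expect_equal(sum(over$labels == 1L), 90L)
  expect_equal(sum(over$labels == 0L), 90L)
  # conservation: everything added is a duplicate of an input positive
  key <- vapply(over$tokens, paste, "", collapse = " ")
  orig <- vapply(data$tokens, paste, "", collapse = " ")
  expect_true(all(key %in% orig))
  expect_true(all(orig %in% key))

  # no-op when the target is already met
  expect_identical(oversample(data, target_ratio = 0.1, seed = 3), data)
  expect_identical(oversample(over, target_ratio = 0.5, seed = 3), over)

  o1 <- oversample(data, 0.4, seed = 9)
  o2 <- oversample(data, 0.4, seed = 9)
  expect_identical(o1, o2)
  expect_gte(mean(o1$labels == 1L), 0.4)

  expect_error(oversample(list(tokens = data$tokens[1:5],
                               labels = rep(1L, 5)), 0.5), "both classes")
  expect_error(oversample(data, 0), "target_ratio")
})

test_that("a template-site-trained CNN generalizes worse to the free-form site", {
  accA <- accB <- numeric(5)
  for (s in 1:5) {
    corp <- generate_corpus(generator_config(n_reports = 500,
                                             coreference_rate = 0,
                                             seed = 200 + s))
    toks <- tokenize(corp$sentences$text)
    tab <- build_embedding_table(toks, d = 50, mode = "skipgram", seed = s)
    site <- corp$reports$site[match(corp$sentences$report_id,
                                    corp$reports$report_id)]
    ib <- which(site == "site_b"); ia <- which(site == "site_a")
    set.seed(s)
    trb <- sample(ib, floor(length(ib) * 0.6))
    rest <- setdiff(ib, trb)
    dvb <- sample(rest, floor(length(rest) / 2)); teb <- setdiff(rest, dvb)
    fit <- train_cnn(list(tokens = toks[trb], labels = corp$sentences$sbi[trb]),
                     list(tokens = toks[dvb], labels = corp$sentences$sbi[dvb]),
                     tab, cnn_hyper(n_filters = 50L), seed = s)
    accB[s] <- mean((sentence_probs(fit, toks[teb], tab) >= 0.5) ==
                      (corp$sentences$sbi[teb] == 1))
    accA[s] <- mean((sentence_probs(fit, toks[ia], tab) >= 0.5) ==
                      (corp$sentences$sbi[ia] == 1))
  }
  # directional, seed-averaged: held-out template-site accuracy is at least
  # as high as free-form-site accuracy
  expect_gte(mean(accB), mean(accA))
})
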