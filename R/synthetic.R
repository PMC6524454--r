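# Synthetic neuroimaging-report generator. Emulates the structural
# properties the analyses assume — two documentation styles (a free-form
# site with hundreds of distinct negative-infarct phrasings vs a
# template-based site with a dozen), low SBI prevalence vs ~60% WMD
# prevalence, hedged / negated / historical mentions, location-only
# confounder sentences, and coreference-split findings that no single
# sentence expresses — together with gold document labels, per-sentence
# binary truth, a stand-in embedding table and an oversampling utility.

fill_frame <- function(frame, slots) {
  for (nm in names(slots)) {
    frame <- gsub(paste0("{", nm, "}"), slots[[nm]], frame, fixed = TRUE)
  }
  frame
}

#' Generator grammar
#'
#' The editable template grammar (cue pools, anatomy pools, sentence
#' frames) behind [generate_corpus()]. The free-form site's negative
#' -infarct phrasing pool is built compositionally as
#' cue x finding-phrase x tail, so the "hundreds of distinct expressions at
#' one site vs a dozen at the other" contrast is generated, not hand-listed.
#'
#' @param path Optional path to a JSON grammar; defaults to the packaged one.
#' @return A named list of string pools.
#' @export
default_grammar <- function(path = NULL) {
  path <- path %||% system.file("extdata", "generator_grammar.json",
                                package = "sbifinder")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Synthetic corpus configuration
#'
#' Defaults state the emulated world: SBI prevalence 0.12 (an explicit
#' stand-in for "a small number of positive cases"; configurable), WMD
#' prevalence 0.60, half of reports from each site, 212 distinct
#' negative-infarction phrasings at the free-form site versus 12 at the
#' template site, and modest rates of hedged, historical, confounder and
#' coreference-split content.
#'
#' @param n_reports Number of reports.
#' @param sbi_prevalence,wmd_prevalence Probability a report carries the
#'   finding (hedged carriers get gold label indeterminate).
#' @param site_a_fraction Fraction of reports from the free-form site.
#' @param richness_site_a,richness_site_b Sizes of the negative-infarct
#'   phrasing pools per site.
#' @param hedge_rate Probability that a carrier finding is hedged.
#' @param historical_rate Probability a non-carrier report mentions a
#'   historical (known/prior) infarct.
#' @param confounder_rate Probability a report contains a location-only
#'   confounder sentence.
#' @param coreference_rate Probability a definite SBI-positive report is
#'   expressed as a coreference-split pair that no single sentence
#'   qualifies.
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_reports = 1000L, sbi_prevalence = 0.12,
                             wmd_prevalence = 0.60, site_a_fraction = 0.5,
                             richness_site_a = 212L, richness_site_b = 12L,
                             hedge_rate = 0.08, historical_rate = 0.10,
                             confounder_rate = 0.15, coreference_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_reports = as.integer(n_reports),
              sbi_prevalence = sbi_prevalence, wmd_prevalence = wmd_prevalence,
              site_a_fraction = site_a_fraction,
              richness_site_a = as.integer(richness_site_a),
              richness_site_b = as.integer(richness_site_b),
              hedge_rate = hedge_rate, historical_rate = historical_rate,
              confounder_rate = confounder_rate,
              coreference_rate = coreference_rate, seed = as.integer(seed))
  rates <- c("sbi_prevalence", "wmd_prevalence", "site_a_fraction",
             "hedge_rate", "historical_rate", "confounder_rate",
             "coreference_rate")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop_fmt("%s must be in [0, 1]", r)
  }
  if (cfg$n_reports < 1L) stop_fmt("n_reports must be >= 1")
  if (cfg$richness_site_a < 1L || cfg$richness_site_b < 1L) {
    stop_fmt("phrasing richness must be >= 1")
  }
  class(cfg) <- "generator_config"
  cfg
}

# Deterministic compositional pool of negative-infarct phrasings.
negation_pool <- function(grammar, size) {
  combos <- expand.grid(tail = grammar$neg_tails, find = grammar$neg_findings,
                        cue = grammar$neg_cues, stringsAsFactors = FALSE)
  phr <- trimws(paste(combos$cue, combos$find, combos$tail))
  phr <- paste0(phr, ".")
  phr <- unique(phr)
  if (size > length(phr)) {
    stop_fmt("requested richness %d exceeds compositional pool size %d",
             size, length(phr))
  }
  phr[seq_len(size)]
}

#' Generate a synthetic labeled corpus
#'
#' Deterministic under the config seed. Returns reports, gold 3-way
#' document labels, per-sentence binary truth for SBI and WMD, and the
#' provenance (template) of every sentence. Positive findings are built
#' from the concept lexicon's own vocabulary so the rule engine can (by
#' construction) recover every non-coreference-split positive; hedged
#' carriers get gold label indeterminate; location-only confounder
#' sentences and historical mentions never make a report positive.
#'
#' @param config A [generator_config()].
#' @param grammar A grammar from [default_grammar()].
#' @return A list of class `synthetic_corpus` with elements `reports`,
#'   `gold` (both in the canonical corpus_io layouts), `sentences`
#'   (`report_id`, `index`, `text`, `sbi`, `wmd`, `template`) and `config`.
#' @export
generate_corpus <- function(config = generator_config(),
                            grammar = default_grammar()) {
  stopifnot(inherits(config, "generator_config"))
  pool_a <- negation_pool(grammar, config$richness_site_a)
  pool_b <- if (config$richness_site_b <= length(grammar$neg_templates_site_b)) {
    grammar$neg_templates_site_b[seq_len(config$richness_site_b)]
  } else {
    unique(c(grammar$neg_templates_site_b,
             negation_pool(grammar, 252)))[seq_len(config$richness_site_b)]
  }

  with_seed(config$seed, {
    n <- config$n_reports
    bundles <- lapply(seq_len(n), function(i) {
      rid <- sprintf("synth-%05d", i)
      site <- if (runif(1) < config$site_a_fraction) "site_a" else "site_b"
      scan <- if (runif(1) < 0.5) "ct" else "mri"
      sbi_carrier <- runif(1) < config$sbi_prevalence
      sbi_hedged <- sbi_carrier && runif(1) < config$hedge_rate
      sbi_coref <- sbi_carrier && !sbi_hedged && runif(1) < config$coreference_rate
      wmd_carrier <- runif(1) < config$wmd_prevalence
      wmd_hedged <- wmd_carrier && runif(1) < config$hedge_rate

      pick <- function(x) x[[sample.int(length(x), 1L)]]
      sent <- list()
      add <- function(text, sbi = 0L, wmd = 0L, template = "") {
        sent[[length(sent) + 1L]] <<- list(text = text, sbi = sbi, wmd = wmd,
                                           template = template)
      }

      # negative-acute-infarction statement: present in every report, drawn
      # from the site's phrasing pool (the documentation-style contrast)
      neg_pool <- if (site == "site_a") pool_a else pool_b
      add(pick(neg_pool), template = paste0("neg_infarct_", site))

      anat <- pick(grammar$anatomy)
      if (sbi_carrier && sbi_hedged) {
        mod <- pick(grammar$chronic_modifiers)
        add(fill_frame(pick(grammar$sbi_hedged_frames),
                       list(modl = tolower(mod), find = pick(grammar$sbi_findings),
                            anat = anat)),
            sbi = 0L, template = "sbi_hedged")
      } else if (sbi_carrier && sbi_coref) {
        pair_i <- sample.int(nrow(grammar$coref_pairs) %||% length(grammar$coref_pairs), 1L)
        pair <- if (is.matrix(grammar$coref_pairs)) grammar$coref_pairs[pair_i, ]
                else grammar$coref_pairs[[pair_i]]
        add(fill_frame(pair[[1]], list(anat = anat)), sbi = 1L,
            template = "sbi_coref_antecedent")
        add(fill_frame(pair[[2]], list(anat = anat)), sbi = 1L,
            template = "sbi_coref_anaphor")
      } else if (sbi_carrier) {
        mod <- pick(grammar$chronic_modifiers)
        add(fill_frame(pick(grammar$sbi_positive_frames),
                       list(mod = mod, modl = tolower(mod),
                            find = pick(grammar$sbi_findings), anat = anat)),
            sbi = 1L, template = "sbi_positive")
      } else if (runif(1) < config$historical_rate) {
        add(fill_frame(pick(grammar$historical_templates), list(anat = anat)),
            template = "sbi_historical")
      }

      if (wmd_carrier) {
        sev <- pick(grammar$wmd_severity)
        frames <- if (wmd_hedged) grammar$wmd_hedged_frames else
          grammar$wmd_positive_frames
        add(fill_frame(pick(frames),
                       list(sev = sev, sevl = tolower(sev),
                            wfind = pick(grammar$wmd_findings))),
            wmd = if (wmd_hedged) 0L else 1L,
            template = if (wmd_hedged) "wmd_hedged" else "wmd_positive")
      } else if (runif(1) < 0.6) {
        add(pick(grammar$wmd_negative_templates), template = "wmd_negative")
      }

      if (runif(1) < config$confounder_rate) {
        aa <- sample(grammar$confounder_anatomy, 3L)
        add(fill_frame(pick(grammar$confounder_frames),
                       list(a1 = aa[[1]], a2 = aa[[2]], a3 = aa[[3]])),
            template = "confounder")
      }

      n_fill <- sample.int(2L, 1L)
      for (f in sample(grammar$fillers, n_fill)) add(f, template = "filler")

      texts <- vapply(sent, `[[`, "", "text")
      # free-form site: shuffled narrative flow; template site: fixed
      # skeleton with FINDINGS / IMPRESSION headers
      if (site == "site_a") {
        ord <- c(1L, if (length(texts) > 1L) 1L + sample.int(length(texts) - 1L))
        sent <- sent[ord]
        texts <- texts[ord]
        body <- paste(texts, collapse = " ")
        text <- sprintf("%s head %s: %s. %s", toupper(scan),
                        if (scan == "ct") "without contrast" else "protocol",
                        pick(grammar$indications), body)
      } else {
        text <- paste(c(sprintf("EXAM: %s BRAIN", toupper(scan)),
                        sprintf("CLINICAL HISTORY: %s.", pick(grammar$indications)),
                        "FINDINGS:", texts, "IMPRESSION:",
                        if (sbi_carrier && !sbi_hedged && !sbi_coref)
                          "Chronic infarct as described above."
                        else "No acute intracranial process."),
                      collapse = "\n")
        if (sbi_carrier && !sbi_hedged && !sbi_coref) {
          sent[[length(sent) + 1L]] <- list(text = "Chronic infarct as described above.",
                                            sbi = 1L, wmd = 0L,
                                            template = "impression_sbi")
        } else {
          sent[[length(sent) + 1L]] <- list(text = "No acute intracranial process.",
                                            sbi = 0L, wmd = 0L,
                                            template = "impression_negative")
        }
      }

      sbi_gold <- if (!sbi_carrier) "negative" else
        if (sbi_hedged) "indeterminate" else "positive"
      wmd_gold <- if (!wmd_carrier) "negative" else
        if (wmd_hedged) "indeterminate" else "positive"

      list(report = data.frame(report_id = rid, site = site, scan_type = scan,
                               text = text, stringsAsFactors = FALSE),
           gold = data.frame(report_id = rid, sbi = sbi_gold, wmd = wmd_gold,
                             annotator = NA_character_, stringsAsFactors = FALSE),
           sentences = data.frame(
             report_id = rid, index = seq_along(sent) - 1L,
             text = vapply(sent, `[[`, "", "text"),
             sbi = vapply(sent, function(s) as.integer(s$sbi), 0L),
             wmd = vapply(sent, function(s) as.integer(s$wmd), 0L),
             template = vapply(sent, `[[`, "", "template"),
             stringsAsFactors = FALSE))
    })
    out <- list(
      reports = do.call(rbind, lapply(bundles, `[[`, "report")),
      gold = do.call(rbind, lapply(bundles, `[[`, "gold")),
      sentences = do.call(rbind, lapply(bundles, `[[`, "sentences")),
      config = config
    )
    out$reports$text <- normalize_report_text(out$reports$text)
    class(out) <- "synthetic_corpus"
    out
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d reports, %d sentences (seed %d)\n",
              nrow(x$reports), nrow(x$sentences), x$config$seed))
  cat(sprintf("  gold SBI: %s\n",
              paste(names(table(x$gold$sbi)), table(x$gold$sbi),
                    sep = "=", collapse = " ")))
  cat(sprintf("  gold WMD: %s\n",
              paste(names(table(x$gold$wmd)), table(x$gold$wmd),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Build a stand-in embedding table
#'
#' The restricted clinical skip-gram table is not distributable, so a
#' stand-in is built from the synthetic corpus itself: either a skip-gram
#' model with negative sampling trained on the token stream
#' (`mode = "skipgram"`), or deterministic per-token unit-norm random
#' vectors (`mode = "seeded_random"`, independent of vocabulary order).
#' Both cover the full corpus vocabulary.
#'
#' @param tokens_list List of token vectors (e.g. `tokenize()` of report
#'   sentences).
#' @param d Embedding dimensionality (default 100).
#' @param mode `"skipgram"` or `"seeded_random"`.
#' @param seed Integer seed.
#' @param window,negative,epochs,lr Skip-gram settings.
#' @return An [embedding_table()].
#' @export
build_embedding_table <- function(tokens_list, d = 100L,
                                  mode = c("skipgram", "seeded_random"),
                                  seed = 1L, window = 5L, negative = 5L,
                                  epochs = 5L, lr = 0.05) {
  mode <- match.arg(mode)
  toks <- unlist(tokens_list)
  if (!length(toks)) stop_fmt("empty corpus")
  if (d < 2) stop_fmt("d must be >= 2")
  vocab <- sort(unique(toks))
  if (mode == "seeded_random") {
    vecs <- t(vapply(vocab, function(tok) {
      v <- with_seed(hash_string(tok, seed), rnorm(d))
      v / sqrt(sum(v^2))
    }, numeric(d)))
    return(embedding_table(vocab, vecs))
  }
  ids <- lapply(tokens_list, function(t) match(t, vocab) - 1L)
  stream <- unlist(lapply(ids, function(x) c(x, -1L)))
  vecs <- sgns_train_cpp(as.integer(stream), length(vocab), as.integer(d),
                         as.integer(window), as.integer(negative),
                         as.integer(epochs), lr, as.integer(seed))
  embedding_table(vocab, vecs)
}

#' Oversample the minority class
#'
#' Duplicates minority-class sentences (sampling with replacement under the
#' seed) until the minority fraction reaches `target_ratio`. Original items
#' are never removed and nothing new is fabricated; if the minority
#' fraction already meets the target the input is returned unchanged.
#'
#' @param data A list with `tokens` (list) and `labels` (0/1 vector).
#' @param target_ratio Desired minority fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return A list in the same layout with duplicates appended.
#' @export
oversample <- function(data, target_ratio = 0.5, seed = 1L) {
  if (target_ratio <= 0 || target_ratio > 1) {
    stop_fmt("target_ratio must be in (0, 1]")
  }
  y <- as.integer(data$labels)
  if (length(unique(y)) < 2L) stop_fmt("need both classes to oversample")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (n_min / (n_min + n_maj) >= target_ratio) return(data)
  n_add <- ceiling((target_ratio * n_maj - (1 - target_ratio) * n_min) /
                     (1 - target_ratio))
  idx_min <- which(y == minority)
  extra <- with_seed(seed, sample(idx_min, n_add, replace = TRUE))
  list(tokens = c(data$tokens, data$tokens[extra]),
       labels = c(y, y[extra]))
}
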