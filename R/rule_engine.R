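# Rule-based information extraction for SBI/WMD: sentence segmentation,
# section detection, lexicon-driven concept matching, contextual attribute
# assignment (status / temporality / experiencer / chronicity) and heuristic
# document-level summarization. All character offsets are 0-based half-open
# into the normalized report (or sentence) text.

# Tokens before a period that never terminate a sentence.
.abbrev <- c("vs", "dr", "mr", "mrs", "ms", "e.g", "i.e", "etc", "al",
             "approx", "fig", "cf", "st", "no")

.scope_terminators <- c("\\bbut\\b", "\\bhowever\\b", ";")

regex_escape <- function(x) gsub("([.\\\\|()\\[\\]{^$*+?}-])", "\\\\\\1", x, perl = TRUE)

surface_pattern <- function(surface) {
  paste0("(?i)\\b", gsub("\\s+", "\\\\s+", regex_escape(surface)), "\\b")
}

#' Split report text into sentences
#'
#' Abbreviation-safe sentence segmentation. Splits at `.`, `!`, `?` followed
#' by whitespace (or end of text) and at newlines, but not after common
#' abbreviations (`vs.`, `e.g.`), single-letter initials, or enumerator
#' tokens such as the `1.` of a numbered list item. Concatenating the
#' returned spans together with the gaps between them reconstructs the text.
#'
#' @param text Report text (non-empty).
#' @return A `data.frame` with columns `index` (0-based sentence index),
#'   `start`, `end` (0-based half-open character offsets into `text`) and
#'   `text` (the trimmed sentence string).
#' @export
segment_sentences <- function(text) {
  if (!nzchar(trimws(text))) stop_fmt("cannot segment empty text")
  nc <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  cuts <- integer(0) # cut AFTER this 1-based position
  term_pos <- which(chars %in% c(".", "!", "?"))
  for (p in term_pos) {
    nxt <- if (p < nc) chars[[p + 1]] else ""
    if (nzchar(nxt) && !grepl("[ \t\n]", nxt)) next # decimal or mid-token dot
    if (chars[[p]] == ".") {
      prefix <- substr(text, 1, p - 1)
      word <- regmatches(prefix, regexpr("[A-Za-z0-9.]+$", prefix))
      if (length(word)) {
        w <- tolower(sub("\\.+$", "", word))
        if (w %in% .abbrev || grepl("^[0-9]+$", w) || grepl("^[a-z]$", w)) next
      }
    }
    cuts <- c(cuts, p)
  }
  cuts <- sort(unique(c(cuts, which(chars == "\n"))))
  bounds <- c(0L, cuts, nc)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[[i]] + 1L # 1-based segment start
    hi <- bounds[[i + 1L]]
    if (hi < lo) next
    seg <- substr(text, lo, hi)
    if (!nzchar(trimws(seg))) next
    lead <- nchar(sub("^(\\s*).*$", "\\1", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    start0 <- lo - 1L + lead              # 0-based
    end0 <- hi - trail                    # half-open
    out[[length(out) + 1L]] <- data.frame(
      start = start0, end = end0,
      text = substr(text, start0 + 1L, end0), stringsAsFactors = FALSE
    )
  }
  sents <- do.call(rbind, out)
  sents <- sents[order(sents$start), , drop = FALSE]
  sents$index <- seq_len(nrow(sents)) - 1L
  rownames(sents) <- NULL
  sents[, c("index", "start", "end", "text")]
}

#' Assign section labels to sentences
#'
#' A sentence beginning (at the start of a line) with a `FINDINGS` or
#' `IMPRESSION` header switches the current section from that sentence
#' onward; all sentences before any header are `other`. A header token
#' embedded mid-sentence ("see impression above") does not switch sections.
#'
#' @param sentences Output of [segment_sentences()].
#' @param text The report text the sentences were segmented from.
#' @return `sentences` with an added `section` column
#'   (`"findings"`/`"impression"`/`"other"`).
#' @export
detect_sections <- function(sentences, text) {
  current <- "other"
  section <- character(nrow(sentences))
  for (i in seq_len(nrow(sentences))) {
    st <- sentences$start[[i]]
    prefix <- substr(text, 1, st)
    at_line_start <- st == 0L || grepl("(^|\n)[ \t]*$", prefix)
    if (at_line_start) {
      head_tok <- tolower(sub("^([A-Za-z]+).*$", "\\1", sentences$text[[i]]))
      if (head_tok %in% c("findings", "finding")) current <- "findings"
      if (head_tok %in% c("impression", "impressions")) current <- "impression"
    }
    section[[i]] <- current
  }
  sentences$section <- section
  sentences
}

#' Default concept lexicon
#'
#' The shipped lexicon of SBI finding / modifier / location terms and WMD
#' finding / exclusion terms used by the rule engine. Modifiers are
#' partitioned into acute (`acute`, `acute or subacute`, `recent`, `new`)
#' and chronic (`remote`, `old`, `chronic`, `prior`, `chronic foci of`,
#' `benign`, `stable small`, `stable`) sets: a silent infarct is by
#' definition non-acute, so only chronic or unmodified findings can make a
#' document SBI-positive.
#'
#' @param path Optional path to a TSV with columns `surface`, `category`,
#'   `concept`; defaults to the packaged lexicon.
#' @return A `data.frame` with columns `surface`, `category`, `concept`,
#'   `pattern` (a compiled case-insensitive regular expression).
#' @export
default_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "box1_lexicon.tsv", package = "sbifinder")
  read_lexicon(path)
}

#' @rdname default_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("surface", "category", "concept") %in% names(lex)))
  if (any(!nzchar(lex$surface))) stop_fmt("lexicon contains an empty surface form")
  lex$pattern <- vapply(lex$surface, surface_pattern, "")
  lex
}

#' Default context cue inventory
#'
#' Cue words and phrases that set contextual attributes of a concept
#' mention: negation and hedging (status), historical and hypothetical
#' framing (temporality), and non-patient experiencers. Cues apply to
#' mentions they precede within the same sentence, with scope terminated by
#' `but`, `however` or a semicolon.
#'
#' @param path Optional path to a TSV with columns `cue`, `attribute`,
#'   `value`, `direction`; defaults to the packaged inventory.
#' @return A `data.frame` with a compiled `pattern` column added.
#' @export
default_cues <- function(path = NULL) {
  path <- path %||% system.file("extdata", "context_cues.tsv", package = "sbifinder")
  cues <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("cue", "attribute", "value", "direction") %in% names(cues)))
  cues$pattern <- vapply(cues$cue, surface_pattern, "")
  cues
}

all_matches <- function(stext, pattern) {
  m <- gregexpr(pattern, stext, perl = TRUE)[[1]]
  if (m[[1]] == -1L) return(NULL)
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Match lexicon concepts in a sentence
#'
#' Case-insensitive, word-boundary-anchored regular-expression matching of
#' every lexicon surface form against a sentence. Overlapping candidates of
#' the same category are resolved longest-match-first, then leftmost. A WMD
#' exclusion match (e.g. "degenerative changes") suppresses any WMD finding
#' match that overlaps or directly abuts it, so "white matter degenerative
#' changes" yields no WMD finding.
#'
#' @param sentence_text A sentence string.
#' @param lexicon A lexicon `data.frame` from [default_lexicon()].
#' @return A `data.frame` of mentions with columns `start`, `end` (0-based
#'   half-open offsets into the sentence), `surface`, `matched_text`,
#'   `category`, `concept`.
#' @export
match_concepts <- function(sentence_text, lexicon = default_lexicon()) {
  cand <- list()
  for (j in seq_len(nrow(lexicon))) {
    hits <- all_matches(sentence_text, lexicon$pattern[[j]])
    if (is.null(hits)) next
    hits$surface <- lexicon$surface[[j]]
    hits$category <- lexicon$category[[j]]
    hits$concept <- lexicon$concept[[j]]
    cand[[length(cand) + 1L]] <- hits
  }
  empty <- data.frame(start = integer(), end = integer(), surface = character(),
                      matched_text = character(), category = character(),
                      concept = character(), stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # longest-match-wins, then leftmost, within each category
  kept <- list()
  for (cat in unique(cand$category)) {
    cc <- cand[cand$category == cat, , drop = FALSE]
    cc <- cc[order(-(cc$end - cc$start), cc$start), , drop = FALSE]
    acc <- cc[0, , drop = FALSE]
    for (i in seq_len(nrow(cc))) {
      ov <- nrow(acc) > 0 && any(cc$start[[i]] < acc$end & acc$start < cc$end[[i]])
      if (!ov) acc <- rbind(acc, cc[i, , drop = FALSE])
    }
    kept[[cat]] <- acc
  }
  res <- do.call(rbind, kept)
  # exclusion suppression: drop WMD findings overlapping/abutting an exclusion
  excl <- res[res$category == "WMD_EXCLUSION", , drop = FALSE]
  if (nrow(excl)) {
    drop <- logical(nrow(res))
    for (i in which(res$category == "WMD_FINDING")) {
      for (e in seq_len(nrow(excl))) {
        overlaps <- res$start[[i]] < excl$end[[e]] && excl$start[[e]] < res$end[[i]]
        gap <- if (res$end[[i]] <= excl$start[[e]]) {
          substr(sentence_text, res$end[[i]] + 1L, excl$start[[e]])
        } else if (excl$end[[e]] <= res$start[[i]]) {
          substr(sentence_text, excl$end[[e]] + 1L, res$start[[i]])
        } else ""
        adjacent <- !overlaps && grepl("^\\s*$", gap)
        if (overlaps || adjacent) { drop[[i]] <- TRUE; break }
      }
    }
    res <- res[!drop, , drop = FALSE]
  }
  res <- res[order(res$start, res$end), , drop = FALSE]
  res$matched_text <- substr(rep(sentence_text, nrow(res)), res$start + 1L, res$end)
  rownames(res) <- NULL
  res[, c("start", "end", "surface", "matched_text", "category", "concept")]
}

#' Assign contextual attributes to mentions
#'
#' Cue-and-scope context detection: a cue sets its attribute on every
#' mention it precedes in the sentence unless a scope terminator (`but`,
#' `however`, `;`) intervenes. Negation outranks hedging. Chronicity of an
#' SBI finding is taken from the nearest SBI modifier mention in the same
#' sentence. Defaults are `confirmed` / `present` / `patient` /
#' `unspecified`.
#'
#' @param mentions Output of [match_concepts()] for one sentence.
#' @param sentence_text The sentence the mentions were matched in.
#' @param cues Cue inventory from [default_cues()].
#' @return `mentions` with added columns `status`, `temporality`,
#'   `experiencer`, `chronicity`.
#' @export
assign_context <- function(mentions, sentence_text, cues = default_cues()) {
  n <- nrow(mentions)
  mentions$status <- rep("confirmed", n)
  mentions$temporality <- rep("present", n)
  mentions$experiencer <- rep("patient", n)
  mentions$chronicity <- rep("unspecified", n)
  if (!n) return(mentions)

  cue_hits <- list()
  for (j in seq_len(nrow(cues))) {
    hits <- all_matches(sentence_text, cues$pattern[[j]])
    if (is.null(hits)) next
    hits$attribute <- cues$attribute[[j]]
    hits$value <- cues$value[[j]]
    cue_hits[[length(cue_hits) + 1L]] <- hits
  }
  cue_hits <- if (length(cue_hits)) do.call(rbind, cue_hits) else NULL
  term_hits <- do.call(rbind, lapply(.scope_terminators, function(p) {
    all_matches(sentence_text, p)
  }))

  in_scope <- function(cue_end, m_start) {
    if (cue_end > m_start) return(FALSE)
    if (is.null(term_hits)) return(TRUE)
    !any(term_hits$start >= cue_end & term_hits$end <= m_start)
  }

  mods <- mentions[mentions$category %in%
                     c("SBI_MODIFIER_ACUTE", "SBI_MODIFIER_CHRONIC"), , drop = FALSE]
  for (i in seq_len(n)) {
    ms <- mentions$start[[i]]
    if (!is.null(cue_hits)) {
      live <- vapply(seq_len(nrow(cue_hits)), function(k) {
        in_scope(cue_hits$end[[k]], ms)
      }, TRUE)
      act <- cue_hits[live, , drop = FALSE]
      vals <- function(attr) act$value[act$attribute == attr]
      sv <- vals("status")
      if ("negated" %in% sv) mentions$status[[i]] <- "negated"
      else if ("probable" %in% sv) mentions$status[[i]] <- "probable"
      tv <- vals("temporality")
      if ("hypothetical" %in% tv) mentions$temporality[[i]] <- "hypothetical"
      else if ("historical" %in% tv) mentions$temporality[[i]] <- "historical"
      if ("other" %in% vals("experiencer")) mentions$experiencer[[i]] <- "other"
    }
    if (mentions$category[[i]] == "SBI_FINDING" && nrow(mods)) {
      mid <- (mentions$start[[i]] + mentions$end[[i]]) / 2
      d <- abs((mods$start + mods$end) / 2 - mid)
      nearest <- mods$category[[which.min(d)]]
      mentions$chronicity[[i]] <-
        if (nearest == "SBI_MODIFIER_ACUTE") "acute" else "chronic"
    }
  }
  mentions
}

qualifies_sbi <- function(m) {
  m$category == "SBI_FINDING" & m$experiencer == "patient" &
    m$temporality == "present" & m$chronicity %in% c("chronic", "unspecified")
}

qualifies_wmd <- function(m) {
  m$category == "WMD_FINDING" & m$experiencer == "patient" &
    m$temporality == "present"
}

#' Summarize mentions into a document classification
#'
#' Precedence ladder per concept: a confirmed qualifying mention makes the
#' document positive; otherwise a hedged (probable) qualifying mention makes
#' it indeterminate; otherwise negative. An SBI finding qualifies when it is
#' the patient's, present (not historical/hypothetical), and chronic or of
#' unspecified chronicity — acute-only infarcts are not silent infarcts. WMD
#' findings qualify under the same ladder without a chronicity constraint.
#'
#' @param mentions Context-resolved mentions of one report (rows from
#'   [assign_context()], any number of sentences).
#' @return A list with `sbi`, `wmd` (3-way labels) and `evidence` (the
#'   mention rows that determined each non-negative label).
#' @export
summarize_document <- function(mentions) {
  lab <- function(qual) {
    if (!nrow(mentions)) return(list(label = "negative", ev = mentions))
    q <- qual(mentions)
    pos <- q & mentions$status == "confirmed"
    ind <- q & mentions$status == "probable"
    if (any(pos)) list(label = "positive", ev = mentions[pos, , drop = FALSE])
    else if (any(ind)) list(label = "indeterminate", ev = mentions[ind, , drop = FALSE])
    else list(label = "negative", ev = mentions[0, , drop = FALSE])
  }
  s <- lab(qualifies_sbi)
  w <- lab(qualifies_wmd)
  list(sbi = s$label, wmd = w$label,
       evidence = list(sbi = s$ev, wmd = w$ev))
}

#' Classify one report with the rule engine
#'
#' Full pipeline: sentence segmentation, section detection, concept
#' matching, context assignment, document summarization. Deterministic.
#'
#' @param report A one-row report `data.frame` or a list with `report_id`
#'   and `text`.
#' @param lexicon,cues Lexicon and cue inventories.
#' @param impression_only If `TRUE`, only mentions in the IMPRESSION section
#'   contribute evidence.
#' @return An object of class `document_classification`: a list with
#'   `report_id`, `sbi`, `wmd`, `evidence`, `mentions`, `sentences`.
#' @export
classify_report <- function(report, lexicon = default_lexicon(),
                            cues = default_cues(), impression_only = FALSE) {
  text <- if (is.data.frame(report)) report$text[[1]] else report$text
  rid <- if (is.data.frame(report)) report$report_id[[1]] else report$report_id %||% NA_character_
  sents <- detect_sections(segment_sentences(text), text)
  all_m <- list()
  for (i in seq_len(nrow(sents))) {
    m <- match_concepts(sents$text[[i]], lexicon)
    if (!nrow(m)) next
    m <- assign_context(m, sents$text[[i]], cues)
    m$sentence_index <- sents$index[[i]]
    m$section <- sents$section[[i]]
    all_m[[length(all_m) + 1L]] <- m
  }
  mentions <- if (length(all_m)) do.call(rbind, all_m) else {
    cbind(match_concepts("", lexicon),
          data.frame(status = character(), temporality = character(),
                     experiencer = character(), chronicity = character(),
                     sentence_index = integer(), section = character()))
  }
  scope <- if (impression_only && nrow(mentions)) {
    mentions[mentions$section == "impression", , drop = FALSE]
  } else mentions
  summ <- summarize_document(scope)
  structure(list(report_id = rid, sbi = summ$sbi, wmd = summ$wmd,
                 evidence = summ$evidence, mentions = mentions,
                 sentences = sents),
            class = "document_classification")
}

#' Classify a corpus with the rule engine
#'
#' @param reports Report `data.frame` from [read_reports()].
#' @inheritParams classify_report
#' @return A `data.frame` with columns `report_id`, `sbi`, `wmd`.
#' @export
classify_corpus <- function(reports, lexicon = default_lexicon(),
                            cues = default_cues(), impression_only = FALSE) {
  out <- lapply(seq_len(nrow(reports)), function(i) {
    cl <- classify_report(reports[i, ], lexicon, cues, impression_only)
    data.frame(report_id = cl$report_id, sbi = cl$sbi, wmd = cl$wmd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.document_classification <- function(x, ...) {
  cat(sprintf("<document_classification> %s\n  SBI: %s   WMD: %s\n",
              x$report_id, x$sbi, x$wmd))
  cat(sprintf("  %d sentence(s), %d concept mention(s)\n",
              nrow(x$sentences), nrow(x$mentions)))
  invisible(x)
}
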