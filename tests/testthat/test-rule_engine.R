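worked_example <- "probable right old frontal lobe subcortical infarct as described above"
confounder_sentence <- paste(
  "there are a bilateral intraparenchymal foci of susceptibility artifact in",
  "the right occipital lobe, right parietal lobe, right subinsular region and",
  "left frontal region")

test_that("sentence segmentation is abbreviation- and enumerator-safe", {
  s <- segment_sentences("No acute infarct. Chronic lacune in left basal ganglia.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text[[1]], "No acute infarct.")

  s <- segment_sentences("a single sentence with no terminal period")
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 0L)
  expect_equal(s$end, nchar("a single sentence with no terminal period"))

  # the enumerator "1." must not create an empty sentence
  s <- segment_sentences("IMPRESSION: 1. No acute infarct.")
  expect_equal(nrow(s), 1L)
  expect_true(all(nzchar(trimws(s$text))))

  s <- segment_sentences("stable vs. slightly smaller lacune. No acute infarct.")
  expect_equal(nrow(s), 2L)
})

test_that("sentence spans reproduce the text they index", {
  corp <- generate_corpus(generator_config(n_reports = 25, seed = 11))
  for (text in corp$reports$text) {
    s <- segment_sentences(text)
    expect_true(all(s$start < s$end))
    expect_true(all(diff(s$start) > 0))
    # non-overlap and exact slicing
    expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
    for (i in seq_len(nrow(s))) {
      expect_identical(substr(text, s$start[[i]] + 1L, s$end[[i]]), s$text[[i]])
    }
  }
})

test_that("section detection is line-anchored", {
  txt <- "Preamble text here.\nFINDINGS:\nNo acute infarct.\nIMPRESSION:\nNormal study."
  s <- detect_sections(segment_sentences(txt), txt)
  expect_equal(s$section, c("other", "findings", "findings", "impression", "impression"))

  txt2 <- "No acute infarct. Please see impression above for details."
  s2 <- detect_sections(segment_sentences(txt2), txt2)
  expect_true(all(s2$section == "other"))

  txt3 <- "Plain report with no headers. Second sentence."
  s3 <- detect_sections(segment_sentences(txt3), txt3)
  expect_true(all(s3$section == "other"))
})

test_that("default lexicon carries the full term inventory", {
  lex <- default_lexicon()
  lookup <- function(s) lex$category[lex$surface == s]
  expect_equal(lookup("lacunes"), "SBI_FINDING")
  expect_equal(lookup("degenerative changes"), "WMD_EXCLUSION")
  expect_length(lookup("stroke"), 0L)
  expect_equal(sum(lex$category == "SBI_FINDING"), 6L)
  expect_setequal(lex$surface[lex$category == "SBI_MODIFIER_ACUTE"],
                  c("acute", "acute or subacute", "recent", "new"))
  expect_setequal(lex$surface[lex$category == "WMD_FINDING"],
                  c("leukoaraiosis", "white matter", "microvascular ischemic",
                    "microvascular leukemic", "microvascular degenerative"))
})

test_that("concept matching: worked example, longest match, exclusions", {
  m <- match_concepts(worked_example)
  expect_equal(m$surface[m$category == "SBI_FINDING"], "infarct")
  expect_equal(m$surface[m$category == "SBI_MODIFIER_CHRONIC"], "old")
  expect_equal(m$surface[m$category == "SBI_LOCATION"], "frontal")

  m <- match_concepts(confounder_sentence)
  expect_equal(sum(m$category == "SBI_FINDING"), 0L)
  expect_gt(sum(m$category == "SBI_LOCATION"), 0L)

  # longest-match-wins: "infarction" never yields its substring "infarct"
  m <- match_concepts("Remote infarction in the pons.")
  expect_equal(m$surface[m$category == "SBI_FINDING"], "infarction")

  expect_equal(sum(match_concepts("white matter degenerative changes")$category ==
                     "WMD_FINDING"), 0L)
  expect_equal(sum(match_concepts("microvascular degenerative changes")$category ==
                     "WMD_FINDING"), 0L)
  # a non-abutting exclusion does not suppress
  m <- match_concepts("white matter disease and cervical degenerative changes")
  expect_equal(sum(m$category == "WMD_FINDING"), 1L)
})

test_that("mention spans reproduce lexicon surfaces", {
  corp <- generate_corpus(generator_config(n_reports = 30, seed = 3))
  lex <- default_lexicon()
  for (st in head(corp$sentences$text, 120)) {
    m <- match_concepts(st, lex)
    for (i in seq_len(nrow(m))) {
      got <- tolower(gsub("\\s+", " ", m$matched_text[[i]]))
      expect_identical(got, m$surface[[i]])
    }
  }
})

test_that("context assignment follows cue-and-scope rules", {
  m <- assign_context(match_concepts(worked_example), worked_example)
  f <- m[m$category == "SBI_FINDING", ]
  expect_equal(f$status, "probable")
  expect_equal(f$temporality, "present")
  expect_equal(f$experiencer, "patient")
  expect_equal(f$chronicity, "chronic")

  s <- "No acute infarct."
  f <- assign_context(match_concepts(s), s)
  f <- f[f$category == "SBI_FINDING", ]
  expect_equal(f$status, "negated")
  expect_equal(f$chronicity, "acute")

  # "but" terminates negation scope: the lacune stays confirmed
  s <- "No acute infarct, but chronic lacune in the left basal ganglia."
  m <- assign_context(match_concepts(s), s)
  lac <- m[m$surface == "lacune", ]
  expect_equal(lac$status, "confirmed")
  expect_equal(lac$chronicity, "chronic")
  inf <- m[m$surface == "infarct", ]
  expect_equal(inf$status, "negated")

  s <- "History of remote infarction on prior imaging."
  m <- assign_context(match_concepts(s), s)
  expect_equal(m$temporality[m$category == "SBI_FINDING"], "historical")

  s <- "Family history of stroke; chronic infarct in the pons."
  m <- assign_context(match_concepts(s), s)
  # the semicolon terminates the family-history scope
  expect_equal(m$experiencer[m$category == "SBI_FINDING"], "patient")
})

test_that("document summarization applies the precedence ladder", {
  classify_text <- function(text) {
    classify_report(list(report_id = "t", text = text))
  }
  cl <- classify_text(paste0(worked_example, "."))
  expect_equal(cl$sbi, "indeterminate")

  cl <- classify_text("No acute infarction.")
  expect_equal(cl$sbi, "negative")
  expect_equal(cl$wmd, "negative")

  cl <- classify_text(paste(
    "Chronic lacunar infarct, left basal ganglia.",
    "Moderate white matter microvascular ischemic changes."))
  expect_equal(cl$sbi, "positive")
  expect_equal(cl$wmd, "positive")

  # acute-only, historical-only and other-experiencer mentions stay negative
  expect_equal(classify_text("Acute infarct in the left thalamus.")$sbi, "negative")
  expect_equal(classify_text("History of remote infarction.")$sbi, "negative")
  expect_equal(classify_text("Mother with old infarct.")$sbi, "negative")
})

test_that("positive and indeterminate labels always carry sound evidence", {
  corp <- generate_corpus(generator_config(n_reports = 60, seed = 13))
  for (i in seq_len(nrow(corp$reports))) {
    cl <- classify_report(corp$reports[i, ])
    for (concept in c("sbi", "wmd")) {
      lab <- cl[[concept]]
      ev <- cl$evidence[[concept]]
      if (lab %in% c("positive", "indeterminate")) {
        expect_gt(nrow(ev), 0L)
        expect_true(all(ev$experiencer == "patient"))
        expect_true(all(ev$temporality == "present"))
        expect_true(all(ev$status == if (lab == "positive") "confirmed" else "probable"))
        if (concept == "sbi") {
          expect_true(all(ev$chronicity %in% c("chronic", "unspecified")))
        }
      }
    }
  }
})

test_that("label monotonicity under appended sentences", {
  corp <- generate_corpus(generator_config(n_reports = 40, seed = 21))
  pred <- classify_corpus(corp$reports)
  neg <- which(pred$sbi == "negative")
  for (i in head(neg, 10)) {
    r <- corp$reports[i, ]
    r$text <- paste(r$text, "Chronic infarct in the left basal ganglia.")
    expect_equal(classify_report(r)$sbi, "positive")
  }
  # pure location sentences never change any label
  for (i in head(seq_len(nrow(corp$reports)), 15)) {
    r <- corp$reports[i, ]
    r$text <- paste(r$text, "Focus of artifact in the left frontal region and cerebellar hemisphere.")
    cl <- classify_report(r)
    expect_equal(cl$sbi, pred$sbi[[i]])
    expect_equal(cl$wmd, pred$wmd[[i]])
  }
})

test_that("coreference-split findings are a pinned false negative", {
  box_text <- paste(
    "Scattered, nonspecific T2 foci, most prominently in the left parietal",
    "white matter where there is an associated region of nonenhancing",
    "encephalomalacia and linear hemosiderin disposition. Linear hemosiderin",
    "deposition overlying the right temporal lobe (series 9, image 16) as",
    "well. No abnormal enhancement today. The above findings are nonspecific",
    "but the evolution, hemosiderin deposition, and gliosis suggest post",
    "ischemic change.")
  cl <- classify_report(list(report_id = "box2", text = box_text))
  # truly SBI-positive, but no sentence holds both the finding and its
  # ischemic attribution: the engine (which does not resolve coreference)
  # must label it negative. Documented expected failure.
  expect_equal(cl$sbi, "negative")
})

test_that("classify_report is deterministic and honours empty lexicons", {
  r <- list(report_id = "t", text = "Chronic infarct. Mild leukoaraiosis.")
  c1 <- classify_report(r)
  c2 <- classify_report(r)
  expect_equal(c1$mentions, c2$mentions)
  expect_equal(c1$sbi, c2$sbi)

  empty_lex <- default_lexicon()[0, ]
  cl <- classify_report(r, lexicon = empty_lex)
  expect_equal(cl$sbi, "negative")
  expect_equal(cl$wmd, "negative")
  expect_equal(nrow(cl$mentions), 0L)
})

test_that("impression_only restricts evidence to the impression section", {
  txt <- "FINDINGS:\nChronic infarct in the pons.\nIMPRESSION:\nNo acute process."
  full <- classify_report(list(report_id = "t", text = txt))
  imp <- classify_report(list(report_id = "t", text = txt), impression_only = TRUE)
  expect_equal(full$sbi, "positive")
  expect_equal(imp$sbi, "negative")
})
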