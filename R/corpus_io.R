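#' Read neuroimaging reports
#'
#' Reads a corpus of free-text neuroimaging reports either from a JSONL file
#' (one JSON object per line with fields `report_id`, `site`, `scan_type`,
#' `text`) or from a directory of `.txt` files with a `metadata.tsv` sidecar
#' (columns `report_id`, `site`, `scan_type`; one `<report_id>.txt` per row).
#'
#' Text is Unicode-normalized (NFC) on read and hyphenated line wraps
#' (`"infarc-\\ntion"`) are rejoined, so downstream character offsets always
#' refer to the normalized text.
#'
#' @param path Path to a `.jsonl` file or a report directory.
#' @param format `"jsonl"` or `"plain_dir"`.
#' @return A `data.frame` with columns `report_id`, `site`, `scan_type`,
#'   `text`, one row per report in input order.
#' @export
read_reports <- function(path, format = c("jsonl", "plain_dir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("path does not exist: %s", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- jsonlite::fromJSON(lines[[i]])
      for (f in c("report_id", "site", "scan_type", "text")) {
        if (is.null(rec[[f]])) {
          stop_fmt("report record on line %d is missing required field '%s'", i, f)
        }
      }
      rec
    })
    reports <- data.frame(
      report_id = vapply(recs, function(r) as.character(r$report_id), ""),
      site = vapply(recs, function(r) tolower(as.character(r$site)), ""),
      scan_type = vapply(recs, function(r) tolower(as.character(r$scan_type)), ""),
      text = vapply(recs, function(r) as.character(r$text), ""),
      stringsAsFactors = FALSE
    )
  } else {
    meta_path <- file.path(path, "metadata.tsv")
    if (!file.exists(meta_path)) stop_fmt("plain_dir corpus needs %s", meta_path)
    meta <- read.delim(meta_path, stringsAsFactors = FALSE, colClasses = "character")
    for (f in c("report_id", "site", "scan_type")) {
      if (is.null(meta[[f]])) stop_fmt("metadata.tsv is missing column '%s'", f)
    }
    txt <- vapply(meta$report_id, function(id) {
      fp <- file.path(path, paste0(id, ".txt"))
      if (!file.exists(fp)) stop_fmt("missing report file %s", fp)
      paste(readLines(fp, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, "")
    reports <- data.frame(
      report_id = meta$report_id, site = tolower(meta$site),
      scan_type = tolower(meta$scan_type), text = unname(txt),
      stringsAsFactors = FALSE
    )
  }
  validate_reports(reports)
}

validate_reports <- function(reports) {
  dup <- reports$report_id[duplicated(reports$report_id)]
  if (length(dup)) stop_fmt("duplicate report_id: %s", dup[[1]])
  if (any(!nzchar(reports$report_id))) stop_fmt("empty report_id")
  bad_site <- setdiff(unique(reports$site), SITES)
  if (length(bad_site)) stop_fmt("invalid site '%s' (expected site_a/site_b)", bad_site[[1]])
  bad_scan <- setdiff(unique(reports$scan_type), SCAN_TYPES)
  if (length(bad_scan)) stop_fmt("invalid scan_type '%s' (expected ct/mri)", bad_scan[[1]])
  blank <- !nzchar(trimws(reports$text))
  if (any(blank)) {
    stop_fmt("report '%s' has whitespace-only text", reports$report_id[blank][[1]])
  }
  reports$text <- normalize_report_text(reports$text)
  reports
}

# NFC normalization plus rejoining of hyphenated line wraps, applied once at
# ingestion so that lexicon matching and mention offsets are stable.
normalize_report_text <- function(text) {
  text <- stringi::stri_trans_nfc(text)
  gsub("([A-Za-z])-\\n([a-z])", "\\1\\2", text)
}

#' Read gold annotations
#'
#' Reads JSONL gold labels, one object per line with fields `report_id`,
#' `sbi`, `wmd` (each one of `"positive"`, `"indeterminate"`, `"negative"`,
#' case-insensitive) and optional `annotator`.
#'
#' @param path Path to an annotation JSONL file.
#' @return A `data.frame` with columns `report_id`, `sbi`, `wmd`, `annotator`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_fmt("path does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]])
    for (f in c("report_id", "sbi", "wmd")) {
      if (is.null(rec[[f]])) stop_fmt("annotation on line %d missing field '%s'", i, f)
    }
    for (f in c("sbi", "wmd")) {
      lab <- tolower(as.character(rec[[f]]))
      if (!lab %in% LABELS3) {
        stop_fmt("annotation on line %d has unknown %s label '%s'", i, f, rec[[f]])
      }
      rec[[f]] <- lab
    }
    rec
  })
  data.frame(
    report_id = vapply(recs, function(r) as.character(r$report_id), ""),
    sbi = vapply(recs, function(r) r$sbi, ""),
    wmd = vapply(recs, function(r) r$wmd, ""),
    annotator = vapply(recs, function(r) {
      a <- r$annotator
      if (is.null(a) || length(a) == 0 || is.na(a)) NA_character_ else as.character(a)
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Three-way corpus split
#'
#' Randomly partitions a corpus into train/dev/test subsets of near-equal
#' size. Any remainder is assigned to train, so a 1000-report corpus yields
#' 334/333/333 (and a 1001-report corpus 335/333/333).
#'
#' @param reports A report `data.frame` (from [read_reports()]) or a
#'   character vector of report ids.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list of class `"corpus_split"` with character-vector elements
#'   `train`, `dev`, `test` and the `seed`.
#' @export
split_corpus <- function(reports, seed) {
  ids <- if (is.data.frame(reports)) reports$report_id else as.character(reports)
  n <- length(ids)
  if (n < 3) stop_fmt("need at least 3 reports to split, got %d", n)
  if (anyDuplicated(ids)) stop_fmt("duplicate report ids in corpus")
  base <- n %/% 3L
  rem <- n %% 3L
  # remainder-to-train: non-divisible corpora give the extra reports to train
  sizes <- c(train = base + rem, dev = base, test = base)
  perm <- with_seed(seed, sample(ids, n))
  out <- list(
    train = perm[seq_len(sizes[["train"]])],
    dev = perm[sizes[["train"]] + seq_len(sizes[["dev"]])],
    test = perm[sizes[["train"]] + sizes[["dev"]] + seq_len(sizes[["test"]])],
    seed = as.integer(seed)
  )
  class(out) <- "corpus_split"
  out
}

#' Write and read document-level predictions
#'
#' Predictions are serialized as JSONL with lower-case labels, one object
#' per report: `{"report_id": ..., "sbi": ..., "wmd": ...}`. `write` then
#' `read` round-trips losslessly.
#'
#' @param classifications `data.frame` with columns `report_id`, `sbi`, `wmd`.
#' @param path Output path.
#' @export
write_predictions <- function(classifications, path) {
  stopifnot(all(c("report_id", "sbi", "wmd") %in% names(classifications)))
  lines <- vapply(seq_len(nrow(classifications)), function(i) {
    jsonlite::toJSON(list(
      report_id = classifications$report_id[[i]],
      sbi = tolower(classifications$sbi[[i]]),
      wmd = tolower(classifications$wmd[[i]])
    ), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop_fmt("path does not exist: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(report_id = character(), sbi = character(),
                      wmd = character(), stringsAsFactors = FALSE))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    report_id = vapply(recs, function(r) as.character(r$report_id), ""),
    sbi = vapply(recs, function(r) tolower(r$sbi), ""),
    wmd = vapply(recs, function(r) tolower(r$wmd), ""),
    stringsAsFactors = FALSE
  )
}

#' Write reports / annotations (JSONL)
#'
#' Inverse of [read_reports()] and [read_annotations()]; used by the
#' synthetic generator and tests.
#'
#' @param reports,annotations Data frames in the canonical column layout.
#' @param path Output path.
#' @export
write_reports <- function(reports, path) {
  lines <- vapply(seq_len(nrow(reports)), function(i) {
    jsonlite::toJSON(list(
      report_id = reports$report_id[[i]], site = reports$site[[i]],
      scan_type = reports$scan_type[[i]], text = reports$text[[i]]
    ), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_reports
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(seq_len(nrow(annotations)), function(i) {
    ann <- annotations$annotator[[i]]
    jsonlite::toJSON(list(
      report_id = annotations$report_id[[i]],
      sbi = tolower(annotations$sbi[[i]]),
      wmd = tolower(annotations$wmd[[i]]),
      annotator = if (is.na(ann)) NULL else ann
    ), auto_unbox = TRUE, null = "null")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
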