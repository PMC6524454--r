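# Evaluation statistics: 2x2 confusion-matrix metrics, Cohen's kappa with
# percent agreement, the McNemar paired-classifier test (exact binomial or
# continuity-corrected chi-square), and the F-measure.

#' Collapse 3-way labels to binary
#'
#' The document labels are 3-way (positive / indeterminate / negative) but
#' the confusion-matrix evaluation is 2x2. `"positive_vs_rest"` (default)
#' maps positive to 1 and everything else to 0;
#' `"positive_plus_indeterminate"` maps both positive and indeterminate
#' to 1.
#'
#' @param labels Character vector of 3-way labels.
#' @param policy Collapse policy.
#' @return Integer vector of 0/1.
#' @export
binarize_labels <- function(labels,
                            policy = c("positive_vs_rest",
                                       "positive_plus_indeterminate")) {
  policy <- match.arg(policy)
  labels <- tolower(as.character(labels))
  bad <- setdiff(unique(labels), LABELS3)
  if (length(bad)) stop_fmt("unknown label '%s'", bad[[1]])
  pos <- if (policy == "positive_vs_rest") "positive" else
    c("positive", "indeterminate")
  as.integer(labels %in% pos)
}

#' Confusion-matrix metrics
#'
#' Computes tp/fp/fn/tn and sensitivity, specificity, PPV, NPV and accuracy
#' from binary gold and predicted labels. A metric whose denominator is zero
#' is reported as `NA` and named in the `undefined` field rather than being
#' silently set to 0.
#'
#' @param gold,pred Equal-length binary (0/1) vectors.
#' @return A list of class `confusion_summary`.
#' @export
confusion_metrics <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop_fmt("gold (%d) and pred (%d) lengths differ", length(gold), length(pred))
  }
  if (!length(gold)) stop_fmt("empty input")
  gold <- as.integer(gold); pred <- as.integer(pred)
  stopifnot(all(gold %in% 0:1), all(pred %in% 0:1))
  tp <- sum(gold == 1 & pred == 1); fp <- sum(gold == 0 & pred == 1)
  fn <- sum(gold == 1 & pred == 0); tn <- sum(gold == 0 & pred == 0)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fp + fn + tn)
  )
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv", "accuracy")], is.na, TRUE)))
  class(out) <- "confusion_summary"
  out
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    cat(sprintf("  %-11s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.3f", x[[m]])))
  }
  invisible(x)
}

#' Cohen's kappa and percent agreement
#'
#' Unweighted Cohen's kappa for two annotators over a shared nominal label
#' set (any number of categories; the 3-way report labels are supported
#' directly). When both annotators assign a single identical category to
#' every item, chance agreement is 1 and kappa is undefined (`NA`) while
#' percent agreement is 100.
#'
#' @param ann1,ann2 Equal-length label vectors (length >= 2).
#' @return A list of class `agreement_summary` with `kappa`,
#'   `percent_agree` (0-100), `n` and the `contingency` table.
#' @export
cohen_kappa <- function(ann1, ann2) {
  if (length(ann1) != length(ann2)) stop_fmt("annotation lengths differ")
  n <- length(ann1)
  if (n < 2) stop_fmt("need at least 2 items")
  levs <- sort(unique(c(as.character(ann1), as.character(ann2))))
  f1 <- factor(as.character(ann1), levels = levs)
  f2 <- factor(as.character(ann2), levels = levs)
  tab <- table(f1, f2)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps * 8) NA_real_ else
    (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, percent_agree = 100 * p_o, n = n,
                 contingency = tab),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("n=%d  %%agree=%.1f  kappa=%s\n", x$n, x$percent_agree,
              if (is.na(x$kappa)) "undefined" else sprintf("%.3f", x$kappa)))
  invisible(x)
}

#' McNemar test for paired classifiers
#'
#' Compares two classifiers on the same gold standard through their
#' discordant pairs: `b` = items A got right and B got wrong, `c` = the
#' reverse. The default exact test uses the binomial distribution,
#' `p = min(1, 2 * min(P(X <= min(b,c)), 0.5))` with `X ~ Bin(b+c, 0.5)`;
#' the `"chisq_cc"` method uses the continuity-corrected statistic
#' `(|b - c| - 1)^2 / (b + c)` on 1 df. When `b + c = 0` the result is
#' degenerate and `p = 1`.
#'
#' @param gold,pred_a,pred_b Equal-length binary vectors.
#' @param method `"exact"` (default) or `"chisq_cc"`.
#' @return A list of class `mcnemar_result` with `b`, `c`, `statistic`,
#'   `p_value`, `method`, `degenerate`.
#' @export
mcnemar_test <- function(gold, pred_a, pred_b, method = c("exact", "chisq_cc")) {
  method <- match.arg(method)
  if (length(gold) != length(pred_a) || length(gold) != length(pred_b)) {
    stop_fmt("gold/pred_a/pred_b lengths differ")
  }
  a_ok <- pred_a == gold; b_ok <- pred_b == gold
  b <- sum(a_ok & !b_ok); cc <- sum(!a_ok & b_ok)
  degenerate <- (b + cc) == 0L
  if (method == "exact") {
    p <- if (degenerate) 1 else min(1, 2 * min(pbinom(min(b, cc), b + cc, 0.5), 0.5))
    stat <- NA_real_
  } else {
    if (degenerate) { stat <- NA_real_; p <- 1 } else {
      stat <- (abs(b - cc) - 1)^2 / (b + cc)
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(b = b, c = cc, statistic = stat, p_value = p,
                 method = method, degenerate = degenerate),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar (%s): b=%d c=%d p=%.4g%s\n", x$method, x$b, x$c,
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' F-measure
#'
#' Harmonic mean of precision and recall, `2pr / (p + r)`; defined as 0
#' (with attribute `degenerate = TRUE`) when both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return The F1 score.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) {
    return(structure(0, degenerate = TRUE))
  }
  2 * precision * recall / (precision + recall)
}
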