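---
title: "Methods: rule-based and neural detection of silent brain infarction in neuroimaging reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based and neural detection of silent brain infarction in neuroimaging reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbifinder)
```

## The problem

Silent brain infarction (SBI) is a brain lesion attributed to vascular
occlusion, visible on CT or MRI in a patient without clinical stroke. It is
an incidental imaging finding: it has no diagnosis code and typically exists
only as a phrase in the free text of a radiology report ("chronic lacunar
infarct, left basal ganglia"). White matter disease (WMD, leukoaraiosis) is
a second, more prevalent incidental finding of the same kind. `sbifinder`
implements the two standard NLP routes to case ascertainment from report
text — a lexicon-driven rule-based information-extraction pipeline and a
convolutional sentence classifier with traditional baselines — together
with the agreement and comparison statistics such a study reports, and a
synthetic corpus generator so that every part of the system can be trained
and validated without restricted clinical data.

Labels are three-way per condition and per report: *positive*,
*indeterminate* (the report hedges), *negative*. Binary evaluation
collapses these with `binarize_labels()`; the default policy maps positive
to 1 and everything else to 0 (`positive_vs_rest`), the alternative
(`positive_plus_indeterminate`) is exposed because the collapse used in the
original evaluation is not recorded anywhere we can check.

## The rule-based pipeline

`classify_report()` is a deterministic composition:

1. **Sentence segmentation** (`segment_sentences()`): split at `.`, `!`,
   `?` followed by whitespace and at newlines, protecting common
   abbreviations ("vs.", "e.g."), single-letter initials, and enumerator
   tokens ("IMPRESSION: 1. No acute infarct." is one sentence, not two
   fragments). Offsets are 0-based half-open into the normalized text;
   slicing a span out of the report reproduces the sentence exactly.
2. **Section detection** (`detect_sections()`): a FINDINGS or IMPRESSION
   header switches the section from that sentence on, but only when the
   header starts its line — "see impression above" mid-sentence does not.
   Sections are annotated but do not gate the decision by default; the
   `impression_only` flag restricts evidence to the IMPRESSION section for
   sites whose findings sections routinely restate history.
3. **Concept matching** (`match_concepts()`): case-insensitive,
   word-boundary-anchored regular expressions over the lexicon, longest
   match first, then leftmost, resolved within category ("infarction" never
   also matches its substring "infarct"). A WMD *exclusion* term
   ("degenerative changes") suppresses WMD finding matches it overlaps or
   directly abuts, so "white matter degenerative changes" — spine disease,
   not leukoaraiosis — produces no WMD finding. Abutment (whitespace-only
   gap) is included deliberately: the motivating phrase has non-overlapping
   spans.
4. **Context assignment** (`assign_context()`): a ConText-style
   cue-and-scope pass. A cue (negation: "no", "without", "no evidence of",
   …; hedging: "probable", "possible", "cannot exclude", …; history:
   "history of", "known", …; conditional: "if"; other-person: "family
   history", "mother", …) applies to every mention to its right in the
   sentence unless a scope terminator ("but", "however", ";") intervenes.
   Negation outranks hedging when both fire. Chronicity of an SBI finding
   comes from the nearest modifier mention in the sentence. Defaults when
   no cue fires: confirmed, present, patient, unspecified. Cue inventories
   ship as editable TSVs (`inst/extdata/context_cues.tsv`).
5. **Summarization** (`summarize_document()`): per condition, a precedence
   ladder over the report's mentions. SBI: any confirmed, present-tense,
   patient-experienced finding with chronic or unspecified chronicity makes
   the document positive; if the best qualifying mention is merely probable
   the document is indeterminate; otherwise negative. WMD is the same
   ladder without the chronicity requirement. Every positive or
   indeterminate label carries the mentions that produced it as evidence.

### Design decisions where the pipeline was underdetermined

The published description of this kind of system names the components but
not their parameters. The choices below are this package's own, made once
and tested:

* **Acute vs chronic modifiers.** The modifier inventory is partitioned
  into acute = {acute, acute or subacute, recent, new} and chronic =
  {remote, old, chronic, prior, chronic foci of, benign, stable small,
  stable}. An acute-only infarct mention never yields SBI-positive: a
  *silent* infarct is by definition a non-acute incidental finding, and
  patients with acute stroke are excluded from this use case upstream.
  A finding with no modifier at all ("lacunar infarct") does qualify —
  unmodified mentions of lacunes in non-stroke patients are how these
  findings are typically written.
* **Location terms never suffice alone.** "left basal ganglia lacunar"
  lives in the location inventory; without a finding term in the sentence
  it contributes nothing. This is exactly the false-positive mode that
  plagues the embedding classifiers (location words co-occur with infarct
  words in training), so the generator emits location-only confounder
  sentences and the test suite pins the rule engine's immunity to them.
* **Conflicting mentions.** One confirmed and one negated mention of the
  same concept in a report: confirmed wins (document positive). The
  alternative reading — conflicts yield indeterminate — is defensible; we
  chose the ladder because radiology reports routinely negate the acute
  form and confirm the chronic form in the same breath ("No acute infarct.
  Chronic lacune…"), and that pattern must come out positive.
* **Coreference is not resolved.** A report that says "focal
  encephalomalacia and gliosis…" in one sentence and "the findings above
  reflect remote ischemic insult" in another is SBI-positive, but no single
  sentence qualifies. This is the known, documented false-negative mode of
  the sentence-scoped engine; the test suite pins it as an expected
  failure rather than papering over it.
* **Unstratified split.** `split_corpus()` permutes uniformly under the
  seed and assigns any remainder to train (1000 → 334/333/333,
  1001 → 335/333/333). Whether the original split was stratified by site or
  label is unrecorded; unstratified is the minimal assumption.

## The CNN

The sentence classifier is defined by five equations: embedding lookup
`x_i = E_{x_i}` (d = 100), convolution `con_i = ReLU(w_k x_{i:i+k-1} + b_k)`
per window size `k`, max-over-time pooling `m_k = max_i con_i`, a fully
connected layer `O = w m + b`, and a two-class softmax
`p(sbi|x, θ) = e^{O_sbi}/(e^{O_sbi} + e^{O_other})`. `cnn_forward()`
implements exactly this; the test suite checks it against a brute-force
loop oracle on small instances and a hand-computed d = 2, n = 3, k = 2
example to 1e-9.

Unstated hyperparameters follow the standard configuration for this
architecture family, all overridable via `cnn_hyper()`: window sizes
{3, 4, 5}, 100 filters per size, dropout 0.5 on the pooled vector
(training only, inverted scaling), 10 epochs of Adam at learning rate 1e-3,
batch size 32. Embeddings are frozen by default (`fine_tune_embeddings`
flips this). Sentences shorter than the largest window are padded with zero
rows; the out-of-vocabulary sentinel is the zero vector. Model selection
keeps the epoch with the best dev accuracy. All randomness — initialization,
shuffling, dropout — flows from one seed in a single thread, so training is
bit-reproducible; the architecture is single-channel (the dual-channel
static+fine-tuned variant is a possible extension, not implemented).

Documents are labeled by **max aggregation**: positive iff any sentence's
positive-class probability reaches `tau_pos` (default 0.5). The sentence
classifier is binary (target vs other), so the ML route never produces
*indeterminate*; under the default `positive_vs_rest` evaluation policy
this costs it nothing on definite reports and counts hedged reports against
it, which is the honest accounting.

## Baselines

Logistic regression (ridge, C = 1, via `glmnet`), a linear soft-margin SVM
(C = 1, Pegasos subgradient descent with averaged iterates — implemented
in-package because no SVM library is available in the target environment),
and a random forest (500 CART trees, Gini splits, `mtry = floor(sqrt(p))`,
compiled) over **mean-pooled** word vectors. Mean pooling is the minimal
reading of "word vectors as input" for fixed-length models; a bag-of-words
mode is exposed as the alternative. Pooling a one-token sentence returns
that token's embedding, and pooling is order-invariant — both are tested.

## PMI keyword ranking

`compute_pmi()` scores n-grams (up to length 3 by default — "patterns" read
as n-grams) against labels at the sentence level, each sentence inheriting
its document's label: `pmi = log2(p(g, l) / (p(g) p(l)))` in bits, with
presence counts (an n-gram counts once per sentence). The default applies
add-one smoothing to each cell of the per-pair 2×2 contingency table so
that never-co-occurring pairs score finite negative values; `smooth =
"none"` gives the raw estimator, which is what the closed-form calibration
cases (1 bit when a token occurs in exactly the positive half; 0 under
independence) and the brute-force oracle tests use. PMI here is a
prototyping aid for lexicon curation, not an inference procedure: no
significance testing is attached.

## Evaluation statistics

* `confusion_metrics()`: tp/fp/fn/tn plus sensitivity, specificity, PPV,
  NPV, accuracy. A metric whose denominator is zero is `NA` and named in
  `undefined` — degenerate synthetic runs report honestly rather than
  silently scoring 0.
* `cohen_kappa()`: unweighted kappa for two raters over any nominal label
  set (the three-way labels are used directly), with percent agreement.
  When both raters are constant and identical, chance agreement is 1 and
  kappa is undefined (`NA`) while agreement is 100% — flagged, not forced
  to 1.
* `mcnemar_test()`: exact binomial by default —
  `p = min(1, 2·min(P(X ≤ min(b,c)), 0.5))`, `X ~ Bin(b+c, ½)` — because
  discordant counts at test-set scale (n ≈ 333) are small; the
  continuity-corrected chi-square `(|b−c|−1)²/(b+c)` is the optional
  large-sample variant. `b + c = 0` returns p = 1 with a degenerate flag.
* `f_measure()`: `2pr/(p+r)`, 0 with a flag when both are 0. (Applying it
  to one published agreement table's own precision 0.92 and recall 0.69
  gives 0.789, not the 0.74 printed there; the package asserts the
  arithmetic, not the typo.)

## The synthetic corpus: what it emulates and what it does not

`generate_corpus()` states a world; its defaults are fixed and tests never
move them toward a pass:

* **Prevalence.** SBI carrier rate 0.12 (a documented stand-in — the
  source setting reports only "a small number of positive cases"; the true
  site-level prevalence is not public), WMD 0.60 (stated directly in the
  motivating study's discussion of class balance).
* **Two documentation styles.** Site A (free-form) draws its
  negative-infarction statement from a compositional pool of 212 distinct
  phrasings (cue × finding-phrase × tail); site B (template) from a fixed
  pool of 12. The 212-vs-12 contrast is the reported sublanguage gap
  between a free-style and a template-based site. Every report carries one
  such statement.
* **Hedged findings** (8% of carriers) are written with "probable"/
  "possible"/"likely" and are gold *indeterminate*. **Historical**
  mentions ("history of remote infarction", 10% of non-carriers) and
  **location-only confounders** (15% of reports) are gold negative.
* **Coreference splits** (5% of definite SBI carriers by default): the
  finding and its ischemic attribution are placed in different sentences,
  neither containing a lexicon finding term. The document is gold positive
  while no sentence qualifies — the engineered hard case for the rule
  engine.
* **Per-sentence binary truth** is emitted alongside document labels, so
  classifier training does not depend on distant labeling. Hedged
  sentences are labeled 0 at the sentence level, keeping sentence truth
  consistent with the `positive_vs_rest` document collapse. Coreference
  split sentences are labeled 1 (jointly they express the finding), which
  is precisely the signal a sentence-scoped rule system cannot use but an
  embedding classifier can.
* **Embeddings.** The clinical skip-gram table used in practice is not
  distributable, so `build_embedding_table()` trains a skip-gram model
  (negative sampling, dynamic window 5, 5 epochs, compiled) on the
  synthetic corpus itself, or generates deterministic per-token unit-norm
  random vectors; d defaults to 100.

A green test on this corpus establishes internal consistency — the engine
recovers exactly the semantics the generator encodes, the CNN can learn the
lexical signal, oversampling does not hurt minority-class sensitivity, the
statistics match their definitions. It does **not** establish clinical
performance: real reports have richer vocabulary, typos, template drift,
cross-sentence discourse far beyond the one engineered pattern, and label
noise. The published headline numbers (rule-based SBI accuracy ≈ 0.99 at
sensitivity 0.925 and specificity 1.000 on a 333-report test set) come from
a restricted corpus this package cannot see, which is why the acceptance
targets here are property-based rather than numeric reproductions.

## Numerical and testing notes

* All offsets are 0-based half-open; report text is NFC-normalized and
  hyphenated line wraps are rejoined at ingestion, so offsets always refer
  to the normalized text.
* Statistics are checked against brute-force oracles (definition recounts,
  full binomial sums over all `b + c ≤ 30`) at 1e-12; the CNN forward pass
  against loop oracles at 1e-9; softmax normalization at 1e-12.
* The label-shuffled no-signal controls shuffle labels on both the
  training and evaluation side. With informative features and a shuffled
  training side only, a forest amplifies the residual chance correlation
  of the shuffle (agreement with true labels ≈ 0.5 ± 1/√n) into well
  -above-chance test accuracy; shuffling both sides makes the control
  well-posed.
* Stochastic directional properties (oversampling helps sensitivity on
  10%-positive data; a template-site-trained CNN generalizes worse to the
  free-form site) are asserted as seed-averaged weak inequalities over 5
  pinned seeds, mirroring how such claims are hedged ("slightly improved")
  in practice.

## Known limitations

* No coreference resolution; the Box-2-style split finding is a pinned
  false negative of the rule engine by design.
* No UMLS or ontology normalization beyond the two concept codes (SBI,
  WMD); no DICOM/HL7 ingestion; no de-identification.
* The SVM exposes a logistic squash of its margin, not a calibrated
  probability; threshold-based document aggregation is unaffected.
* The CNN is single-channel; hyperparameter search, calibration analysis
  and ROC curves are out of scope.
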