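# sbifinder

Detection of **silent brain infarction (SBI)** and **white matter disease
(WMD)** in free-text neuroimaging reports.

A silent brain infarct is a lesion attributed to vascular occlusion, seen on
CT or MRI in a patient with no clinical history of stroke. It is common in
the elderly, carries real stroke risk, and has no diagnosis code: when it is
recorded at all, it is recorded as an *incidental finding* in the free text
of a radiology report. The same is true of white matter disease
(leukoaraiosis). `sbifinder` provides the NLP machinery to find these cases
in report text at scale, plus everything needed to train and validate the
system without access to restricted clinical corpora.

## What is in the package

**Rule-based information extraction** (`classify_report()`,
`classify_corpus()`): sentence segmentation, FINDINGS/IMPRESSION section
detection, case-insensitive word-boundary regular-expression matching
against a curated lexicon of SBI finding / modifier / location terms and WMD
finding / exclusion terms, ConText-style cue-and-scope assignment of
*status* (confirmed / probable / negated), *temporality* (present /
historical / hypothetical) and *experiencer* (patient / other), and a
document-level precedence ladder: a confirmed, present, patient, chronic-or
-unmodified finding makes a report **positive**; a hedged one makes it
**indeterminate**; everything else (negated, acute-only, historical,
other-person) is **negative**.

**CNN sentence classifier** (`train_cnn()`, `cnn_forward()`): the standard
convolutional architecture for sentence classification, written out against
its defining equations. Each token maps to its embedding row `x_i = E_{x_i}`
(d = 100 by default); for every window size `k`, filters compute
`con_i = ReLU(w_k · x_{i:i+k-1} + b_k)`; max-over-time pooling takes
`m_k = max_i con_i`; a fully connected layer `O = w·m + b` feeds a 2-class
softmax `p(sbi | x, θ) = e^{O_sbi} / (e^{O_sbi} + e^{O_other})`.
Training is mini-batch Adam with dropout on the pooled vector, dev-set model
selection, and bit-reproducible seeding. Documents are labeled by max
aggregation over sentence probabilities.

**Traditional baselines** (`train_baseline()`): ridge logistic regression,
a linear SVM, and a random forest over mean-pooled word vectors (or
bag-of-words), mirroring the comparison suite such a study runs.

**PMI keyword ranking** (`compute_pmi()`): pointwise mutual information of
n-grams against document labels, the tool used to prototype and audit the
lexicon.

**Evaluation statistics** (`confusion_metrics()`, `cohen_kappa()`,
`mcnemar_test()`, `f_measure()`): 2×2 confusion metrics with explicit
undefined-value handling, unweighted Cohen's kappa with percent agreement
for inter-annotator studies, the exact-binomial (or continuity-corrected
chi-square) McNemar test for paired classifiers, and the F-measure.

**Synthetic corpus generator** (`generate_corpus()`): labeled synthetic
reports with the structure the analyses assume — two documentation styles
(a free-form site drawing negative-infarct phrasings from a 212-expression
compositional pool vs a template site with 12), low SBI prevalence vs ~60%
WMD prevalence, hedged / negated / historical mentions, location-only
confounder sentences, and coreference-split findings that defeat any
single-sentence system. Plus a skip-gram (or seeded-random) stand-in
embedding table (`build_embedding_table()`) and minority-class
`oversample()`.

## Worked example

```r
library(sbifinder)

s <- "probable right old frontal lobe subcortical infarct as described above"
assign_context(match_concepts(s), s)[, c("matched_text", "category", "status",
                                         "temporality", "chronicity")]
#>   matched_text             category   status temporality  chronicity
#> 1          old SBI_MODIFIER_CHRONIC probable     present unspecified
#> 2      frontal         SBI_LOCATION probable     present unspecified
#> 3      infarct          SBI_FINDING probable     present     chronic
```

The infarct mention is hedged ("probable"), present-tense, the patient's
own, and chronic ("old") — so a report containing only this sentence is
labeled SBI-**indeterminate**. A definite report:

```r
classify_report(list(report_id = "example-1", text =
  "FINDINGS:\nNo acute infarct, but chronic lacune in the left basal ganglia.\nModerate white matter microvascular ischemic changes.\nIMPRESSION:\nChronic lacunar infarct."))
#> <document_classification> example-1
#>   SBI: positive   WMD: positive
#>   5 sentence(s), 9 concept mention(s)
```

Note the scope handling: "No acute infarct, **but** chronic lacune" — the
negation stops at "but", the lacune is confirmed and chronic, and the
report is positive. End to end on a synthetic corpus:

```r
corp <- generate_corpus(generator_config(n_reports = 200, seed = 42))
pred <- classify_corpus(corp$reports)
confusion_metrics(binarize_labels(corp$gold$sbi), binarize_labels(pred$sbi))
#> tp=18 fp=0 fn=1 tn=181
#>   sensitivity 0.947
#>   specificity 1.000
#>   ppv         1.000
#>   npv         0.995
#>   accuracy    0.995
```

The one false negative is a coreference-split report (the finding and its
ischemic attribution live in different sentences) — the documented failure
mode of any single-sentence rule system, generated on purpose at a 5% rate.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/sbifinder", package="sbifinder"))')
Rscript $CLI generate --n 1000 --seed 5 --out corpus/
Rscript $CLI rule-classify --in corpus/reports.jsonl --out pred.jsonl
Rscript $CLI evaluate --gold corpus/gold.jsonl --pred pred.jsonl --out metrics.json
```

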