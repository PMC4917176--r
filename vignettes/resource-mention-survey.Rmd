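---
title: "Surveying database and software usage in the literature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying database and software usage in the literature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`resmine` re-implements, as a tested pipeline, a literature-mining survey of
bioinformatics *resources* — databases, software, packages and ontologies —
mentioned in full-text biomedical articles. This vignette is the package's
own account of the methods: the recognition model, the false-positive
filter, the survey statistics, and the synthetic corpus that stands in for
a full-text archive. The analysis drivers under `analysis/` run the whole
study in order; every computation they perform lives in the package and is
unit-tested.

## The recognition model

Recognition is dictionary- and rule-based with document-level score
pooling. Text is shallow-parsed deterministically: offset-preserving
tokenisation, sentence splitting, a coarse part-of-speech tagger driven by
closed-class word lists and morphology, noun-phrase chunking with a
nearest-head link per token. A full statistical dependency parse buys
little for this task at considerable cost, so the head links used by the
keyword-association rules come from the chunker; this is a documented
approximation and the package's own design choice.

Candidates come from two sources: dictionary matches (token 1–4-grams
looked up under a shared normalisation — case-folded, whitespace-collapsed,
trailing version tokens stripped — which always yield candidates, even
bare; short all-caps names are the exception and match case-sensitively,
since the lowercase spelling of an acronym like "GO" or "IN" is ordinary
running text, not a name variant), and name-like tokens (proper-noun or acronym-cased) that attract at
least one contextual positive rule. Each candidate records every rule it
matched from a fixed inventory of 17 (dictionary, version-number, URL,
citation-marker, positive keyword, negative keyword, two Hearst templates,
head-association, restricted-head, propagation, three case classes, two
acronym-resolution outcomes, name morphology); rule identifiers are stable
because they double as the filter's feature ids. The *restricted* head
nouns (program, system, project, service) are too ambiguous on their own
and only count when corroborated by a second positive contextual rule.

A candidate's raw score is the weighted sum of its matched rules. The
weights and the acceptance threshold `tau` are not part of the published
method and are shipped in `inst/extdata/rules_config.json`, calibrated once
against the synthetic gold corpus; the case-class rules (12–14) carry zero
weight there because their numeric effect is applied by a separate
piecewise adjustment (below).

Three document-level steps follow sentence-level scoring:

* **Document-wide adjustment.** Candidates sharing a normalised surface
  form form a cohort; each member gains
  `min(alpha * (n - 1) * mean(max(raw, 0)), cap)` with `alpha = 0.3`,
  `cap = 2`. Many weak clues for the same name can jointly cross the
  threshold; singletons and all-negative cohorts gain nothing, and the
  adjustment never lowers a score.
* **Acronym resolution.** For an all-caps 2–6-character dictionary
  candidate whose entry records an expected long form, a
  parenthesis-pattern detector (scanning up to `nchar(acronym) + 5` words
  left of "(ACR)") extracts the document's own definition; a normalised
  edit distance above `tolerance = 0.2` rejects every occurrence of that
  acronym in the document, a match adds the verified-acronym rule. With no
  in-text definition the candidate passes through.
* **Propagation.** Once a cohort's best member crosses `tau`, all bare
  occurrences of its surface form are promoted to mentions (flagged with
  the propagation rule) and inherit the cohort's best adjusted score; how
  the original system scored propagated mentions is unpublished, and
  inheriting the seed score is this package's choice — it makes
  document-level evidence directly actionable at the mention level.

Finally, a case/length adjustment (+1 for short all-caps, +0.5 for short
mixed case, −1 for short lowercase common words, identity otherwise —
monotone in the score) is applied and candidates at or above `tau = 2.5`
become mentions, sorted by span. Identical input and configuration yield
byte-identical output.

## The false-positive filter

Accepted mentions are re-scored by a classifier that sees *only* the rule
profile: 17 binary flags plus the rule count, 18 features, no lexical
information — permuting surface strings cannot change its predictions.
Random forest and naive Bayes are first-class families (linear and RBF
SVMs ride behind the same interface); families are compared by 10-fold
cross-validation repeated over shuffles, reporting precision, recall, F
and AUC means with standard deviations. The deployed filter is trained on
all labelled data and removes a mention when it is at least 80% confident
the mention is a false positive — the boundary itself is removal, reading
the operating point literally. Training labels come from lenient gold
alignment by default (the strict/lenient choice for training labels is
unpublished; both are supported).

## Survey statistics

All statistics run on a usage table with two counting levels per
(resource, partition, year, journal) cell: total mention occurrences, and
document-level mentions counting a resource once per document. Corpora are
partitioned by journal subject codes with hierarchical prefix subsumption
(medicine `H02.403`, biology `H01.158.273`, bioinformatics
`H01.158.273.180`), which makes bioinformatics a strict subset of biology;
journals with several codes join every matching partition, uncatalogued
journals only the full corpus.

* **Reported proportions and means** round half-up to one decimal, the
  convention of the published tables they are checked against.
* **Temporal series** take, per year, the top-100 resources by
  document-level count (boundary ties are all included — at desk scale the
  boundary count is often 1, so the pool can exceed its nominal size) and
  normalise counts to pool fractions, which sum to one each year.
* **Year0 normalisation** divides each resource's trajectory by its value
  in the first year it enters the pool; when a resource drops out and
  re-enters, the first appearance stays the baseline.
* **The random-walk envelope** estimates the step spread `sigma` as the
  standard deviation of pooled year-over-year changes of Year0-normalised
  series and draws `1 ± z * sigma * sqrt(t)`. The estimator for `sigma`
  is unspecified in the original description; pooling the changes of the
  partition's top-N established resources (default 20) is this package's
  choice — tail resources with yearly counts near 1 would otherwise
  dominate the spread and blind the envelope.
* **The change score** sums |x(y+1) − x(y)| over *consecutive observed*
  year pairs. As printed, the original summation limit would require a
  term beyond the final study year; summing observed pairs resolves that
  inconsistency. Resources seen in a single year score 0 and are dropped
  from change-score tables.
* **Persistence** keeps resources with an unbroken yearly run of
  document mentions between their first and last observed year, excludes
  anything mentioned in the window's first year ("always existed"), and
  splits by whether the run reaches the final year.
* **Long-tail summaries** report the singleton fraction, the singletons'
  share of total counts, and the shares of the top 1, top 10 and top
  `ceiling(0.05 n)` names.
* **Clustering** decomposes the raw sparse resource × journal count matrix
  by SVD (no centering — centering would densify the matrix, which is the
  stated reason PCA is unsuitable), drops the first component as scale,
  and embeds journals on components 2–3 (resources via the same
  decomposition's left vectors). Variance fractions are reported over the
  computed rank (default 10) — a documented denominator choice. Tests
  compare embeddings up to per-component sign.

## The synthetic corpus

The generator emulates the study conditions end to end: JATS-like XML
articles with sectioned bodies (heading variants, ~10% deliberately
exotic so the zoner's recall is exercised), figure captions, journal and
year metadata over seven synthetic journals spanning the subject
hierarchy, and gold standoff annotations whose spans slice the emitted
text exactly. Mentions are drawn from a Zipf law (exponent 1.1 over 3,000
names — roughly half of the mentioned names end up as singletons, a
pronounced long tail) embedded in the sentence frames the rules target:
keyword-adjacent (30%), versioned (20%), URL-adjacent (10%), Hearst (5%),
citation-adjacent (5%), bare (30%). One percent of dictionary names are
ambiguous common English words that also appear as ordinary words in
distractor sentences; acronym resources are sometimes introduced with
their long form, and occasionally an article defines a *colliding*
expansion and uses the acronym in its non-resource sense, exercising the
acronym filter. Captions prefer visualisation-flagged tools. A planted
strongly growing resource (weight multiplier `1 + 0.35 (y − 2000)`) and a
declining one give the temporal machinery known signal.

The default corpus is 2,000 articles. The temporal sub-study
(`temporal_study_config()`) samples 6,000 articles over a 1,000-name
dictionary with the trends planted at Zipf ranks 5 and 3: envelope-based
trend detection needs yearly document counts in the tens for the analysed
series, which the survey-wide defaults do not provide — that is a power
consideration decided at design time, and `sample_truth_usage()` draws
only the usage counts (the identical statistical model, no text) so
multi-seed studies stay cheap.

What the generator does *not* emulate: real linguistic variety (sentences
come from templates), citation networks, OCR noise, reference lists,
multilingual text, or name nesting ("R package ggplot2"). Passing tests
therefore demonstrate that the pipeline's machinery is correct under the
modelled phenomena, not that its operating point on real full text matches
the synthetic one.

## Numerical and degenerate-input choices

Offsets are 0-based half-open over the stripped body string; the caption
stream never shares offsets with the body. Mentions straddling a section
boundary take the section of their start offset. Span evaluation is
one-to-one maximum-cardinality matching preferring larger overlaps (ties:
left-most), computed with augmenting paths, so it provably agrees with an
exhaustive matching oracle; name identity is not required for a span
match. Undefined precision/recall (empty denominator) is flagged and
reported as 0 with a warning. AUC is the rank statistic with ties counted
half. Unparseable articles are skipped and counted, never fatal; a missing
year flags the article rather than dropping it, and such mentions are kept
in all-years margins but excluded from temporal cells. Zero pooled
variance collapses the envelope to its baseline and is flagged. Zipf
exponents are fit by OLS on log count vs log rank over ranks with at least
5 observations, below which sampled rank-frequency curves flatten.

## Problem sizes

The test suite and acceptance script use the corpus sizes of the study
design: the 2,000-article default corpus for end-to-end recognition,
filtering and long-tail recovery; 100–150-article corpora for oracle
equivalence and unit-level checks; 1,000 null replicates for envelope
coverage; 10 seeds of the temporal sub-study for trend recovery; and
1,000 labelled candidates for classifier calibration against the
closed-form Bayes AUC of the generating mixture.

## Known limitations

The rule inventory is a documented reconstruction — the original system's
precise rules, weights and threshold are unpublished, so quantitative
scores on real text will differ from any published operating point.
Variant generation (case, hyphen/space, camel-case splits,
version-stripping) is likewise a stand-in for unpublished normalisation
rules. The shallow parse occasionally mis-attaches heads in long
coordinations; sentence-initial capitalised common words can enter as
name-like candidates (the filter learns to remove most). Canonical-name
merging is dictionary-driven; names absent from the dictionary are merged
only by surface identity.
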