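# Run the dictionary+rule recogniser over the corpus and score it against
# the gold annotations, before any machine-learning filtering.

source("analysis/00_common.R")

corp <- study_corpus()
mentions <- recognize_corpus(corp$articles, corp$dictionary)

ev <- evaluate_mentions(mentions, corp$gold)
write_tsv(ev, file.path(RESULTS, "ner_evaluation_prefilter.tsv"))
print(ev)
cat(sprintf(
  "Extracted %d mentions from %d articles (gold: %d). Strict F1 = %.2f.\n",
  nrow(mentions), length(corp$articles), nrow(corp$gold),
  ev$f1[ev$mode == "strict"]))

write_mentions(mentions, file.path(RESULTS, "mentions_prefilter.tsv"))
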