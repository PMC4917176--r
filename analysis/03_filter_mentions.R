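# Train the rule-feature false-positive filter, compare model families by
# repeated cross-validation, and apply the best model at 80% confidence.

source("analysis/00_common.R")

corp <- study_corpus()
mentions <- read_mentions(file.path(RESULTS, "mentions_prefilter.tsv"))
labelled <- label_mentions(mentions, corp$gold, "lenient")

# model bake-off on the labelled mentions (10-fold CV, 5 shuffles)
cv <- cross_validate(labelled, c("random_forest", "naive_bayes"),
                     folds = 10, repeats = 5, seed = STUDY_SEED)
write_tsv(cv, file.path(RESULTS, "filter_model_selection.tsv"))
print(cv)

model <- train_filter(labelled, "random_forest", seed = STUDY_SEED)
kept <- apply_filter(mentions, model, confidence = 0.80)

before <- evaluate_mentions(mentions, corp$gold)
after <- evaluate_mentions(kept, corp$gold)
comp <- bind_rows(mutate(before, stage = "prefilter"),
                  mutate(after, stage = "postfilter"))
write_tsv(comp, file.path(RESULTS, "ner_evaluation_stages.tsv"))
print(comp)

cat(sprintf(
  "Filter removed %d of %d mentions; strict precision %.2f -> %.2f, recall %.2f -> %.2f.\n",
  nrow(mentions) - nrow(kept), nrow(mentions),
  before$precision[before$mode == "strict"],
  after$precision[after$mode == "strict"],
  before$recall[before$mode == "strict"],
  after$recall[after$mode == "strict"]))

write_mentions(kept, mentions_path)
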