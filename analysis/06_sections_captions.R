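# Where in a paper are resources mentioned? Zone every document into
# introduction / methods / results-discussion / conclusion and rank
# resources per section; compare the caption stream's preferences.

source("analysis/00_common.R")

corp <- study_corpus()
parts <- partition_corpus(corp$articles, corp$catalog)
mentions <- read_mentions(mentions_path)
zoned <- zone_corpus(mentions, corp$articles)

sec_counts <- count(zoned, section, name = "mentions")
write_tsv(sec_counts, file.path(RESULTS, "section_counts.tsv"))
print(sec_counts)
body_counts <- filter(sec_counts, section != "caption")
cat("Methods carries the most body mentions:",
    body_counts$section[which.max(body_counts$mentions)] == "methods", "\n")

st <- section_usage_table(zoned, parts$full, n = 10)
write_tsv(st, file.path(RESULTS, "section_top_resources.tsv"))

# caption stream: share of visualisation-flagged tools
vis <- corp$dict_truth$canonical[corp$dict_truth$vis]
caps <- zoned[zoned$stream == "caption", ]
cat(sprintf(
  "Caption mentions: %d; %.0f%% are visualisation-flagged tools (dictionary base rate %.0f%%).\n",
  nrow(caps), 100 * mean(caps$canonical %in% vis),
  100 * mean(corp$dict_truth$vis)))
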