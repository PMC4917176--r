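# Build the synthetic study corpus: 2,000 JATS-like articles over
# 2000-2013 with gold annotations, and summarise its partitions the way a
# corpus overview table would.

source("analysis/00_common.R")

corp <- study_corpus()
parts <- partition_corpus(corp$articles, corp$catalog)

overview <- bind_rows(lapply(names(parts), function(p) {
  s <- corpus_summary(parts[[p]])
  tibble::tibble(corpus = p, journals = s$n_journals, documents = s$n_docs)
}))
write_tsv(overview, file.path(RESULTS, "corpus_overview.tsv"))
print(overview)

cat(sprintf(
  "Corpus: %d articles, %d gold mentions (%d in captions); %d dictionary names.\n",
  length(corp$articles), nrow(corp$gold),
  sum(corp$gold$stream == "caption"),
  nrow(corp$dictionary$entries)))
cat("The bioinformatics partition is a strict subset of biology:",
    all(parts$bioinformatics$doc_ids %in% parts$biology$doc_ids), "\n")
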