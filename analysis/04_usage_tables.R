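# The survey's usage statistics: per-partition means and top-N tables,
# journal proportions, name overlap between partitions, and the long tail.

source("analysis/00_common.R")

corp <- study_corpus()
parts <- partition_corpus(corp$articles, corp$catalog)
dm <- corpus_meta(corp$articles)
mentions <- read_mentions(mentions_path)
u <- aggregate_usage(mentions, parts, dm)

# mean mentions per document per partition
means <- bind_rows(lapply(names(parts), function(p) {
  cells <- u$cells[u$cells$partition == p, ]
  nd <- length(unique(u$docs$doc_id[u$docs$partition == p]))
  tibble::tibble(corpus = p, documents = nd,
                 mentions = sum(cells$mention_count),
                 mean_per_doc = mean_mentions_per_document(
                   sum(cells$mention_count), nd))
}))
write_tsv(means, file.path(RESULTS, "mention_means.tsv"))
print(means)

# top-10 tables at both counting levels for every partition
tops <- bind_rows(lapply(names(parts), function(p) {
  bind_rows(
    mutate(top_resources(u, p, "mention", 10), level = "mention",
           corpus = p),
    mutate(top_resources(u, p, "document", 10), level = "document",
           corpus = p))
}))
write_tsv(tops, file.path(RESULTS, "top_resources.tsv"))
print(filter(tops, corpus == "bioinformatics"))

# journal proportions (all journals pass the floor at this corpus size)
jp <- journal_proportions(u, min_articles = 50L)
write_tsv(jp, file.path(RESULTS, "journal_proportions.tsv"))
print(jp)

# name overlap between the sub-corpora
ov <- name_overlap(u)
write_tsv(ov$per_partition, file.path(RESULTS, "name_overlap.tsv"))
print(ov$per_partition)
cat("bioinformatics-only names:",
    ov$per_partition$n_unique[ov$per_partition$partition == "bioinformatics"],
    "(strict subset of biology, so necessarily 0)\n")

# long-tail structure
lt <- long_tail_summary(u, "full")
write_tsv(tibble::as_tibble(lt[1:6]), file.path(RESULTS, "long_tail.tsv"))
cat(sprintf(
  "%d names; %.0f%% singletons carrying %.0f%% of document mentions; top 5%% of names (%d) carry %.0f%%.\n",
  lt$n_resources, 100 * lt$singleton_fraction,
  100 * lt$singleton_mention_share, lt$top_5pct_names,
  100 * lt$top_5pct_share))
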