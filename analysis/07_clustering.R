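# Cluster journals by the resources they mention (and resources by the
# journals mentioning them) on components 2-3 of an SVD of the raw
# document-level count matrix; component 1 is scale and is dropped.

source("analysis/00_common.R")

corp <- study_corpus()
parts <- partition_corpus(corp$articles, corp$catalog)
dm <- corpus_meta(corp$articles)
mentions <- read_mentions(mentions_path)
u <- aggregate_usage(mentions, parts, dm)

m <- build_count_matrix(u, "full")
cat(sprintf("Count matrix: %d resources x %d journals, %d non-zeros.\n",
            nrow(m), ncol(m), Matrix::nnzero(m)))

pj <- svd_project(m, k = 3)
write_tsv(pj$coords, file.path(RESULTS, "journal_projection.tsv"))
vf <- variance_explained(pj)
cat(sprintf(
  "Component 1 (scale, dropped) carries %.0f%% of the variation; components 2-3 carry %.0f%%.\n",
  100 * vf[1], 100 * sum(vf[2:3])))

pr <- svd_project(m, k = 3, transpose = TRUE)
write_tsv(head(arrange(pr$coords, -abs(comp2)), 200),
          file.path(RESULTS, "resource_projection.tsv"))
jsonlite::write_json(
  list(singular_values = pj$singular_values,
       variance_fractions = vf),
  file.path(RESULTS, "svd_summary.json"), auto_unbox = TRUE, digits = NA)
print(pj$coords)
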