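# Temporal analyses: relative usage in the yearly top-100 pool, Year0
# normalisation with random-walk significance bounds, the year-over-year
# change score, and persistence runs of medium-usage resources.

source("analysis/00_common.R")

corp <- study_corpus()
parts <- partition_corpus(corp$articles, corp$catalog)
dm <- corpus_meta(corp$articles)
mentions <- read_mentions(mentions_path)
u <- aggregate_usage(mentions, parts, dm)
years <- corp$config$years

ser <- relative_usage_series(u, "full", years)
write_tsv(ser, file.path(RESULTS, "relative_usage_series.tsv"))

tr <- trend_significance(u, "full", years)
write_tsv(tr$envelope$bounds, file.path(RESULTS, "randomwalk_bounds.tsv"))
write_tsv(tr$flags, file.path(RESULTS, "trend_flags.tsv"))
cat(sprintf("Envelope sigma = %.3f; %d resources exit the upper bound.\n",
            tr$envelope$sigma, sum(tr$flags$exits_upper)))
cat("Planted growing resource", corp$planted$grow, "flagged:",
    tr$flags$exits_upper[tr$flags$canonical == corp$planted$grow], "\n")

ds <- delta_sigma_table(ser)
write_tsv(arrange(ds, -delta_sigma), file.path(RESULTS, "delta_sigma.tsv"))
print(head(arrange(ds, -delta_sigma), 10))

ps <- persistence_set(u, "full", start_year = min(years),
                      end_year = max(years))
write_tsv(ps, file.path(RESULTS, "persistence.tsv"))
cat(sprintf("%d persistent resources (unbroken runs, none in %d); %d still current in %d.\n",
            nrow(ps), min(years), sum(ps$current), max(years)))
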