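# Shared setup for the analysis drivers: one seed, one corpus, one place
# for outputs. Each numbered script can be run on its own; the corpus and
# extracted mentions are cached under results/ so later steps reuse them.

suppressPackageStartupMessages({
  library(resmine)
  library(dplyr)
  library(readr)
})

STUDY_SEED <- 101L
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

study_corpus <- function() {
  generate_corpus(generator_config(seed = STUDY_SEED))
}

mentions_path <- file.path(RESULTS, "mentions_filtered.tsv")

# mentions are persisted with the rule set flattened to a comma list;
# missing values round-trip as empty fields so that a resource literally
# named "NA" (acronym initials) survives re-reading
write_mentions <- function(m, path) {
  m$rules <- vapply(m$rules, paste, character(1), collapse = ",")
  write_tsv(m, path, na = "")
}

read_mentions <- function(path) {
  m <- read_tsv(path, show_col_types = FALSE, na = "",
                col_types = cols(rules = col_character(),
                                 .default = col_guess()))
  m$rules <- lapply(strsplit(m$rules, ",", fixed = TRUE), as.integer)
  m
}
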