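#!/usr/bin/env Rscript
# Stage 3: climbing assay.
#
# Pooled pass fractions per genotype at each assay age and the relative
# reduction of the A30P group with the control set to 100% ability.

suppressPackageStartupMessages(library(flycourt))

trials <- read_climbing("results/climbing.csv")
rows <- list()
for (age in sort(unique(trials$age_days))) {
  s_ctrl <- climbing_score(trials, "control", age_days = age)
  s_pd <- climbing_score(trials, "a30p", age_days = age)
  red <- climbing_reduction_pct(s_pd, s_ctrl)
  cat(sprintf("day %2d: control %.2f, a30p %.2f -> %.1f%% reduction\n",
              age, s_ctrl, s_pd, red))
  rows[[length(rows) + 1L]] <- tibble::tibble(
    age_days = age, score_ctrl = s_ctrl, score_pd = s_pd,
    reduction_pct = red)
}
readr::write_csv(dplyr::bind_rows(rows), "results/climbing_scores.csv")
cat("wrote results/climbing_scores.csv\n")
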