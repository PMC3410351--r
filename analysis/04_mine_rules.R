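#!/usr/bin/env Rscript
# Stage 4: rule mining.
#
# Learns all qualifying "if then" rules (probability >= 0.8, support >= 2,
# conjunctions of up to two conditions on distinct features) over the
# eight per-fly features of the simulated cohort, then assembles the
# necessary-and-sufficient ("if and only if") rule set by greedy forward
# selection and evaluates it on the cohort.

suppressPackageStartupMessages(library(flycourt))

vectors <- suppressWarnings(readr::read_csv(
  "results/parameter_vectors.csv",
  col_types = readr::cols(), progress = FALSE))

rt <- mine_rules(vectors)
print(rt)

sel <- select_iff_ruleset(rt, vectors, name = "simulated-cohort-iff")
print(sel$rule_set)
print(sel$report)

write_ruleset(sel$rule_set, "results/iff_rules.json")
jsonlite::write_json(unclass(sel$report), "results/iff_report.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/iff_rules.json, results/iff_report.json\n")
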