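#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# 28 control (Oregon-R-like) and 28 A30P couples observed for up to 600 s
# (copulation-truncated), plus climbing trials at day 6 (no deficit
# expected) and day 21 (PD deficit expressed). Outputs: bout-level session
# CSV and the two climbing tables under results/.

suppressPackageStartupMessages(library(flycourt))

seed <- 2012
dir.create("results", showWarnings = FALSE)

sessions <- generate_sessions(generator_config(n_per_group = 28,
                                               seed = seed))
write_sessions(sessions, "results/sessions.csv")
cat(sprintf("wrote %d sessions (%d events) to results/sessions.csv\n",
            length(sessions),
            sum(vapply(sessions, function(s) nrow(s$events), integer(1)))))

# day 6: both genotypes climb equally well; day 21: 28% relative deficit
climb <- dplyr::bind_rows(
  generate_climbing(0.9, 0.9, n_vials = 5, flies_per_vial = 10,
                    seed = seed + 1, age_days = 6),
  generate_climbing(0.9, 0.648, n_vials = 5, flies_per_vial = 10,
                    seed = seed + 2, age_days = 21)
)
write_climbing(climb, "results/climbing.csv")
cat(sprintf("wrote %d climbing vials to results/climbing.csv\n",
            nrow(climb)))
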