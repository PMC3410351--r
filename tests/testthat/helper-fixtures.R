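# Small in-code fixtures shared across test files.

# One-couple session with arbitrary bouts.
make_session <- function(id = "c1", genotype = "control",
                         events = data.frame(element = "orientation",
                                             start_s = 0, end_s = 10),
                         cap = 600) {
  courtship_session(id, genotype, events, observation_cap_s = cap)
}

# A bare parameter-vector row with overridable fields; defaults chosen so
# that no published rule fires (nse 20, total 600, atc 2, licking 10).
make_vector <- function(couple_id = "x", genotype = "control",
                        orientation_time_s = 200, vibration_time_s = 100,
                        licking_count = 10, atc_count = 2,
                        copulated = FALSE, nse_count = 20,
                        total_time_s = 600) {
  tibble::tibble(
    couple_id = couple_id, genotype = genotype,
    healthy = genotype == "control",
    orientation_time_s = orientation_time_s,
    vibration_time_s = vibration_time_s,
    licking_count = as.integer(licking_count),
    atc_count = as.integer(atc_count),
    copulated = copulated, nse_count = as.integer(nse_count),
    total_time_s = total_time_s, sfi = 1 / (nse_count + 1)
  )
}

# Tiny labeled datasets for mining tests. Only the listed features are
# mined; remaining columns are fillers.
toy_separable <- function() {
  # healthy iff nse_count <= 5, 8 rows
  nse <- c(1, 3, 4, 5, 9, 12, 20, 33)
  healthy <- nse <= 5
  dplyr::bind_rows(lapply(seq_along(nse), function(i) {
    make_vector(sprintf("t%02d", i),
                genotype = if (healthy[i]) "control" else "a30p",
                nse_count = nse[i])
  }))
}

toy_noisy <- function() {
  # 8 rows, 3 informative features, overlapping classes
  nse <- c(2, 4, 6, 9, 3, 11, 14, 18)
  lick <- c(30, 25, 12, 8, 28, 6, 22, 4)
  cop <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  gt <- c("control", "control", "control", "control",
          "a30p", "a30p", "a30p", "a30p")
  dplyr::bind_rows(lapply(1:8, function(i) {
    make_vector(sprintf("n%02d", i), genotype = gt[i], nse_count = nse[i],
                licking_count = lick[i], copulated = cop[i])
  }))
}

toy_tiny3 <- function() {
  # 6 rows x 3 features for max_conjunction = 3 oracle checks
  nse <- c(2, 5, 8, 3, 9, 12)
  atc <- c(3, 1, 3, 2, 1, 0)
  cop <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  gt <- c("control", "control", "control", "a30p", "a30p", "a30p")
  dplyr::bind_rows(lapply(1:6, function(i) {
    make_vector(sprintf("y%02d", i), genotype = gt[i], nse_count = nse[i],
                atc_count = atc[i], copulated = cop[i])
  }))
}

# Canonical string form of a rule for set comparison.
rule_to_string <- function(r) {
  conds <- sort(vapply(r$conditions, function(cond) {
    sprintf("%s[%.10g,%.10g]", cond$feature, cond$low, cond$high)
  }, character(1)))
  sprintf("%s|%s|p=%.10g|s=%d", r$predicted,
          paste(conds, collapse = "&"), r$probability, r$support)
}

rule_table_strings <- function(rt) {
  sort(vapply(as_rule_list(rt), rule_to_string, character(1)))
}
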