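# Independent brute-force oracles for the rule learner: plain nested loops
# over explicitly enumerated conditions and conjunctions, no shared code
# with the implementation.

oracle_feature_kind <- c(
  orientation_time_s = "continuous", vibration_time_s = "continuous",
  licking_count = "count", atc_count = "count", copulated = "boolean",
  nse_count = "count", total_time_s = "continuous", sfi = "continuous"
)

oracle_candidates <- function(df, features) {
  cands <- list()
  for (f in features) {
    u <- sort(unique(as.numeric(df[[f]])))
    if (oracle_feature_kind[[f]] == "boolean") {
      for (val in u) {
        cands[[length(cands) + 1L]] <- list(feature = f, low = val,
                                            high = val)
      }
    } else {
      for (i in seq_along(u)) {
        for (j in i:length(u)) {
          cands[[length(cands) + 1L]] <- list(feature = f, low = u[i],
                                              high = u[j])
        }
      }
    }
  }
  cands
}

# All rules passing the thresholds, then superset pruning; returns a sorted
# character vector in the same canonical form as rule_to_string().
oracle_mine <- function(df, features, min_prob = 0.8, min_supp = 2,
                        max_conj = 2) {
  cands <- oracle_candidates(df, features)
  n <- nrow(df)
  match_row <- function(cond, r) {
    x <- as.numeric(df[[cond$feature]][r])
    x >= cond$low && x <= cond$high
  }
  rules <- list()
  for (size in seq_len(max_conj)) {
    for (cs in utils::combn(seq_along(cands), size, simplify = FALSE)) {
      feats <- vapply(cands[cs], `[[`, character(1), "feature")
      if (anyDuplicated(feats)) next
      hit <- vapply(seq_len(n), function(r) {
        all(vapply(cands[cs], match_row, logical(1), r = r))
      }, logical(1))
      supp <- sum(hit)
      if (supp < min_supp) next
      for (label in c("healthy", "sick")) {
        p <- if (label == "healthy") mean(df$healthy[hit]) else
          mean(!df$healthy[hit])
        if (p >= min_prob) {
          rules[[length(rules) + 1L]] <- list(conds = cs, label = label,
                                              prob = p, supp = supp)
        }
      }
    }
  }
  keep <- rep(TRUE, length(rules))
  for (a in seq_along(rules)) {
    for (b in seq_along(rules)) {
      if (a == b) next
      ra <- rules[[a]]; rb <- rules[[b]]
      if (rb$label == ra$label && length(rb$conds) < length(ra$conds) &&
          all(rb$conds %in% ra$conds) && rb$prob >= ra$prob) {
        keep[a] <- FALSE
        break
      }
    }
  }
  out <- vapply(rules[keep], function(r) {
    conds <- sort(vapply(cands[r$conds], function(cond) {
      sprintf("%s[%.10g,%.10g]", cond$feature, cond$low, cond$high)
    }, character(1)))
    sprintf("%s|%s|p=%.10g|s=%d", r$label, paste(conds, collapse = "&"),
            r$prob, as.integer(r$supp))
  }, character(1))
  sort(out)
}

# Best achievable two-sided success rate of any disjunction of up to
# `max_size` healthy-predicting rules from a rule_table, by exhaustive
# subset enumeration over distinct coverage patterns.
oracle_best_success <- function(rt, df, max_size = 7) {
  h <- which(rt$rules$predicted == "healthy")
  rl <- as_rule_list(rt, h)
  n <- nrow(df)
  cov <- vapply(rl, function(r) {
    vapply(seq_len(n), function(i) {
      all(vapply(r$conditions, function(cond) {
        x <- as.numeric(df[[cond$feature]][i])
        x >= cond$low && x <= cond$high
      }, logical(1)))
    }, logical(1))
  }, logical(n))
  cov <- unique(t(cov))  # distinct coverage patterns only
  m <- nrow(cov)
  best <- sum(!df$healthy) / n  # empty disjunction: all predicted sick
  for (size in seq_len(min(max_size, m))) {
    for (sub in utils::combn(seq_len(m), size, simplify = FALSE)) {
      pred_healthy <- colSums(cov[sub, , drop = FALSE]) > 0
      s <- sum(pred_healthy == df$healthy) / n
      if (s > best) best <- s
    }
  }
  best
}
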