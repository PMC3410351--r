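test_that("candidate conditions enumerate contiguous runs and observed endpoints", {
  df <- dplyr::bind_rows(lapply(c(1, 2, 3), function(k) {
    make_vector(paste0("c", k), nse_count = k)
  }))
  cc <- candidate_conditions(df, features = "nse_count")
  expect_equal(nrow(cc), 6)
  expect_setequal(paste(cc$low, cc$high),
                  c("1 1", "2 2", "3 3", "1 2", "2 3", "1 3"))
  # Boolean feature: exactly the two point conditions
  df$copulated <- c(TRUE, FALSE, TRUE)
  cb <- candidate_conditions(df, features = "copulated")
  expect_equal(nrow(cb), 2)
  expect_equal(cb$low, cb$high)
  # matches the independent enumeration on a mixed feature set
  noisy <- toy_noisy()
  cc2 <- candidate_conditions(noisy,
                              features = c("nse_count", "licking_count",
                                           "copulated", "sfi"))
  expect_equal(nrow(cc2),
               length(oracle_candidates(noisy,
                                        c("nse_count", "licking_count",
                                          "copulated", "sfi"))))
})

test_that("binned mode caps continuous endpoints at the bin boundaries", {
  set.seed(5)
  df <- dplyr::bind_rows(lapply(1:100, function(i) {
    make_vector(paste0("b", i), orientation_time_s = runif(1, 0, 500))
  }))
  cc <- candidate_conditions(df, mining_config(n_bins = 8),
                             features = "orientation_time_s")
  expect_lte(nrow(cc), 9 * 10 / 2)  # at most C(9,2)+9 intervals
  # counts remain exhaustive over observed values regardless of n
  df$nse_count <- rep(c(1L, 2L, 3L), length.out = 100)
  cn <- candidate_conditions(df, mining_config(), features = "nse_count")
  expect_equal(nrow(cn), 6)
})

test_that("mined rules on separable data include the separating rule", {
  df <- toy_separable()
  rt <- mine_rules(df, features = "nse_count")
  strs <- rule_table_strings(rt)
  expect_true(any(grepl("healthy\\|nse_count\\[1,5\\]\\|p=1\\|s=4", strs)))
  sel <- select_iff_ruleset(rt, df)
  expect_equal(sel$report$success_rate, 1)
  expect_equal(sel$report$improvement_factor, Inf)
})

test_that("mine_rules agrees exactly with the brute-force oracle", {
  cases <- list(
    list(df = toy_separable(), feats = "nse_count", conj = 2),
    list(df = toy_noisy(), feats = c("nse_count", "licking_count"),
         conj = 2),
    list(df = toy_noisy(),
         feats = c("nse_count", "licking_count", "copulated", "sfi"),
         conj = 2),
    list(df = toy_tiny3(), feats = c("nse_count", "atc_count", "copulated"),
         conj = 3)
  )
  for (cs in cases) {
    rt <- mine_rules(cs$df, mining_config(max_conjunction = cs$conj),
                     features = cs$feats)
    expect_identical(rule_table_strings(rt),
                     oracle_mine(cs$df, cs$feats, max_conj = cs$conj))
  }
})

test_that("raising thresholds never enlarges the rule list", {
  df <- toy_noisy()
  feats <- c("nse_count", "licking_count", "copulated")
  base <- rule_table_strings(mine_rules(df, mining_config(), feats))
  for (mp in c(0.85, 0.9, 1.0)) {
    higher <- rule_table_strings(
      mine_rules(df, mining_config(min_probability = mp), feats))
    # stricter rules differ only by pruning context; compare condition sets
    strip <- function(x) sub("\\|p=.*$", "", x)
    expect_true(all(strip(higher) %in% strip(base)))
    expect_lte(length(higher), length(base))
  }
  for (msup in c(3, 4)) {
    higher <- mine_rules(df, mining_config(min_support = msup), feats)
    expect_lte(n_rules(higher), n_rules(mine_rules(df, mining_config(),
                                                   feats)))
    expect_true(all(higher$rules$support >= msup))
  }
})

test_that("mining is invariant under row permutation and audits clean", {
  df <- toy_noisy()
  feats <- c("nse_count", "licking_count", "copulated")
  rt <- mine_rules(df, features = feats)
  set.seed(9)
  rt_perm <- mine_rules(df[sample(nrow(df)), ], features = feats)
  expect_identical(rule_table_strings(rt), rule_table_strings(rt_perm))
  aud <- audit_rules(rt, df)
  expect_true(all(aud$consistent))
  expect_error(mine_rules(df[df$healthy, ], features = feats),
               "both healthy and sick")
})

test_that("greedy if-and-only-if selection matches exhaustive subset search", {
  cases <- list(
    list(df = toy_separable(), feats = "nse_count"),
    list(df = toy_tiny3(), feats = c("nse_count", "atc_count", "copulated"))
  )
  for (cs in cases) {
    rt <- mine_rules(cs$df, features = cs$feats)
    sel <- select_iff_ruleset(rt, cs$df)
    expect_equal(sel$report$success_rate,
                 oracle_best_success(rt, cs$df, max_size = 7))
    # every selected rule predicts healthy and audits clean
    aud <- audit_rules(sel$rule_set$rules, cs$df)
    expect_true(all(aud$consistent))
  }
})

test_that("duplicating every row doubles supports (absolute thresholds)", {
  df <- toy_separable()
  rt1 <- mine_rules(df, mining_config(min_support = 2),
                    features = "nse_count")
  df2 <- dplyr::bind_rows(df, df)
  rt2 <- mine_rules(df2, mining_config(min_support = 4),
                    features = "nse_count")
  s1 <- sub("s=(\\d+)$", "", rule_table_strings(rt1))
  s2 <- sub("s=(\\d+)$", "", rule_table_strings(rt2))
  expect_identical(s1, s2)
  expect_equal(sort(rt2$rules$support), sort(2L * rt1$rules$support))
})

test_that("the full pipeline mines a usable rule set from a synthetic cohort", {
  sessions <- generate_sessions(generator_config(n_per_group = 28, seed = 1))
  vectors <- parameter_vectors(sessions)
  rt <- mine_rules(vectors)
  expect_gt(n_rules(rt), 0)
  sel <- select_iff_ruleset(rt, vectors)
  expect_gte(sel$report$success_rate, 0.7)
  expect_true(all(audit_rules(sel$rule_set$rules, vectors)$consistent))
  # determinism: same cohort, same result
  sel2 <- select_iff_ruleset(mine_rules(vectors), vectors)
  expect_equal(sel2$report, sel$report)
})
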