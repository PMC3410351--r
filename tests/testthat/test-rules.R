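test_that("condition membership is inclusive at both endpoints", {
  c_nse <- rule_condition("nse_count", 3, 5)
  expect_true(condition_holds(make_vector(nse_count = 4), c_nse))
  expect_true(condition_holds(make_vector(nse_count = 3), c_nse))
  expect_true(condition_holds(make_vector(nse_count = 5), c_nse))
  expect_false(condition_holds(make_vector(nse_count = 6), c_nse))

  c_atc <- rule_condition("atc_count", 3, 3, kind = "exact_count")
  expect_false(condition_holds(make_vector(atc_count = 2), c_atc))
  expect_true(condition_holds(make_vector(atc_count = 3), c_atc))

  expect_error(condition_holds(list(foo = 1), c_nse), "unknown feature")
  expect_error(rule_condition("nse_count", 5, 3))
  expect_error(rule_condition("not_a_feature", 1, 2))
})

test_that("the classifier is a disjunction: healthy iff any rule fires", {
  rs <- table1_rules()
  # satisfies condition (iii) only: atc = 3
  expect_equal(classify_fly(make_vector(atc_count = 3), rs), "healthy")
  # satisfies nothing
  expect_equal(classify_fly(make_vector(), rs), "sick")
  # missing features error out before classification
  expect_error(classify_fly(tibble::tibble(nse_count = 4), rs),
               "lacks feature")
})

test_that("the published rule set encodes seven rules with disjoint NSE intervals", {
  rs <- table1_rules()
  expect_length(rs$rules, 7)
  sizes <- vapply(rs$rules, function(r) length(r$conditions), integer(1))
  expect_equal(sort(sizes), c(1, 1, 1, 1, 2, 2, 2))
  nse_iv <- list()
  for (r in rs$rules) {
    for (cond in r$conditions) {
      if (cond$feature == "nse_count") {
        nse_iv[[length(nse_iv) + 1L]] <- c(cond$low, cond$high)
      }
    }
  }
  expect_length(nse_iv, 4)
  expect_setequal(vapply(nse_iv, paste, character(1), collapse = "-"),
                  c("3-5", "1-2", "6-17", "35-51"))
  # pairwise disjoint
  for (a in seq_along(nse_iv)) {
    for (b in seq_along(nse_iv)) {
      if (a >= b) next
      expect_true(nse_iv[[a]][2] < nse_iv[[b]][1] ||
                    nse_iv[[b]][2] < nse_iv[[a]][1])
    }
  }
})

test_that("rule sets round-trip through JSON", {
  rs <- table1_rules()
  f <- withr::local_tempfile(fileext = ".json")
  write_ruleset(rs, f)
  back <- read_ruleset(f)
  expect_equal(back, rs)
  expect_error(rule_set(list(courtship_rule(
    rule_condition("nse_count", 0, 2), "sick"))), "predict 'healthy'")
})

test_that("evaluate reports the published statistics on the synthetic cohort", {
  cohort <- synthetic_table1_cohort()
  expect_equal(nrow(cohort), 56)
  expect_equal(sum(cohort$healthy), 28)
  rep <- evaluate_ruleset(cohort, table1_rules())
  expect_equal(rep$n_correct, 46)
  expect_equal(rep$success_rate, 46 / 56)
  expect_equal(round(rep$success_rate, 3), 0.821)
  expect_equal(rep$p_healthy_given_hit, 23 / 28)
  expect_equal(rep$p_sick_given_miss, 23 / 28)
  expect_equal(rep$improvement_factor, 2.8)
})

test_that("improvement factor is chance error over observed error", {
  # success 0.5 at prior 0.5 -> no improvement
  v <- dplyr::bind_rows(
    make_vector("a", genotype = "control", nse_count = 4),
    make_vector("b", genotype = "a30p", nse_count = 4))
  rs <- rule_set(courtship_rule(rule_condition("nse_count", 3, 5), "healthy"))
  rep <- evaluate_ruleset(v, rs)
  expect_equal(rep$success_rate, 0.5)
  expect_equal(rep$improvement_factor, 1)
  # perfect classification -> +Inf sentinel
  v2 <- dplyr::bind_rows(
    make_vector("a", genotype = "control", nse_count = 4),
    make_vector("b", genotype = "a30p", nse_count = 30))
  rep2 <- evaluate_ruleset(v2, rs)
  expect_equal(rep2$success_rate, 1)
  expect_equal(rep2$improvement_factor, Inf)
  # improvement factor at prior p uses the chance error min(p, 1-p)
  rep3 <- evaluate_ruleset(v, rs, prior = 0.8)
  expect_equal(rep3$improvement_factor, 0.2 / 0.5)
})

test_that("adding a rule can only flip predictions from sick to healthy", {
  set.seed(11)
  cohort <- synthetic_table1_cohort()
  cohort$nse_count <- sample(0:40, 56, replace = TRUE)
  cohort$sfi <- sfi(cohort$nse_count)
  rs7 <- table1_rules()
  for (k in 1:6) {
    rs_k <- rule_set(rs7$rules[seq_len(k)])
    rs_k1 <- rule_set(rs7$rules[seq_len(k + 1)])
    pred_k <- vapply(seq_len(56), function(i)
      classify_fly(cohort[i, ], rs_k), character(1))
    pred_k1 <- vapply(seq_len(56), function(i)
      classify_fly(cohort[i, ], rs_k1), character(1))
    expect_true(all(pred_k1[pred_k == "healthy"] == "healthy"))
  }
})

test_that("evaluate is invariant under dataset permutation", {
  cohort <- synthetic_table1_cohort()
  shuffled <- cohort[sample(nrow(cohort)), ]
  expect_equal(evaluate_ruleset(shuffled, table1_rules()),
               evaluate_ruleset(cohort, table1_rules()))
})
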