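# Interval/count conditions, conjunctive rules and the "if and only if"
# rule-set classifier.
#
# A Condition is an inclusive interval [low, high] on one of the eight
# per-fly features (exact counts are intervals with low == high). A Rule is
# a conjunction of 1+ conditions predicting "healthy" or "sick". A RuleSet
# is a disjunction of healthy-predicting rules used as a
# necessary-and-sufficient classifier: a fly satisfying at least one rule's
# conjunction is called healthy, otherwise sick.

#' Construct a rule condition
#'
#' @param feature One of [parameter_features].
#' @param low,high Inclusive interval bounds (`low <= high`).
#' @param kind `"interval"` or `"exact_count"`; defaults to `"exact_count"`
#'   when `low == high` and both are whole numbers, else `"interval"`.
#' @param average Optional annotation (a reported within-interval average);
#'   stored as metadata only, never used in evaluation.
#' @return A list of class `rule_condition`.
#' @export
rule_condition <- function(feature, low, high, kind = NULL, average = NULL) {
  stopifnot(feature %in% parameter_features, is.numeric(low), is.numeric(high),
            length(low) == 1L, length(high) == 1L, low <= high)
  if (is.null(kind)) {
    kind <- if (low == high && low == round(low)) "exact_count" else "interval"
  }
  kind <- match.arg(kind, c("interval", "exact_count"))
  if (kind == "exact_count" && !(low == high && low == round(low))) {
    stop("exact_count conditions require integer low == high", call. = FALSE)
  }
  structure(list(feature = feature, kind = kind,
                 low = as.numeric(low), high = as.numeric(high),
                 average = average),
            class = "rule_condition")
}

#' Does a parameter vector satisfy a condition?
#'
#' Interval membership with both endpoints inclusive. Logical features
#' (`copulated`) are coerced to 0/1.
#'
#' @param v A one-row parameter vector (see [parameter_vector()]) or a named
#'   list containing the condition's feature.
#' @param cond A [rule_condition()].
#' @return `TRUE` or `FALSE`.
#' @export
condition_holds <- function(v, cond) {
  if (!cond$feature %in% names(v)) {
    stop(sprintf("unknown feature '%s'", cond$feature), call. = FALSE)
  }
  x <- as.numeric(v[[cond$feature]])
  stopifnot(length(x) == 1L, is.finite(x))
  x >= cond$low && x <= cond$high
}

#' Construct a conjunctive rule
#'
#' @param conditions List of [rule_condition()]s (a conjunction; all must
#'   hold for the rule to fire). Conditions in one rule address distinct
#'   features.
#' @param predicted `"healthy"` or `"sick"`.
#' @param probability Empirical P(predicted label | conjunction holds), if
#'   known.
#' @param support Number of cases satisfying the conjunction, if known.
#' @return A list of class `courtship_rule`.
#' @export
courtship_rule <- function(conditions, predicted,
                           probability = NA_real_, support = NA_integer_) {
  if (inherits(conditions, "rule_condition")) conditions <- list(conditions)
  stopifnot(length(conditions) >= 1L,
            all(vapply(conditions, inherits, logical(1), "rule_condition")))
  feats <- vapply(conditions, `[[`, character(1), "feature")
  if (anyDuplicated(feats)) {
    stop("conditions within a rule must address distinct features",
         call. = FALSE)
  }
  predicted <- match.arg(predicted, c("healthy", "sick"))
  stopifnot(is.na(probability) || (probability >= 0 && probability <= 1))
  structure(list(conditions = conditions, predicted = predicted,
                 probability = as.numeric(probability),
                 support = as.integer(support)),
            class = "courtship_rule")
}

#' Does a rule's conjunction hold for a parameter vector?
#'
#' @param v One-row parameter vector.
#' @param rule A [courtship_rule()].
#' @return `TRUE` iff every condition holds.
#' @export
rule_matches <- function(v, rule) {
  all(vapply(rule$conditions, function(cond) condition_holds(v, cond),
             logical(1)))
}

#' Construct a rule set
#'
#' A disjunction of healthy-predicting rules interpreted as necessary and
#' sufficient for health: satisfied => healthy, unsatisfied => sick.
#'
#' @param rules Non-empty list of [courtship_rule()]s, all predicting
#'   `"healthy"`.
#' @param name Label for reports.
#' @return A list of class `rule_set`.
#' @export
rule_set <- function(rules, name = "ruleset") {
  if (inherits(rules, "courtship_rule")) rules <- list(rules)
  stopifnot(length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "courtship_rule")))
  if (!all(vapply(rules, `[[`, character(1), "predicted") == "healthy")) {
    stop("all rules in a rule set must predict 'healthy'", call. = FALSE)
  }
  structure(list(name = name, rules = rules), class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> '%s': %d rules (healthy iff any holds)\n",
              x$name, length(x$rules)))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    conds <- vapply(r$conditions, function(cond) {
      if (cond$kind == "exact_count") {
        sprintf("%s = %g", cond$feature, cond$low)
      } else {
        sprintf("%s in [%g, %g]", cond$feature, cond$low, cond$high)
      }
    }, character(1))
    extra <- if (!is.na(r$probability)) {
      sprintf("  (p=%.3f, support=%d)", r$probability, r$support)
    } else ""
    cat(sprintf("  (%d) %s%s\n", i, paste(conds, collapse = " & "), extra))
  }
  invisible(x)
}

#' Classify a fly with a rule set
#'
#' `"healthy"` iff at least one rule's conjunction is satisfied, `"sick"`
#' otherwise.
#'
#' @param v One-row parameter vector with all eight [parameter_features].
#' @param rs A [rule_set()].
#' @return `"healthy"` or `"sick"`.
#' @export
classify_fly <- function(v, rs) {
  missing <- setdiff(unique(unlist(lapply(rs$rules, function(r) {
    vapply(r$conditions, `[[`, character(1), "feature")
  }))), names(v))
  if (length(missing) > 0L) {
    stop(sprintf("parameter vector lacks feature(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(vapply(rs$rules, function(r) rule_matches(v, r), logical(1)))) {
    "healthy"
  } else {
    "sick"
  }
}

# Logical matrix: rows of `dataset` x rules of `rs`; TRUE where the rule's
# conjunction holds. Vectorized workhorse behind classify/evaluate.
ruleset_match_matrix <- function(dataset, rs) {
  n <- nrow(dataset)
  vapply(rs$rules, function(r) {
    m <- rep(TRUE, n)
    for (cond in r$conditions) {
      if (!cond$feature %in% names(dataset)) {
        stop(sprintf("unknown feature '%s'", cond$feature), call. = FALSE)
      }
      x <- as.numeric(dataset[[cond$feature]])
      m <- m & x >= cond$low & x <= cond$high
    }
    m
  }, logical(n))
}

#' Evaluate a rule set on labeled parameter vectors
#'
#' Applies the necessary-and-sufficient interpretation to every row and
#' reports the confusion counts, the conditional probabilities
#' P(healthy | at least one condition holds) and P(sick | none holds), the
#' success rate and the improvement factor over chance
#' (`min(prior, 1 - prior) / (1 - success_rate)`; with the default prior
#' 0.5 this is the chance error rate divided by the observed error rate).
#'
#' @param dataset Tibble of parameter vectors with a logical `healthy`
#'   label column.
#' @param rs A [rule_set()].
#' @param prior Prior probability that a fly is healthy (default 0.5).
#' @return A list of class `classification_report`: `n_total`, `n_correct`,
#'   `success_rate`, `p_healthy_given_hit`, `p_sick_given_miss`, `prior`,
#'   `improvement_factor`, and the confusion counts `n_hit_healthy`,
#'   `n_hit_sick`, `n_miss_healthy`, `n_miss_sick`. A perfect classifier
#'   reports `improvement_factor = Inf`.
#' @export
evaluate_ruleset <- function(dataset, rs, prior = 0.5) {
  stopifnot(nrow(dataset) > 0L, "healthy" %in% names(dataset),
            is.logical(dataset$healthy), !anyNA(dataset$healthy),
            prior > 0, prior < 1)
  mm <- ruleset_match_matrix(dataset, rs)
  hit <- if (is.matrix(mm)) rowSums(mm) > 0L else mm
  healthy <- dataset$healthy
  n <- nrow(dataset)
  n_correct <- sum(hit == healthy)
  success <- n_correct / n
  impf <- if (success >= 1) Inf else min(prior, 1 - prior) / (1 - success)
  structure(list(
    n_total = n,
    n_correct = n_correct,
    success_rate = success,
    p_healthy_given_hit = if (any(hit)) mean(healthy[hit]) else NA_real_,
    p_sick_given_miss = if (any(!hit)) mean(!healthy[!hit]) else NA_real_,
    prior = prior,
    improvement_factor = impf,
    n_hit_healthy = sum(hit & healthy),
    n_hit_sick = sum(hit & !healthy),
    n_miss_healthy = sum(!hit & healthy),
    n_miss_sick = sum(!hit & !healthy)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d cases\n", x$n_total))
  cat(sprintf("  success rate:          %.3f (%d/%d)\n",
              x$success_rate, x$n_correct, x$n_total))
  cat(sprintf("  P(healthy | >=1 rule): %.3f (%d of %d hits)\n",
              x$p_healthy_given_hit, x$n_hit_healthy,
              x$n_hit_healthy + x$n_hit_sick))
  cat(sprintf("  P(sick | no rule):     %.3f (%d of %d misses)\n",
              x$p_sick_given_miss, x$n_miss_sick,
              x$n_miss_healthy + x$n_miss_sick))
  cat(sprintf("  improvement factor:    %.3f (prior %.3f)\n",
              x$improvement_factor, x$prior))
  invisible(x)
}

#' Read / write rule sets as JSON
#'
#' Schema: `{name, rules: [{conditions: [{feature, kind, low, high,
#' average?}], predicted, probability?, support?}]}`. The optional
#' `average` annotations are carried through as metadata.
#'
#' @param path File path.
#' @return `read_ruleset()` returns a [rule_set()].
#' @export
read_ruleset <- function(path) {
  stopifnot(file.exists(path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(!is.null(j$rules), length(j$rules) >= 1L)
  rules <- lapply(j$rules, function(jr) {
    conds <- lapply(jr$conditions, function(jc) {
      rule_condition(jc$feature, jc$low, jc$high, kind = jc$kind,
                     average = jc$average)
    })
    courtship_rule(conds, jr$predicted,
                   probability = jr$probability %||% NA_real_,
                   support = jr$support %||% NA_integer_)
  })
  rule_set(rules, name = j$name %||% "ruleset")
}

#' @rdname read_ruleset
#' @param rs A [rule_set()].
#' @export
write_ruleset <- function(rs, path) {
  j <- list(
    name = rs$name,
    rules = lapply(rs$rules, function(r) {
      out <- list(
        conditions = lapply(r$conditions, function(cond) {
          jc <- list(feature = cond$feature, kind = cond$kind,
                     low = cond$low, high = cond$high)
          if (!is.null(cond$average)) jc$average <- cond$average
          jc
        }),
        predicted = r$predicted
      )
      if (!is.na(r$probability)) out$probability <- r$probability
      if (!is.na(r$support)) out$support <- r$support
      out
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' The published seven-condition diagnostic rule set
#'
#' The seven interval conditions reported by the study's data-mining
#' analysis of 56 courtship sessions (four of the seven involve the NSE
#' count). Shipped as a JSON fixture; the within-interval "average"
#' annotations are preserved as metadata but never used in classification.
#'
#' @return A [rule_set()] of seven healthy-predicting rules.
#' @export
table1_rules <- function() {
  read_ruleset(system.file("extdata", "table1_rules.json",
                           package = "flycourt", mustWork = TRUE))
}

#' Synthetic 56-couple evaluation cohort
#'
#' The study's raw per-fly recordings are unpublished. This deterministic,
#' synthetic stand-in reproduces the published confusion structure of the
#' seven-condition rule set on 28 healthy + 28 sick flies: 23 of 28 healthy
#' flies satisfy at least one condition (via the NSE-in-3..5 rule) and 23
#' of 28 sick flies satisfy none, so that evaluating [table1_rules()] on it
#' yields success rate 46/56 = 0.821, both conditional probabilities 0.821,
#' and improvement factor 2.8 against a 0.5 prior. Feature values outside
#' the NSE count are fixed at levels that no condition matches.
#'
#' @return Tibble of 56 parameter vectors with `healthy` labels.
#' @export
synthetic_table1_cohort <- function() {
  # nse = 4 hits condition (i) [3,5]; nse = 20 (with total time 600, atc 2,
  # licking 10, vibration 100) escapes all seven conditions.
  mk <- function(id, genotype, nse) {
    tibble::tibble(
      couple_id = id, genotype = genotype, healthy = genotype == "control",
      orientation_time_s = 200, vibration_time_s = 100,
      licking_count = 10L, atc_count = 2L, copulated = FALSE,
      nse_count = as.integer(nse), total_time_s = 600, sfi = sfi(nse)
    )
  }
  dplyr::bind_rows(
    mk(sprintf("h%02d", 1:23), "control", 4),
    mk(sprintf("h%02d", 24:28), "control", 20),
    mk(sprintf("s%02d", 1:23), "a30p", 20),
    mk(sprintf("s%02d", 24:28), "a30p", 4)
  )
}
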