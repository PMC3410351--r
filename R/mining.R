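# Association-rule learning over the eight per-fly features with the
# Boolean health condition as the dependent variable.
#
# The learner enumerates every candidate interval condition per feature,
# every conjunction of conditions on distinct features up to
# max_conjunction, keeps conjunctions whose empirical conditional
# probability and support clear the configured thresholds (for both target
# labels), prunes rules dominated by an equally-or-more-probable shorter
# sub-rule, and finally assembles a necessary-and-sufficient ("if and only
# if") disjunction of healthy-predicting rules by greedy forward selection
# on the two-sided success rate. All iteration orders are fixed; mining is
# fully deterministic.
#
# Exhaustive enumeration on 56 cases yields ~10^6 qualifying rules, so the
# mined set is kept columnar (a rule_table: condition indices + statistics)
# rather than as a list of S3 rule objects; rules materialize on demand.

# Feature typing drives candidate enumeration: counts/booleans enumerate
# contiguous runs of observed values, continuous features enumerate
# observed-value endpoints (exhaustive mode) or equal-frequency bin
# boundaries (binned mode, n > exhaustive_max_n).
feature_kinds <- c(
  orientation_time_s = "continuous", vibration_time_s = "continuous",
  licking_count = "count", atc_count = "count", copulated = "boolean",
  nse_count = "count", total_time_s = "continuous", sfi = "continuous"
)

#' Mining configuration
#'
#' @param min_probability Minimum empirical P(label | conjunction) for a
#'   rule to be reported; must exceed 0.5 (a rule below chance for its
#'   label is not a rule). Default 0.8.
#' @param min_support Minimum number of cases satisfying the conjunction
#'   (absolute count, not a fraction; duplicating every row doubles every
#'   support). Default 2.
#' @param max_conjunction Maximum conditions per rule (1, 2 or 3).
#'   Default 2.
#' @param exhaustive_max_n Exhaustive interval enumeration for continuous
#'   features is used up to this many rows; above it, interval endpoints
#'   come from equal-frequency binning. Default 64.
#' @param n_bins Number of equal-frequency bins in binned mode. Default 8.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(min_probability = 0.8, min_support = 2,
                          max_conjunction = 2, exhaustive_max_n = 64,
                          n_bins = 8) {
  stopifnot(min_probability > 0.5, min_probability <= 1,
            min_support >= 1, max_conjunction %in% 1:3,
            exhaustive_max_n >= 1, n_bins >= 2)
  structure(list(min_probability = min_probability,
                 min_support = as.integer(min_support),
                 max_conjunction = as.integer(max_conjunction),
                 exhaustive_max_n = as.integer(exhaustive_max_n),
                 n_bins = as.integer(n_bins)),
            class = "mining_config")
}

#' Enumerate candidate interval conditions
#'
#' For count and Boolean features: every contiguous run of observed values
#' (Booleans yield exactly the two point conditions). For continuous
#' features: every interval whose endpoints are observed values (exhaustive
#' mode, `nrow <= exhaustive_max_n`) or equal-frequency bin boundaries
#' (binned mode). Deduplicated, in deterministic order (feature, low,
#' high).
#'
#' @param dataset Tibble of parameter vectors.
#' @param cfg A [mining_config()].
#' @param features Features to enumerate over (default all eight).
#' @return Tibble with columns `feature`, `kind`, `low`, `high`.
#' @export
candidate_conditions <- function(dataset, cfg = mining_config(),
                                 features = parameter_features) {
  stopifnot(nrow(dataset) >= 1L, all(features %in% names(dataset)))
  out <- lapply(features, function(f) {
    v <- as.numeric(dataset[[f]])
    fk <- feature_kinds[[f]]
    if (fk == "boolean") {
      u <- sort(unique(v))
      return(tibble::tibble(feature = f, kind = "exact_count",
                            low = u, high = u))
    }
    u <- sort(unique(v))
    if (fk == "continuous" && nrow(dataset) > cfg$exhaustive_max_n) {
      u <- sort(unique(unname(
        stats::quantile(v, probs = seq(0, 1, length.out = cfg$n_bins + 1),
                        type = 1)
      )))
    }
    idx <- which(upper.tri(diag(length(u)), diag = TRUE), arr.ind = TRUE)
    lo <- u[idx[, "row"]]
    hi <- u[idx[, "col"]]
    kind <- ifelse(fk == "count" & lo == hi, "exact_count", "interval")
    tibble::tibble(feature = f, kind = kind, low = lo, high = hi)
  })
  conds <- dplyr::bind_rows(out)
  conds <- dplyr::distinct(conds)
  conds[order(conds$feature, conds$low, conds$high), ]
}

# Logical membership matrix: rows = candidate conditions, cols = dataset
# rows.
condition_matrix <- function(dataset, conds) {
  n <- nrow(dataset)
  m <- matrix(FALSE, nrow = nrow(conds), ncol = n)
  for (f in unique(conds$feature)) {
    ri <- which(conds$feature == f)
    v <- as.numeric(dataset[[f]])
    m[ri, ] <- outer(conds$low[ri], v, `<=`) & outer(conds$high[ri], v, `>=`)
  }
  m
}

# Canonical identity strings of single conditions, vectorized.
cond_labels <- function(conds) {
  sprintf("%s[%.10g,%.10g]", conds$feature, conds$low, conds$high)
}

#' Mine all qualifying "if then" rules
#'
#' Finds every conjunction of up to `max_conjunction` candidate conditions
#' on distinct features whose empirical conditional probability for a label
#' (healthy or sick) reaches `min_probability` with support at least
#' `min_support`. Rules whose condition set strictly contains that of an
#' equally-or-more-probable shorter rule for the same label are pruned.
#' Each rule carries its empirical probability and support.
#'
#' @param dataset Tibble of parameter vectors with a logical `healthy`
#'   column; both labels must be present.
#' @param cfg A [mining_config()].
#' @param features Features to mine over (default all eight).
#' @return A `rule_table`: the candidate-condition tibble plus one row per
#'   mined rule (condition indices `i1..i3`, `predicted`, `probability`,
#'   `support`), in deterministic order (label, conjunction size, canonical
#'   condition key). Materialize individual rules with [as_rule_list()];
#'   feed the whole table to [select_iff_ruleset()] or [audit_rules()].
#' @export
mine_rules <- function(dataset, cfg = mining_config(),
                       features = parameter_features) {
  stopifnot("healthy" %in% names(dataset), is.logical(dataset$healthy))
  if (length(unique(dataset$healthy)) < 2L) {
    stop("both healthy and sick labels must be present", call. = FALSE)
  }
  conds <- candidate_conditions(dataset, cfg, features)
  M <- condition_matrix(dataset, conds)
  healthy <- dataset$healthy
  n_cond <- nrow(conds)
  feat_of <- conds$feature

  supp1 <- as.integer(rowSums(M))
  nh1 <- as.integer(M %*% healthy)
  mp <- cfg$min_probability
  ms <- cfg$min_support

  chunks <- list()  # columnar accumulator: i1, i2, i3, label, supp, prob
  emit <- function(i1, i2, i3, label, supp, prob) {
    chunks[[length(chunks) + 1L]] <<- tibble::tibble(
      i1 = as.integer(i1), i2 = as.integer(i2), i3 = as.integer(i3),
      predicted = label, probability = prob, support = as.integer(supp))
  }

  # singles; per-condition best kept probability by label drives pruning
  best1 <- matrix(-Inf, nrow = n_cond, ncol = 2,
                  dimnames = list(NULL, c("healthy", "sick")))
  ph1 <- ifelse(supp1 > 0L, nh1 / supp1, NA_real_)
  for (label in c("healthy", "sick")) {
    p <- if (label == "healthy") ph1 else 1 - ph1
    hit <- which(supp1 >= ms & !is.na(p) & p >= mp)
    if (length(hit) > 0L) {
      best1[hit, label] <- p[hit]
      emit(hit, NA, NA, label, supp1[hit], p[hit])
    }
  }

  pair_best <- NULL  # filled when triples need pair-level pruning info
  track_pairs <- cfg$max_conjunction >= 3L
  pair_records <- list()
  if (cfg$max_conjunction >= 2L && n_cond >= 2L) {
    feats <- unique(feat_of)
    Mh <- M * rep(healthy, each = n_cond)  # numeric for crossprod
    Mn <- M * 1
    blocks <- lapply(feats, function(f) which(feat_of == f))
    for (a in seq_along(feats)) {
      for (b in seq_along(feats)) {
        if (b <= a) next
        ia <- blocks[[a]]; ib <- blocks[[b]]
        S <- tcrossprod(Mn[ia, , drop = FALSE], Mn[ib, , drop = FALSE])
        H <- tcrossprod(Mh[ia, , drop = FALSE], Mn[ib, , drop = FALSE])
        ok <- S >= ms
        if (!any(ok)) next
        Ph <- H / S
        for (label in c("healthy", "sick")) {
          prob_m <- if (label == "healthy") Ph else 1 - Ph
          idx <- which(ok & prob_m >= mp, arr.ind = TRUE)
          if (nrow(idx) == 0L) next
          ci <- ia[idx[, 1L]]
          cj <- ib[idx[, 2L]]
          prob <- prob_m[idx]
          supp <- S[idx]
          # prune: a contained single rule at least as probable dominates
          keep <- pmax(best1[ci, label], best1[cj, label]) < prob
          if (!any(keep)) next
          emit(ci[keep], cj[keep], NA, label, supp[keep], prob[keep])
          if (track_pairs) {
            pair_records[[length(pair_records) + 1L]] <- tibble::tibble(
              i = ci[keep], j = cj[keep], label = label, prob = prob[keep])
          }
        }
      }
    }
  }

  if (cfg$max_conjunction >= 3L && n_cond >= 3L) {
    pair_best <- new.env(parent = emptyenv())
    for (pr in pair_records) {
      for (k in seq_len(nrow(pr))) {
        key <- sprintf("%d,%d,%s", pr$i[k], pr$j[k], pr$label[k])
        cur <- pair_best[[key]]
        pair_best[[key]] <- max(if (is.null(cur)) -Inf else cur, pr$prob[k])
      }
    }
    tr <- mine_triples(conds, M, healthy, cfg, best1, pair_best)
    if (nrow(tr) > 0L) {
      emit(tr$i1, tr$i2, tr$i3, tr$predicted, tr$support, tr$probability)
    }
  }

  rules <- dplyr::bind_rows(chunks)
  labels <- cond_labels(conds)
  new_rule_table(rules, conds, labels, nrow(dataset))
}

# Deterministic ordering + class stamp for the mined-rule container.
new_rule_table <- function(rules, conds, labels, n_cases) {
  if (nrow(rules) > 0L) {
    l1 <- labels[rules$i1]
    l2 <- ifelse(is.na(rules$i2), "", labels[rules$i2])
    l3 <- ifelse(is.na(rules$i3), "", labels[rules$i3])
    # canonical sorted key; vectorized for the common sizes 1 and 2
    key <- ifelse(l2 == "", l1,
                  paste(pmin(l1, l2), pmax(l1, l2), sep = "&"))
    has3 <- which(l3 != "")
    if (length(has3) > 0L) {
      key[has3] <- vapply(has3, function(k) {
        paste(sort(c(l1[k], l2[k], l3[k])), collapse = "&")
      }, character(1))
    }
    size <- 1L + !is.na(rules$i2) + !is.na(rules$i3)
    ord <- order(rules$predicted, size, key)
    rules <- rules[ord, ]
    rules$key <- key[ord]
    rules$n_conditions <- size[ord]
  } else {
    rules$key <- character(0)
    rules$n_conditions <- integer(0)
  }
  structure(list(rules = rules, conditions = conds, n_cases = n_cases),
            class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  r <- x$rules
  cat(sprintf(
    "<rule_table> %d rules (%d healthy / %d sick) over %d candidate conditions, %d cases\n",
    nrow(r), sum(r$predicted == "healthy"), sum(r$predicted == "sick"),
    nrow(x$conditions), x$n_cases))
  invisible(x)
}

#' Number of mined rules in a rule table
#' @param x A `rule_table` from [mine_rules()].
#' @export
n_rules <- function(x) nrow(x$rules)

#' Materialize mined rules as rule objects
#'
#' Converts rows of a [mine_rules()] rule table into [courtship_rule()]
#' objects. Intended for small selections; the full exhaustive table on a
#' realistic cohort holds ~10^6 rules.
#'
#' @param x A `rule_table`.
#' @param which Row indices to materialize (default all).
#' @return List of [courtship_rule()]s.
#' @export
as_rule_list <- function(x, which = seq_len(nrow(x$rules))) {
  stopifnot(inherits(x, "rule_table"))
  conds <- x$conditions
  lapply(which, function(k) {
    r <- x$rules[k, ]
    ii <- c(r$i1, r$i2, r$i3)
    ii <- ii[!is.na(ii)]
    conditions <- lapply(ii, function(i) {
      rule_condition(conds$feature[i], conds$low[i], conds$high[i],
                     kind = conds$kind[i])
    })
    courtship_rule(conditions, r$predicted, probability = r$probability,
                   support = r$support)
  })
}

# Rules x dataset-rows coverage matrix for a subset of rule_table rows.
rule_table_coverage <- function(x, dataset, which) {
  M <- condition_matrix(dataset, x$conditions)
  r <- x$rules[which, ]
  cov <- t(M[r$i1, , drop = FALSE])
  if (any(!is.na(r$i2))) {
    m2 <- t(M[ifelse(is.na(r$i2), 1L, r$i2), , drop = FALSE])
    m2[, is.na(r$i2)] <- TRUE
    cov <- cov & m2
  }
  if (any(!is.na(r$i3))) {
    m3 <- t(M[ifelse(is.na(r$i3), 1L, r$i3), , drop = FALSE])
    m3[, is.na(r$i3)] <- TRUE
    cov <- cov & m3
  }
  cov  # n_rows(dataset) x length(which)
}

# Size-3 conjunctions by direct loop over the first condition; intended for
# small datasets (the default configuration stops at pairs).
mine_triples <- function(conds, M, healthy, cfg, best1, pair_best) {
  n_cond <- nrow(conds)
  feat_of <- conds$feature
  feats <- unique(feat_of)
  mp <- cfg$min_probability
  ms <- cfg$min_support
  lookup_pair <- function(i, j, label) {
    key <- sprintf("%d,%d,%s", min(i, j), max(i, j), label)
    v <- pair_best[[key]]
    if (is.null(v)) -Inf else v
  }
  out <- list()
  for (fa in seq_along(feats)) {
    ia <- which(feat_of == feats[fa])
    rest_feats <- feats[-seq_len(fa)]
    if (length(rest_feats) < 2L) next
    for (i in ia) {
      rows_i <- M[i, ]
      if (sum(rows_i) < ms) next
      for (fb_i in seq_along(rest_feats)) {
        for (fc_i in seq_along(rest_feats)) {
          if (fc_i <= fb_i) next
          ib <- which(feat_of == rest_feats[fb_i])
          ic <- which(feat_of == rest_feats[fc_i])
          Mb <- M[ib, rows_i, drop = FALSE] * 1
          Mc <- M[ic, rows_i, drop = FALSE] * 1
          Mbh <- M[ib, rows_i, drop = FALSE] *
            rep(healthy[rows_i], each = length(ib))
          S <- tcrossprod(Mb, Mc)
          H <- tcrossprod(Mbh, Mc)
          ok <- S >= ms
          if (!any(ok)) next
          Ph <- H / S
          for (label in c("healthy", "sick")) {
            prob_m <- if (label == "healthy") Ph else 1 - Ph
            idx <- which(ok & prob_m >= mp, arr.ind = TRUE)
            if (nrow(idx) == 0L) next
            for (k in seq_len(nrow(idx))) {
              cj <- ib[idx[k, 1L]]
              ck <- ic[idx[k, 2L]]
              prob <- prob_m[idx[k, 1L], idx[k, 2L]]
              shorter <- max(best1[i, label], best1[cj, label],
                             best1[ck, label],
                             lookup_pair(i, cj, label),
                             lookup_pair(i, ck, label),
                             lookup_pair(cj, ck, label))
              if (shorter >= prob) next
              out[[length(out) + 1L]] <- tibble::tibble(
                i1 = i, i2 = cj, i3 = ck, predicted = label,
                probability = prob,
                support = as.integer(S[idx[k, 1L], idx[k, 2L]]))
            }
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(i1 = integer(), i2 = integer(), i3 = integer(),
                   predicted = character(), probability = double(),
                   support = integer())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Audit mined rules against the dataset
#'
#' Recomputes each rule's support and empirical probability directly from
#' the data and compares with the values the rule carries. Used as a
#' self-consistency check.
#'
#' @param rules A `rule_table` from [mine_rules()], or a list of
#'   [courtship_rule()]s.
#' @param dataset Tibble of labeled parameter vectors.
#' @return Tibble with recomputed `support`/`probability`, the stated
#'   values, and a logical `consistent` column.
#' @export
audit_rules <- function(rules, dataset) {
  if (inherits(rules, "rule_table")) {
    cov <- rule_table_coverage(rules, dataset, seq_len(nrow(rules$rules)))
    supp <- as.integer(colSums(cov))
    nh <- as.integer(crossprod(cov, dataset$healthy))
    p_lab <- ifelse(rules$rules$predicted == "healthy",
                    nh / supp, (supp - nh) / supp)
    return(tibble::tibble(
      predicted = rules$rules$predicted, support = supp,
      probability = p_lab,
      stated_support = rules$rules$support,
      stated_probability = rules$rules$probability,
      consistent = supp == rules$rules$support &
        abs(p_lab - rules$rules$probability) < 1e-12
    ))
  }
  rows <- lapply(rules, function(r) {
    m <- rep(TRUE, nrow(dataset))
    for (cond in r$conditions) {
      x <- as.numeric(dataset[[cond$feature]])
      m <- m & x >= cond$low & x <= cond$high
    }
    supp <- sum(m)
    p_lab <- if (r$predicted == "healthy") {
      mean(dataset$healthy[m])
    } else {
      mean(!dataset$healthy[m])
    }
    tibble::tibble(
      predicted = r$predicted, support = supp, probability = p_lab,
      stated_support = r$support, stated_probability = r$probability,
      consistent = supp == r$support &
        isTRUE(all.equal(p_lab, r$probability, tolerance = 1e-12))
    )
  })
  dplyr::bind_rows(rows)
}

#' Assemble a necessary-and-sufficient rule set
#'
#' Greedy forward selection over the healthy-predicting mined rules,
#' maximizing the two-sided success rate of the disjunction classifier
#' (healthy iff any selected rule fires). Ties are broken by higher
#' support, then fewer conditions, then canonical lexical order of the
#' condition set; selection stops when no addition strictly improves the
#' success rate.
#'
#' @param rules A `rule_table` from [mine_rules()], or a list of
#'   [courtship_rule()]s.
#' @param dataset Tibble of labeled parameter vectors the set is optimized
#'   against.
#' @param name Name for the resulting rule set.
#' @return List with components `rule_set` (a [rule_set()]) and `report`
#'   (its [evaluate_ruleset()] result on `dataset`).
#' @export
select_iff_ruleset <- function(rules, dataset, name = "iff") {
  if (inherits(rules, "rule_table")) {
    h_idx <- which(rules$rules$predicted == "healthy")
    if (length(h_idx) == 0L) {
      stop("no healthy-predicting rules to select from", call. = FALSE)
    }
    mm <- rule_table_coverage(rules, dataset, h_idx)
    supports <- rules$rules$support[h_idx]
    sizes <- rules$rules$n_conditions[h_idx]
    keys <- rules$rules$key[h_idx]
    materialize <- function(chosen) as_rule_list(rules, h_idx[chosen])
  } else {
    h_rules <- Filter(function(r) r$predicted == "healthy", rules)
    if (length(h_rules) == 0L) {
      stop("no healthy-predicting rules to select from", call. = FALSE)
    }
    mm <- ruleset_match_matrix(dataset, rule_set(h_rules, "pool"))
    if (!is.matrix(mm)) mm <- matrix(mm, ncol = length(h_rules))
    supports <- vapply(h_rules, `[[`, integer(1), "support")
    sizes <- vapply(h_rules, function(r) length(r$conditions), integer(1))
    keys <- vapply(h_rules, function(r) {
      paste(sort(vapply(r$conditions, function(cond) {
        sprintf("%s[%.10g,%.10g]", cond$feature, cond$low, cond$high)
      }, character(1))), collapse = "&")
    }, character(1))
    materialize <- function(chosen) h_rules[chosen]
  }
  healthy <- dataset$healthy
  n <- nrow(dataset)
  storage.mode(mm) <- "double"  # one-time coercion for fast crossprod

  covered <- rep(FALSE, n)
  chosen <- integer(0)
  repeat {
    # adding rule r flips its newly covered rows to "healthy" predictions:
    # gain = (+1 per newly covered healthy) - (1 per newly covered sick)
    w <- ifelse(healthy, 1, -1)
    w[covered] <- 0
    gains <- as.vector(crossprod(mm, w))
    gains[chosen] <- -Inf
    best_gain <- max(gains)
    if (best_gain <= 0) break
    cand <- which(gains == best_gain)
    cand <- cand[order(-supports[cand], sizes[cand], keys[cand])]
    pick <- cand[1L]
    chosen <- c(chosen, pick)
    covered <- covered | mm[, pick]
  }
  if (length(chosen) == 0L) {
    stop("no rule improves on the trivial all-sick classifier",
         call. = FALSE)
  }
  rs <- rule_set(materialize(chosen), name = name)
  list(rule_set = rs, report = evaluate_ruleset(dataset, rs))
}
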