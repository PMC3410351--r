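# Negative-geotaxis climbing assay: vials are tapped to the bench and left
# standing for 18 s; a fly passes if it climbs at least 1 cm. The study
# design is 5 vials of 10 flies per genotype, assayed at day 6 and day 21.

climbing_csv_cols <- c("vial_id", "genotype", "age_days", "n_flies", "n_passed")

#' Construct a table of climbing trials
#'
#' @param vial_id Character vector of vial identifiers.
#' @param genotype Genotype per vial (one of [courtship_genotypes]).
#' @param n_flies Flies per vial (default 10).
#' @param n_passed Flies that climbed at least 1 cm within 18 s.
#' @param age_days Age at assay, days (metadata; default 6).
#' @return Tibble with one row per vial.
#' @export
climbing_trials <- function(vial_id, genotype, n_flies = 10, n_passed,
                            age_days = 6) {
  stopifnot(all(genotype %in% courtship_genotypes),
            all(n_flies > 0), all(n_passed >= 0), all(n_passed <= n_flies))
  tibble::tibble(
    vial_id = as.character(vial_id), genotype = genotype,
    age_days = as.numeric(age_days),
    n_flies = as.integer(n_flies), n_passed = as.integer(n_passed)
  )
}

#' Read / write climbing trial tables
#'
#' CSV with columns `vial_id, genotype, age_days, n_flies, n_passed`.
#'
#' @param path File path.
#' @return `read_climbing()` returns a validated tibble of trials.
#' @export
read_climbing <- function(path) {
  stopifnot(file.exists(path))
  check_csv_header(path, climbing_csv_cols)
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      vial_id = readr::col_character(),
      genotype = readr::col_character(),
      age_days = readr::col_double(),
      n_flies = readr::col_integer(),
      n_passed = readr::col_integer()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0L || anyNA(df)) {
    stop("parse error in climbing table", call. = FALSE)
  }
  climbing_trials(df$vial_id, df$genotype, df$n_flies, df$n_passed,
                  df$age_days)
}

#' @rdname read_climbing
#' @param trials Tibble of climbing trials.
#' @export
write_climbing <- function(trials, path) {
  readr::write_csv(trials[climbing_csv_cols], path, progress = FALSE)
  invisible(path)
}

#' Pooled climbing score for a genotype
#'
#' Total flies passed over total flies assayed, pooled across vials (with
#' equal vial sizes this equals the mean per-vial pass fraction).
#'
#' @param trials Tibble of climbing trials.
#' @param genotype Genotype to score.
#' @param age_days Optional: restrict to one assay age.
#' @return Pass fraction in `[0, 1]`.
#' @export
climbing_score <- function(trials, genotype, age_days = NULL) {
  genotype <- match.arg(genotype, courtship_genotypes)
  t <- trials[trials$genotype == genotype, ]
  if (!is.null(age_days)) t <- t[t$age_days == age_days, ]
  if (nrow(t) == 0L) {
    stop(sprintf("no climbing trials for genotype '%s'", genotype),
         call. = FALSE)
  }
  sum(t$n_passed) / sum(t$n_flies)
}

#' Relative reduction in climbing ability
#'
#' `100 * (1 - score_pd / score_ctrl)`: the control group is set to 100%
#' climbing ability and the PD group's deficit is reported as a percent
#' reduction.
#'
#' @param score_pd,score_ctrl Pass fractions from [climbing_score()];
#'   `score_ctrl` must be positive.
#' @return Percent reduction.
#' @examples
#' climbing_reduction_pct(0.648, 0.9)  # 28
#' @export
climbing_reduction_pct <- function(score_pd, score_ctrl) {
  stopifnot(all(score_ctrl > 0))
  100 * (1 - score_pd / score_ctrl)
}
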