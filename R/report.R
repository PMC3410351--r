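# Report assembly: the relative-activity table (six traits + composite)
# and the end-to-end courtship report tying the pipeline stages together.

#' Relative-activity table for the six courtship traits
#'
#' One row per trait (orientation, vibration, licking, ATC, copulation,
#' SFI) with the control and PD group values, the PD group's activity as
#' percent of control (unrounded and rounded to whole percents, the
#' reporting convention), plus a final `composite` row carrying the
#' six-trait composite score.
#'
#' @param summary_pd,summary_ctrl One-row group summaries
#'   ([group_summary()]).
#' @return Tibble with columns `trait`, `control`, `pd`, `relative_pct`,
#'   `relative_pct_rounded`.
#' @export
relative_activity_table <- function(summary_pd, summary_ctrl) {
  rel <- relative_activities(summary_pd, summary_ctrl)
  tbl <- tibble::tibble(
    trait = names(composite_traits),
    control = vapply(composite_traits, function(col) summary_ctrl[[col]],
                     numeric(1), USE.NAMES = FALSE),
    pd = vapply(composite_traits, function(col) summary_pd[[col]],
                numeric(1), USE.NAMES = FALSE),
    relative_pct = unname(rel)
  )
  comp <- composite_score(summary_pd, summary_ctrl)
  tbl <- dplyr::bind_rows(
    tbl,
    tibble::tibble(trait = "composite", control = 100, pd = NA_real_,
                   relative_pct = comp)
  )
  tbl$relative_pct_rounded <- round(tbl$relative_pct)
  tbl
}

#' End-to-end courtship report
#'
#' Computes parameter vectors, the two group summaries, the
#' relative-activity table, the copulation reduction, and the mean per-fly
#' SFI ratio between groups from a list of sessions.
#'
#' @param sessions List of `courtship_session`s containing both genotypes.
#' @return A list of class `courtship_report`: `vectors`, `summary_ctrl`,
#'   `summary_pd`, `activity_table`, `composite_score`,
#'   `copulation_reduction_pct`, `sfi_ratio_pct`.
#' @export
courtship_report <- function(sessions) {
  vectors <- parameter_vectors(sessions)
  s_ctrl <- group_summary(vectors, "control")
  s_pd <- group_summary(vectors, "a30p")
  tbl <- relative_activity_table(s_pd, s_ctrl)
  structure(list(
    vectors = vectors,
    summary_ctrl = s_ctrl,
    summary_pd = s_pd,
    activity_table = tbl,
    composite_score = composite_score(s_pd, s_ctrl),
    copulation_reduction_pct = copulation_reduction_pct(
      s_pd$copulation_total, s_ctrl$copulation_total),
    sfi_ratio_pct = relative_activity_pct(s_pd$mean_sfi, s_ctrl$mean_sfi)
  ), class = "courtship_report")
}

#' @export
print.courtship_report <- function(x, ...) {
  cat(sprintf("<courtship_report> %d control + %d a30p couples\n",
              x$summary_ctrl$n, x$summary_pd$n))
  cat("relative activity of a30p vs control (control = 100%):\n")
  tbl <- x$activity_table
  for (i in seq_len(nrow(tbl))) {
    cat(sprintf("  %-11s %3.0f%%  (%.1f unrounded)\n",
                tbl$trait[i], tbl$relative_pct_rounded[i],
                tbl$relative_pct[i]))
  }
  cat(sprintf("copulations: %d vs %d (%.1f%% fewer in a30p)\n",
              x$summary_pd$copulation_total, x$summary_ctrl$copulation_total,
              x$copulation_reduction_pct))
  invisible(x)
}
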