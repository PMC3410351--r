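# Per-couple courtship parameters, normalizations, group summaries and the
# six-trait composite courtship score.
#
# Eight features describe each fly: orientation_time_s, vibration_time_s,
# licking_count, atc_count, copulated, nse_count, total_time_s, sfi.
# "healthy" (control genotype) is the Boolean dependent variable used by the
# rule learner.

#' Names of the eight per-fly features
#'
#' The feature set used by the rule learner: summed bout durations for
#' orientation and wing vibration, bout counts for licking, attempted
#' copulation (ATC) and non-sexual encounters (NSE), the copulation
#' indicator, total ritual time, and the sexual focus index
#' SFI = 1/(NSE + 1).
#'
#' @format Character vector of length 8.
#' @export
parameter_features <- c(
  "orientation_time_s", "vibration_time_s", "licking_count", "atc_count",
  "copulated", "nse_count", "total_time_s", "sfi"
)

#' Sexual focus index
#'
#' `SFI = 1/(NSE + 1)`: 1 for a male whose every encounter with the female
#' leads to courtship, decreasing toward 0 as non-sexual encounters
#' accumulate.
#'
#' @param nse_count Non-negative integer count of non-sexual encounters.
#' @return SFI in (0, 1].
#' @examples
#' sfi(0)   # 1
#' sfi(21)  # 1/22
#' @export
sfi <- function(nse_count) {
  stopifnot(all(nse_count >= 0))
  1 / (nse_count + 1)
}

#' Extract the per-couple parameter vector from a session
#'
#' Orientation/vibration times are summed bout durations; licking, ATC and
#' NSE are bout counts; `copulated` flags a copulation event; `sfi` is
#' computed from the NSE count; `healthy` is `TRUE` for the control
#' genotype.
#'
#' @param session A `courtship_session`.
#' @return A one-row tibble with columns `couple_id`, `genotype`, `healthy`
#'   and the eight [parameter_features].
#' @export
parameter_vector <- function(session) {
  validate_session(session)
  ev <- session$events
  dur <- function(el) sum(ev$end_s[ev$element == el] -
                            ev$start_s[ev$element == el])
  cnt <- function(el) sum(ev$element == el)
  n_nse <- cnt("nse")
  tibble::tibble(
    couple_id = session$couple_id,
    genotype = session$genotype,
    healthy = session$genotype == "control",
    orientation_time_s = dur("orientation"),
    vibration_time_s = dur("vibration"),
    licking_count = cnt("licking"),
    atc_count = cnt("attempted_copulation"),
    copulated = cnt("copulation") > 0L,
    nse_count = n_nse,
    total_time_s = total_time(session),
    sfi = sfi(n_nse)
  )
}

#' Parameter vectors for a list of sessions
#'
#' @param sessions List of `courtship_session` objects.
#' @return Tibble with one row per session; see [parameter_vector()].
#' @export
parameter_vectors <- function(sessions) {
  dplyr::bind_rows(purrr::map(sessions, parameter_vector))
}

#' Time fraction as a percentage
#'
#' `100 * time_s / total_s`, the normalization applied to orientation and
#' vibration times so that fast-copulating males (short sessions) are not
#' penalized.
#'
#' @param time_s Time spent in the element, seconds.
#' @param total_s Total session time, seconds (> 0).
#' @return Percent of total time, in `[0, 100]`.
#' @export
time_fraction_pct <- function(time_s, total_s) {
  stopifnot(all(total_s > 0), all(time_s >= 0), all(time_s <= total_s))
  100 * time_s / total_s
}

#' Count normalized by session time
#'
#' `count * 100 / total_s`: the per-100-seconds rate used for licking and
#' attempted-copulation counts.
#'
#' @param count Event count (or a group mean count).
#' @param total_s Total session time, seconds (> 0).
#' @return Normalized rate.
#' @export
count_rate_norm <- function(count, total_s) {
  stopifnot(all(total_s > 0))
  count * 100 / total_s
}

#' Activity of one group relative to another, in percent
#'
#' `100 * mean_pd / mean_ctrl`, the study's normalization that sets control
#' behavior to 100%.
#'
#' @param mean_pd Group mean for the Parkinson's-model group.
#' @param mean_ctrl Group mean for the control group (> 0).
#' @return Percent, unrounded. Reports conventionally round to whole
#'   percents; see [relative_activity_table()].
#' @examples
#' relative_activity_pct(41.3, 56.6)  # ~73
#' @export
relative_activity_pct <- function(mean_pd, mean_ctrl) {
  stopifnot(all(mean_ctrl > 0))
  100 * mean_pd / mean_ctrl
}

#' Percent reduction in copulations
#'
#' `100 * (1 - n_pd / n_ctrl)` for summed copulation counts (copulation is
#' binary per couple, so totals rather than means are compared).
#'
#' @param n_pd Copulations in the Parkinson's-model group.
#' @param n_ctrl Copulations in the control group (> 0).
#' @return Percent reduction, unrounded.
#' @examples
#' copulation_reduction_pct(8, 11)  # ~27.3
#' @export
copulation_reduction_pct <- function(n_pd, n_ctrl) {
  stopifnot(all(n_ctrl > 0))
  100 * (1 - n_pd / n_ctrl)
}

#' Group summary of normalized courtship parameters
#'
#' Arithmetic means of the per-couple normalized values: orientation and
#' vibration as percent of total time, licking and ATC as counts per 100 s,
#' NSE and SFI unnormalized (NSEs occur mostly before any sexual activity,
#' so dividing by total time would distort them). Copulations are summed,
#' not averaged.
#'
#' @param vectors Tibble of parameter vectors ([parameter_vectors()]).
#' @param genotype Which genotype to summarize.
#' @return One-row tibble: `genotype`, `n`, `mean_orientation_pct`,
#'   `mean_vibration_pct`, `mean_licking_norm`, `mean_atc_norm`,
#'   `copulation_total`, `mean_nse`, `mean_sfi`.
#' @export
group_summary <- function(vectors, genotype) {
  genotype <- match.arg(genotype, courtship_genotypes)
  v <- vectors[vectors$genotype == genotype, ]
  if (nrow(v) == 0L) {
    stop(sprintf("no parameter vectors with genotype '%s'", genotype),
         call. = FALSE)
  }
  tibble::tibble(
    genotype = genotype,
    n = nrow(v),
    mean_orientation_pct = mean(time_fraction_pct(v$orientation_time_s,
                                                  v$total_time_s)),
    mean_vibration_pct = mean(time_fraction_pct(v$vibration_time_s,
                                                v$total_time_s)),
    mean_licking_norm = mean(count_rate_norm(v$licking_count, v$total_time_s)),
    mean_atc_norm = mean(count_rate_norm(v$atc_count, v$total_time_s)),
    copulation_total = sum(v$copulated),
    mean_nse = mean(v$nse_count),
    mean_sfi = mean(v$sfi)
  )
}

# The six traits entering the composite score, as (report label, summary
# column) pairs. SFI stands in for NSE so that every trait is
# monotone-increasing in courtship quality.
composite_traits <- c(
  orientation = "mean_orientation_pct",
  vibration = "mean_vibration_pct",
  licking = "mean_licking_norm",
  atc = "mean_atc_norm",
  copulation = "copulation_total",
  sfi = "mean_sfi"
)

#' Per-trait relative activity of the PD group
#'
#' Each of the six traits (orientation, vibration, licking, ATC,
#' copulation, SFI) expressed as percent of the control group's value.
#'
#' @param summary_pd,summary_ctrl One-row group summaries
#'   ([group_summary()]); every control component must be positive.
#' @return Named numeric vector of six relative activities, unrounded.
#' @export
relative_activities <- function(summary_pd, summary_ctrl) {
  vapply(composite_traits, function(col) {
    ctrl <- summary_ctrl[[col]]
    if (ctrl <= 0) {
      stop(sprintf("control component '%s' is not positive", col),
           call. = FALSE)
    }
    relative_activity_pct(summary_pd[[col]], ctrl)
  }, numeric(1))
}

#' Composite courtship score
#'
#' The six per-trait relative activities summed and rescaled so that the
#' control group scores 100%. A group behaviorally identical to control
#' scores 100; uniform impairment to half of control scores 50.
#'
#' @inheritParams relative_activities
#' @return Composite score in percent (a single number).
#' @export
composite_score <- function(summary_pd, summary_ctrl) {
  sum(relative_activities(summary_pd, summary_ctrl)) / length(composite_traits)
}
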