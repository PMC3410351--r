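# Synthetic courtship sessions and climbing trials emulating the study
# design: two genotype groups (wild-type control, alpha-syn A30P) of 28
# males each, 600 s observations ending early at copulation, with the
# published group means as generator targets.
#
# Distributional families are the simplest ones matching the published
# means: Beta for time fractions (mean m, concentration c => shape m*c,
# (1-m)*c), Poisson for counts, Bernoulli for copulation, Uniform(300, cap)
# for copulation latency. No dispersion information is published; the
# concentration default is a free choice documented in the vignette.

#' Generator configuration
#'
#' Defaults encode the study conditions: 28 couples per group; control
#' group orientation 56.6% and vibration 21.5% of session time, licking
#' 3.4 and attempted copulations 0.4 per 100 s, copulation probability
#' 11/28, mean NSE 21; A30P group 41.3%, 17.2%, 2.0, 0.2, 8/28 and 33
#' respectively; 600 s observation cap.
#'
#' @param n_per_group Couples per genotype group.
#' @param seed Integer seed; every draw derives from it.
#' @param observation_cap_s Observation cap, seconds.
#' @param concentration Beta concentration for the orientation/vibration
#'   time fractions (larger = less couple-to-couple variability).
#' @param copulation_latency_range Range (seconds) of the uniform
#'   copulation start time for copulating couples.
#' @param groups Named list (`control`, `a30p`) of per-genotype parameter
#'   blocks with entries `orientation_frac_mean`, `vibration_frac_mean`,
#'   `licking_norm_mean`, `atc_norm_mean`, `p_copulate`, `nse_mean`.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 28, seed = 1,
                             observation_cap_s = 600,
                             concentration = 50,
                             copulation_latency_range = c(300, 600),
                             groups = list(
                               control = list(
                                 orientation_frac_mean = 0.566,
                                 vibration_frac_mean = 0.215,
                                 licking_norm_mean = 3.4,
                                 atc_norm_mean = 0.4,
                                 p_copulate = 11 / 28,
                                 nse_mean = 21
                               ),
                               a30p = list(
                                 orientation_frac_mean = 0.413,
                                 vibration_frac_mean = 0.172,
                                 licking_norm_mean = 2.0,
                                 atc_norm_mean = 0.2,
                                 p_copulate = 8 / 28,
                                 nse_mean = 33
                               )
                             )) {
  stopifnot(n_per_group >= 1, observation_cap_s > 0, concentration > 0,
            length(copulation_latency_range) == 2L,
            copulation_latency_range[1] > 0,
            copulation_latency_range[2] <= observation_cap_s,
            identical(sort(names(groups)), sort(courtship_genotypes)))
  for (g in groups) {
    stopifnot(g$orientation_frac_mean > 0, g$orientation_frac_mean < 1,
              g$vibration_frac_mean > 0, g$vibration_frac_mean < 1,
              g$licking_norm_mean >= 0, g$atc_norm_mean >= 0,
              g$p_copulate >= 0, g$p_copulate <= 1, g$nse_mean > 0)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed),
                 observation_cap_s = observation_cap_s,
                 concentration = concentration,
                 copulation_latency_range = copulation_latency_range,
                 groups = groups),
            class = "generator_config")
}

# Lay out `k` bouts with the given durations (centiseconds) non-overlapping
# within [0, total_c], separated by k+1 random gaps that consume the free
# time. Returns a 2-column integer matrix (start, end) in centiseconds.
layout_bouts <- function(durations_c, total_c) {
  k <- length(durations_c)
  if (k == 0L) return(matrix(integer(0), ncol = 2))
  free <- total_c - sum(durations_c)
  stopifnot(free >= 0)
  # split free time into k+1 integer gaps via rounded stick-breaking
  cuts <- sort(stats::runif(k, 0, free))
  gaps <- diff(c(0, round(cuts), free))
  starts <- unname(cumsum(c(0, durations_c[-k])) +
                     cumsum(gaps[-length(gaps)]))
  cbind(starts, starts + durations_c, deparse.level = 0)
}

# Draw bout durations (2-20 s, centisecond grid) summing exactly to
# target_c centiseconds.
draw_bout_durations <- function(target_c) {
  if (target_c <= 0) return(integer(0))
  out <- integer(0)
  remaining <- target_c
  while (remaining > 0) {
    d <- min(round(stats::runif(1, 200, 2000)), remaining)
    out <- c(out, d)
    remaining <- remaining - d
  }
  out
}

generate_one_session <- function(id, genotype, g, cfg) {
  cap_c <- round(cfg$observation_cap_s * 100)
  copulated <- stats::runif(1) < g$p_copulate
  total_c <- if (copulated) {
    round(stats::runif(1, cfg$copulation_latency_range[1],
                       cfg$copulation_latency_range[2]) * 100)
  } else {
    cap_c
  }
  rbeta_mean <- function(m) {
    stats::rbeta(1, m * cfg$concentration, (1 - m) * cfg$concentration)
  }
  events <- list()
  add <- function(element, m) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      element = element, start_s = m[, 1] / 100, end_s = m[, 2] / 100)
  }
  for (el in c("orientation", "vibration")) {
    m <- if (el == "orientation") g$orientation_frac_mean else
      g$vibration_frac_mean
    frac <- rbeta_mean(m)
    target_c <- round(frac * total_c)
    add(el, layout_bouts(draw_bout_durations(target_c), total_c))
  }
  total_s <- total_c / 100
  for (el in c("licking", "attempted_copulation")) {
    rate <- if (el == "licking") g$licking_norm_mean else g$atc_norm_mean
    k <- stats::rpois(1, rate * total_s / 100)
    # short 0.5 s bouts; cap the count so the layout always fits
    k <- min(k, total_c %/% 50L)
    add(el, layout_bouts(rep(50L, k), total_c))
  }
  n_nse <- stats::rpois(1, g$nse_mean)
  if (n_nse > 0) {
    t_nse <- sort(round(stats::runif(n_nse, 0, total_c)))
    events[[length(events) + 1L]] <- tibble::tibble(
      element = "nse", start_s = t_nse / 100, end_s = t_nse / 100)
  }
  if (copulated) {
    events[[length(events) + 1L]] <- tibble::tibble(
      element = "copulation", start_s = total_s, end_s = total_s)
  }
  courtship_session(id, genotype, dplyr::bind_rows(events),
                    observation_cap_s = cfg$observation_cap_s)
}

#' Generate synthetic courtship sessions
#'
#' Per couple: copulation ~ Bernoulli(`p_copulate`) with the session
#' truncated at a Uniform(300, cap) latency when it occurs; orientation and
#' vibration time fractions ~ Beta(mean, concentration), realized as
#' non-overlapping 2-20 s bouts; licking/ATC counts ~ Poisson(rate x
#' total/100) as short bouts; NSEs ~ Poisson(`nse_mean`) as instantaneous
#' events. All times lie on the 0.01 s grid, so sessions round-trip through
#' CSV bit-identically. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return List of `2 * n_per_group` validated `courtship_session`s
#'   (controls first).
#' @export
generate_sessions <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  sessions <- list()
  for (gt in courtship_genotypes) {
    g <- cfg$groups[[gt]]
    for (i in seq_len(cfg$n_per_group)) {
      id <- sprintf("%s_%04d", gt, i)
      sessions[[length(sessions) + 1L]] <- generate_one_session(id, gt, g, cfg)
    }
  }
  sessions
}

#' Generate synthetic climbing trials
#'
#' Per vial, `n_passed ~ Binomial(flies_per_vial, p)` with the genotype's
#' pass probability; seed-reproducible.
#'
#' @param p_ctrl,p_pd Pass probabilities for control and A30P flies.
#' @param n_vials Vials per genotype (study design: 5).
#' @param flies_per_vial Flies per vial (study design: 10).
#' @param seed Integer seed.
#' @param age_days Assay age metadata (default 21, the age at which the
#'   climbing deficit is expressed).
#' @return Tibble of climbing trials (see [climbing_trials()]).
#' @export
generate_climbing <- function(p_ctrl, p_pd, n_vials = 5, flies_per_vial = 10,
                              seed = 1, age_days = 21) {
  stopifnot(p_ctrl >= 0, p_ctrl <= 1, p_pd >= 0, p_pd <= 1, n_vials >= 1,
            flies_per_vial >= 1)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  dplyr::bind_rows(lapply(courtship_genotypes, function(gt) {
    p <- if (gt == "control") p_ctrl else p_pd
    climbing_trials(
      vial_id = sprintf("%s_v%03d", gt, seq_len(n_vials)),
      genotype = gt,
      n_flies = flies_per_vial,
      n_passed = stats::rbinom(n_vials, flies_per_vial, p),
      age_days = age_days
    )
  }))
}
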