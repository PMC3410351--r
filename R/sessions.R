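# Event-log data model for courtship sessions.
#
# A session is one male/female couple observed for up to `observation_cap_s`
# seconds (600 s in the study design) or until copulation. Behavior is stored
# as bouts: (element, start_s, end_s). Bouts of different elements may overlap
# (a male orients while vibrating); bouts of the same element may not.

#' Behavioral elements of the courtship ethogram
#'
#' The five classical elements of the male courtship ritual plus the
#' non-sexual encounter (NSE), a male-female encounter not followed by any
#' sexual activity. NSEs are instantaneous by convention
#' (`end_s == start_s`).
#'
#' @format Character vector of the six recognized element names.
#' @export
courtship_elements <- c(
  "orientation", "vibration", "licking",
  "attempted_copulation", "copulation", "nse"
)

#' Genotype vocabulary
#'
#' `"control"` is the wild-type (Oregon-R) group; `"a30p"` is the
#' Parkinson's-model group expressing alpha-synuclein A30P pan-neurally.
#'
#' @format Character vector of length 2.
#' @export
courtship_genotypes <- c("control", "a30p")

#' Construct a courtship session
#'
#' Bundles a couple's annotated observation into a validated session object.
#'
#' @param couple_id Single string identifying the couple.
#' @param genotype One of [courtship_genotypes] (the male's genotype).
#' @param events Data frame with columns `element`, `start_s`, `end_s`;
#'   one row per behavioral bout. May be empty.
#' @param observation_cap_s Maximum observation time in seconds (default 600).
#'
#' @return An object of class `courtship_session`: a list with fields
#'   `couple_id`, `genotype`, `observation_cap_s` and `events` (a tibble
#'   ordered by `start_s`).
#'
#' @details The session ends at the copulation start time if a copulation
#'   event is present, otherwise at `observation_cap_s`; see [total_time()].
#'   Validation enforces: known elements, `0 <= start_s <= end_s`, all events
#'   within the session's total time, at most one copulation, no overlap
#'   between bouts of the same element (touching endpoints are allowed), and
#'   per-element duration sums not exceeding the total time.
#'
#' @examples
#' s <- courtship_session(
#'   "c1", "control",
#'   data.frame(element = "orientation", start_s = 0, end_s = 10)
#' )
#' total_time(s)
#' @export
courtship_session <- function(couple_id, genotype, events,
                              observation_cap_s = 600) {
  stopifnot(is.character(couple_id), length(couple_id) == 1L)
  genotype <- match.arg(genotype, courtship_genotypes)
  stopifnot(is.numeric(observation_cap_s), length(observation_cap_s) == 1L,
            observation_cap_s > 0)
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0L) {
    events <- tibble::tibble(element = character(),
                             start_s = double(), end_s = double())
  }
  required <- c("element", "start_s", "end_s")
  if (!all(required %in% names(events))) {
    stop("events must have columns element, start_s, end_s", call. = FALSE)
  }
  events <- events[required]
  events <- events[order(events$start_s, events$element), ]
  x <- structure(
    list(couple_id = couple_id, genotype = genotype,
         observation_cap_s = as.numeric(observation_cap_s),
         events = events),
    class = "courtship_session"
  )
  validate_session(x)
  x
}

#' Validate a courtship session
#'
#' Checks every invariant of the session data model and fails with an error
#' naming the couple and the violated rule. Called by [courtship_session()]
#' and [read_sessions()]; exported so externally assembled objects can be
#' re-checked.
#'
#' @param session A `courtship_session`.
#' @return The session, invisibly, if valid.
#' @export
validate_session <- function(session) {
  ev <- session$events
  id <- session$couple_id
  fail <- function(rule) {
    stop(sprintf("invalid session '%s': %s", id, rule), call. = FALSE)
  }
  if (!all(ev$element %in% courtship_elements)) {
    fail(paste0("unknown element(s): ",
                paste(unique(setdiff(ev$element, courtship_elements)),
                      collapse = ", ")))
  }
  if (any(!is.finite(ev$start_s)) || any(!is.finite(ev$end_s))) {
    fail("non-finite event times")
  }
  if (any(ev$start_s < 0)) fail("event start_s < 0")
  if (any(ev$end_s < ev$start_s)) fail("event end_s < start_s")
  n_cop <- sum(ev$element == "copulation")
  if (n_cop > 1L) fail("more than one copulation event")
  tt <- total_time(session)
  if (!(tt > 0 && tt <= session$observation_cap_s)) {
    fail("total time outside (0, observation_cap_s]")
  }
  tol <- 1e-9
  if (any(ev$end_s > tt + tol)) {
    fail("event extends past the session's total time")
  }
  for (el in unique(ev$element)) {
    e <- ev[ev$element == el, ]
    if (nrow(e) > 1L) {
      e <- e[order(e$start_s, e$end_s), ]
      if (any(e$start_s[-1L] < e$end_s[-nrow(e)] - tol)) {
        fail(sprintf("overlapping '%s' bouts", el))
      }
    }
    if (sum(e$end_s - e$start_s) > tt + tol) {
      fail(sprintf("summed '%s' bout durations exceed total time", el))
    }
  }
  invisible(session)
}

#' Total observation time of a session
#'
#' The denominator used to time-normalize courtship parameters: the
#' copulation start time if the couple copulated (the session ends when
#' copulation begins), otherwise the observation cap.
#'
#' @param session A `courtship_session`.
#' @param from_first_act If `TRUE`, measure from the first courtship act
#'   (first bout of any element other than `nse`) instead of from 0. The
#'   study's "total ritual time" is taken as the default (from 0); the
#'   alternative reading is exposed here for sensitivity checks.
#' @return Time in seconds.
#' @examples
#' s <- courtship_session("c1", "control",
#'   data.frame(element = "orientation", start_s = 5, end_s = 20))
#' total_time(s)                        # 600: no copulation
#' @export
total_time <- function(session, from_first_act = FALSE) {
  ev <- session$events
  cop <- ev$start_s[ev$element == "copulation"]
  t_end <- if (length(cop) >= 1L) min(cop) else session$observation_cap_s
  if (!from_first_act) return(t_end)
  acts <- ev$start_s[ev$element != "nse"]
  t0 <- if (length(acts)) min(acts) else 0
  t_end - t0
}

#' @export
print.courtship_session <- function(x, ...) {
  cat(sprintf("<courtship_session> couple %s (%s): %d events, total time %.2f s\n",
              x$couple_id, x$genotype, nrow(x$events), total_time(x)))
  invisible(x)
}

session_csv_cols <- c("couple_id", "genotype", "element", "start_s", "end_s")

# Fail early, before the parser sees the file, if the header is not the
# documented schema.
check_csv_header <- function(path, expected) {
  hdr <- strsplit(readLines(path, n = 1L, warn = FALSE), ",")[[1L]]
  if (!identical(hdr, expected)) {
    stop(sprintf("malformed header: expected columns %s",
                 paste(expected, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read courtship sessions from CSV
#'
#' Reads a bout-level event log (columns `couple_id, genotype, element,
#' start_s, end_s`, one row per bout, UTF-8, comma-separated, header
#' required), groups rows by couple and returns validated sessions in
#' deterministic order (by `couple_id`, events by `start_s`).
#'
#' @param path Path to the CSV file.
#' @param observation_cap_s Observation cap applied to every session
#'   (default 600 s).
#' @return List of `courtship_session` objects.
#' @seealso [write_sessions()] for the inverse; the pair round-trips exactly
#'   (times are written with 2-decimal precision, so inputs on a 0.01 s grid
#'   are preserved bit-identically).
#' @export
read_sessions <- function(path, observation_cap_s = 600) {
  stopifnot(file.exists(path))
  check_csv_header(path, session_csv_cols)
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      couple_id = readr::col_character(),
      genotype = readr::col_character(),
      element = readr::col_character(),
      start_s = readr::col_double(),
      end_s = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop(sprintf("parse error at line %d: %s",
                 probs$row[1L] + 1L, probs$expected[1L]), call. = FALSE)
  }
  if (anyNA(df)) {
    bad <- which(!stats::complete.cases(df))[1L]
    stop(sprintf("parse error at line %d: missing value", bad + 1L),
         call. = FALSE)
  }
  ids <- unique(df$couple_id)
  lapply(sort(ids), function(id) {
    rows <- df[df$couple_id == id, ]
    gt <- unique(rows$genotype)
    if (length(gt) != 1L) {
      stop(sprintf("invalid session '%s': inconsistent genotype", id),
           call. = FALSE)
    }
    if (!gt %in% courtship_genotypes) {
      stop(sprintf("invalid session '%s': unknown genotype '%s'", id, gt),
           call. = FALSE)
    }
    courtship_session(id, gt, rows[c("element", "start_s", "end_s")],
                      observation_cap_s = observation_cap_s)
  })
}

#' Write courtship sessions to CSV
#'
#' One row per bout; times are printed with 2 decimals (0.01 s grid). An
#' empty session list yields a header-only file. Output is re-readable by
#' [read_sessions()].
#'
#' @param sessions List of `courtship_session` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  rows <- purrr::map(sessions, function(s) {
    validate_session(s)
    if (nrow(s$events) == 0L) return(NULL)
    tibble::tibble(
      couple_id = s$couple_id, genotype = s$genotype,
      element = s$events$element,
      start_s = sprintf("%.2f", s$events$start_s),
      end_s = sprintf("%.2f", s$events$end_s)
    )
  })
  df <- dplyr::bind_rows(rows)
  if (nrow(df) == 0L) {
    df <- tibble::tibble(couple_id = character(), genotype = character(),
                         element = character(), start_s = character(),
                         end_s = character())
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
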