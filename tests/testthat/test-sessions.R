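test_that("a minimal well-formed file reads into one session, one event", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("couple_id,genotype,element,start_s,end_s",
               "c1,control,orientation,0.00,10.00"), f)
  sessions <- read_sessions(f)
  expect_length(sessions, 1)
  expect_equal(sessions[[1]]$couple_id, "c1")
  expect_equal(nrow(sessions[[1]]$events), 1)
  expect_equal(sessions[[1]]$events$end_s, 10)
})

test_that("validation rejects malformed input with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  # two copulation rows for one couple
  writeLines(c("couple_id,genotype,element,start_s,end_s",
               "c1,control,copulation,100.00,100.00",
               "c1,control,copulation,200.00,200.00"), f)
  expect_error(read_sessions(f), "more than one copulation")

  writeLines(c("couple_id,genotype,element,start_s,end_s",
               "c1,control,orientation,ten,20.00"), f)
  expect_error(read_sessions(f), "parse error")

  writeLines(c("couple_id,genotype,wrong,start_s,end_s",
               "c1,control,orientation,0.00,20.00"), f)
  expect_error(read_sessions(f), "header")

  # same-element overlap
  expect_error(
    make_session(events = data.frame(
      element = c("orientation", "orientation"),
      start_s = c(0, 5), end_s = c(10, 15))),
    "overlapping")
  # different elements may overlap
  expect_silent(make_session(events = data.frame(
    element = c("orientation", "vibration"),
    start_s = c(0, 5), end_s = c(10, 15))))
  # touching same-element bouts are not an overlap
  expect_silent(make_session(events = data.frame(
    element = c("orientation", "orientation"),
    start_s = c(0, 10), end_s = c(10, 15))))

  expect_error(
    make_session(events = data.frame(element = "orientation",
                                     start_s = 0, end_s = 700)),
    "past the session")
  expect_error(
    make_session(events = data.frame(element = "grooming",
                                     start_s = 0, end_s = 1)),
    "unknown element")
  expect_error(
    make_session(events = data.frame(element = "orientation",
                                     start_s = 5, end_s = 2)),
    "end_s < start_s")
})

test_that("total_time is the copulation start when present, else the cap", {
  s <- make_session()
  expect_equal(total_time(s), 600)
  s_cop <- make_session(events = data.frame(
    element = c("orientation", "copulation"),
    start_s = c(0, 354.95), end_s = c(10, 354.95)))
  expect_equal(total_time(s_cop), 354.95)
  expect_lte(total_time(s_cop), 600)
  # invariant under event reordering
  s_rev <- make_session(events = data.frame(
    element = c("copulation", "orientation"),
    start_s = c(354.95, 0), end_s = c(354.95, 10)))
  expect_equal(total_time(s_rev), total_time(s_cop))
  # from the first courtship act
  s2 <- make_session(events = data.frame(
    element = c("nse", "orientation", "copulation"),
    start_s = c(1, 50, 400), end_s = c(1, 60, 400)))
  expect_equal(total_time(s2), 400)
  expect_equal(total_time(s2, from_first_act = TRUE), 350)
})

test_that("write then read is the identity on session lists", {
  # empty list -> header-only file
  f <- withr::local_tempfile(fileext = ".csv")
  write_sessions(list(), f)
  expect_equal(readLines(f), "couple_id,genotype,element,start_s,end_s")
  expect_length(read_sessions(f), 0)

  # 56-session synthetic round trip, bit-identical
  sessions <- generate_sessions(generator_config(n_per_group = 28,
                                                 seed = 404))
  write_sessions(sessions, f)
  back <- read_sessions(f)
  ids <- vapply(sessions, `[[`, character(1), "couple_id")
  expect_identical(lapply(sessions[order(ids)], unclass),
                   lapply(back, unclass))
  n_events <- sum(vapply(sessions, function(s) nrow(s$events), integer(1)))
  expect_equal(length(readLines(f)) - 1L, n_events)
})
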