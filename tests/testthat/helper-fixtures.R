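# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# hand-built event table (POSIXct timestamps)
make_events <- function(ids, opens, closes,
                        visit = 1L,
                        page_type = "core-content",
                        content_section = "quitting") {
  data.frame(
    participant_id = ids,
    visit_index = visit,
    open_time = ts(opens),
    close_time = ts(closes),
    page_type = page_type,
    content_section = content_section,
    stringsAsFactors = FALSE
  )
}

# hand-built viewing records
make_records <- function(ids, positions, durations, timed_out,
                         page_type = "core-content",
                         content_section = "quitting",
                         timeout_min = 30) {
  r <- data.frame(
    participant_id = ids, position = positions,
    duration_min = durations, timed_out = timed_out,
    page_type = rep(page_type, length.out = length(ids)),
    content_section = rep(content_section, length.out = length(ids)),
    stringsAsFactors = FALSE
  )
  attr(r, "timeout_min") <- timeout_min
  r
}

make_participants <- function(ids, arm = 0L, stratum = 1L) {
  data.frame(participant_id = ids, arm = arm, stratum = stratum,
             stringsAsFactors = FALSE)
}

# simulate a cohort and parse its own event log in memory
sim_and_parse <- function(seed, n = 300, ...) {
  cfg <- sim_config(n_participants = n, seed = seed, ...)
  cohort <- generate_cohort(cfg)
  records <- if (nrow(cohort$events)) {
    compute_durations(as_events(cohort$events), timeout_min = cfg$timeout_min)
  } else {
    make_records(character(), integer(), numeric(), logical())
  }
  list(cohort = cohort, records = records, participants = cohort$participants,
       config = cfg)
}

# draw a zero-inflated Poisson sample with intercept-only zero part
rzip <- function(n, pi, mu) {
  structural <- stats::rbinom(n, 1, pi) == 1
  y <- stats::rpois(n, mu)
  y[structural] <- 0L
  y
}
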