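# Parsing navigation event logs into per-page viewing durations.
#
# A page view is one open-to-close interval on a single intervention page,
# delimited by navigation timestamps.  Intervention platforms force a logout
# after a fixed period of inactivity (here 30 minutes by default); the close
# stamp of such a view records the forced logout, not actual reading time,
# so its duration is unknown and flagged as missing.

#' Read a page-view event log
#'
#' Reads a comma-separated event log with header columns
#' \code{participant_id, visit_index, open_time, close_time, page_type,
#' content_section}.  Timestamps are ISO-8601 at second resolution
#' (\code{YYYY-MM-DD HH:MM:SS} or with a \code{T} separator);
#' \code{close_time} may be empty for a view that never closed (browser
#' killed).
#'
#' @param path path to the delimited event-log file.
#' @return a data.frame of events with parsed POSIXct timestamps, sorted by
#'   participant and open time.
#' @export
read_event_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("participant_id", "visit_index", "open_time", "close_time",
              "page_type", "content_section")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("event log is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ev <- data.frame(
    participant_id  = raw$participant_id,
    visit_index     = as.integer(raw$visit_index),
    open_time       = parse_timestamp(raw$open_time),
    close_time      = parse_timestamp(raw$close_time),
    page_type       = raw$page_type,
    content_section = raw$content_section,
    stringsAsFactors = FALSE
  )
  ev[order(ev$participant_id, ev$open_time), , drop = FALSE]
}

#' Coerce an in-memory event table to parsed events
#'
#' Applies the same timestamp parsing as [read_event_log()] to a data.frame
#' already in memory (e.g. the event log emitted by [generate_cohort()]),
#' avoiding a round-trip through disk.
#'
#' @param events data.frame with character or POSIXct \code{open_time} /
#'   \code{close_time} columns.
#' @return events with POSIXct timestamps, sorted by participant and open
#'   time.
#' @export
as_events <- function(events) {
  if (!inherits(events$open_time, "POSIXct")) events$open_time <- parse_timestamp(events$open_time)
  if (!inherits(events$close_time, "POSIXct")) events$close_time <- parse_timestamp(events$close_time)
  events[order(events$participant_id, events$open_time), , drop = FALSE]
}

#' Compute per-page viewing durations and flag time-outs
#'
#' Converts page-view events into viewing records.  Elapsed open-to-close
#' time below \code{timeout_min} becomes an observed duration in minutes;
#' elapsed time at or above the threshold is the platform's forced-logout
#' signature, so the record is flagged \code{timed_out} and its duration is
#' set to \code{NA} (missing, to be imputed downstream).  A view with no
#' close stamp at all is likewise treated as timed out.
#'
#' Events with \code{close_time} earlier than \code{open_time} are rejected
#' individually (kept in the \code{rejected} attribute and reported via a
#' warning); a duplicated (participant, open time) pair indicates a corrupt
#' log and rejects the whole file.
#'
#' @param events data.frame of events as returned by [read_event_log()].
#' @param timeout_min inactivity time-out threshold in minutes (default 30).
#'   Post-hoc truncation designs can supply their truncation point here.
#' @return a data.frame of viewing records with columns
#'   \code{participant_id, position, duration_min, timed_out, page_type,
#'   content_section}; \code{position} numbers each participant's views
#'   1-based across all visits.  Rejected events are attached as the
#'   \code{rejected} attribute.
#' @export
compute_durations <- function(events, timeout_min = 30) {
  stopifnot(is.numeric(timeout_min), length(timeout_min) == 1, timeout_min > 0)
  ev <- events[order(events$participant_id, events$open_time), , drop = FALSE]

  key <- paste(ev$participant_id, format(ev$open_time, "%Y-%m-%d %H:%M:%S"))
  if (anyDuplicated(key)) {
    stop("duplicate (participant, open_time) pair(s); rejecting file: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }

  bad <- !is.na(ev$close_time) & ev$close_time < ev$open_time
  rejected <- ev[bad, , drop = FALSE]
  if (nrow(rejected)) {
    warning(sprintf("rejected %d event(s) with close_time before open_time", nrow(rejected)))
  }
  ev <- ev[!bad, , drop = FALSE]

  elapsed <- as.numeric(difftime(ev$close_time, ev$open_time, units = "mins"))
  timed_out <- is.na(ev$close_time) | elapsed >= timeout_min

  rec <- data.frame(
    participant_id  = ev$participant_id,
    position        = stats::ave(seq_len(nrow(ev)), ev$participant_id, FUN = seq_along),
    duration_min    = ifelse(timed_out, NA_real_, elapsed),
    timed_out       = timed_out,
    page_type       = ev$page_type,
    content_section = ev$content_section,
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  attr(rec, "rejected") <- rejected
  attr(rec, "timeout_min") <- timeout_min
  rec
}

#' Summarize viewing records
#'
#' Counts participants with at least one view, total and timed-out views,
#' and the share of views timed out (two decimals, half-up), and computes
#' the median and interquartile range of the observed (non-timed-out)
#' durations.
#'
#' @param records viewing records from [compute_durations()].
#' @return an object of class \code{view_summary}.
#' @export
summarize_views <- function(records) {
  if (!nrow(records)) stop("empty record list")
  obs <- records$duration_min[!records$timed_out]
  n_views <- nrow(records)
  n_to <- sum(records$timed_out)
  by_part <- tapply(records$timed_out, records$participant_id, any)
  s <- list(
    n_participants       = length(unique(records$participant_id)),
    n_views              = n_views,
    n_timed_out          = n_to,
    pct_timed_out        = pct2(n_to, n_views),
    n_participants_timed_out = sum(by_part),
    median_min           = if (length(obs)) stats::median(obs) else NA_real_,
    iqr_min              = if (length(obs)) unname(stats::quantile(obs, c(0.25, 0.75))) else c(NA_real_, NA_real_),
    median_available     = length(obs) > 0
  )
  class(s) <- "view_summary"
  s
}

#' @export
print.view_summary <- function(x, ...) {
  cat("Page-view summary\n")
  cat(sprintf("  participants with >=1 view : %d\n", x$n_participants))
  cat(sprintf("  page views                 : %d\n", x$n_views))
  cat(sprintf("  timed-out views            : %d (%.2f%%)\n", x$n_timed_out, x$pct_timed_out))
  cat(sprintf("  participants with time-out : %d\n", x$n_participants_timed_out))
  if (x$median_available) {
    cat(sprintf("  observed duration median   : %.2f min (IQR %.2f-%.2f)\n",
                x$median_min, x$iqr_min[1], x$iqr_min[2]))
  } else {
    cat("  observed duration median   : unavailable (all views timed out)\n")
  }
  invisible(x)
}

#' Write viewing records as delimited text
#'
#' @param records viewing records.
#' @param path output CSV path.
#' @export
write_viewing_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
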