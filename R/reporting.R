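# Paper-style summary outputs: cohort-flow counts with printed percentages,
# the observed-duration histogram, and the sensitivity plot.

#' Build a run report
#'
#' Collects cohort counts (with percentages printed to two decimals,
#' half-up, and their numerator/denominator pairs kept alongside so every
#' printed share is reproducible), the observed-duration summary, and any
#' analysis results into one report object.
#'
#' @param records viewing records.
#' @param participants participant table (denominator for enrollment).
#' @param events optional raw event log (for the visit count).
#' @param mi optional \code{mi_analysis} result.
#' @param sensitivity optional \code{sensitivity_result} table.
#' @param seed optional seed recorded for provenance.
#' @return object of class \code{run_report}.
#' @export
build_report <- function(records, participants, events = NULL, mi = NULL,
                         sensitivity = NULL, seed = NULL) {
  if (is.null(records) || is.null(participants)) stop("missing upstream artifact: records/participants")
  n_enrolled <- nrow(participants)
  accessed_ids <- unique(records$participant_id)
  n_accessed <- length(accessed_ids)
  n_views <- nrow(records)
  n_to <- sum(records$timed_out)
  by_part <- if (n_views) tapply(records$timed_out, records$participant_id, any) else logical()
  n_part_to <- sum(by_part)
  n_visits <- if (!is.null(events) && nrow(events)) {
    nrow(unique(events[c("participant_id", "visit_index")]))
  } else NA_integer_

  pcts <- list(
    accessed = list(num = n_accessed, den = n_enrolled,
                    pct = if (n_enrolled) pct2(n_accessed, n_enrolled) else NA_real_),
    timed_out_views = list(num = n_to, den = n_views,
                           pct = if (n_views) pct2(n_to, n_views) else NA_real_),
    participants_timed_out = list(num = n_part_to, den = n_accessed,
                                  pct = if (n_accessed) pct2(n_part_to, n_accessed) else NA_real_)
  )
  obs <- records$duration_min[!records$timed_out]
  structure(
    list(
      n_enrolled = n_enrolled, n_accessed = n_accessed, n_visits = n_visits,
      n_views = n_views, n_timed_out = n_to, n_participants_timed_out = n_part_to,
      pcts = pcts,
      median_min = if (length(obs)) stats::median(obs) else NA_real_,
      iqr_min = if (length(obs)) unname(stats::quantile(obs, c(0.25, 0.75)))
                else c(NA_real_, NA_real_),
      mi = mi, sensitivity = sensitivity,
      seed = seed, created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  fmt_pct <- function(p) if (is.na(p$pct)) sprintf("%d/%d", p$num, p$den)
                         else sprintf("%d (%.2f%%, %d/%d)", p$num, p$pct, p$num, p$den)
  cat("Engagement run report\n")
  cat(sprintf("  enrolled                     : %d\n", x$n_enrolled))
  cat(sprintf("  accessed at least once       : %s\n", fmt_pct(x$pcts$accessed)))
  if (!is.na(x$n_visits)) cat(sprintf("  intervention visits          : %d\n", x$n_visits))
  cat(sprintf("  page views                   : %d\n", x$n_views))
  cat(sprintf("  timed-out page views         : %s\n", fmt_pct(x$pcts$timed_out_views)))
  cat(sprintf("  participants with a time-out : %s\n", fmt_pct(x$pcts$participants_timed_out)))
  if (!is.na(x$median_min)) {
    cat(sprintf("  observed view median         : %.2f min (IQR %.2f-%.2f)\n",
                x$median_min, x$iqr_min[1], x$iqr_min[2]))
  }
  if (!is.null(x$mi)) {
    cat("\n")
    print(x$mi)
  }
  if (!is.null(x$sensitivity)) {
    s <- x$sensitivity
    lo <- s[1, ]; hi <- s[nrow(s), ]
    cat("\nConstant-assignment sensitivity (grid endpoints):\n")
    cat(sprintf("  assign %.5f min: ratio %.2f (%.2f-%.2f)\n",
                lo$assigned_min, lo$ratio, lo$ci_lo, lo$ci_hi))
    cat(sprintf("  assign %.5f min: ratio %.2f (%.2f-%.2f)\n",
                hi$assigned_min, hi$ratio, hi$ci_lo, hi$ci_hi))
  }
  if (!is.null(x$seed)) cat(sprintf("\n  provenance: seed %s, created %s\n", x$seed, x$created))
  invisible(x)
}

#' Write a report as text and key-value files
#'
#' @param report a \code{run_report}.
#' @param path text output path; a machine-readable \code{.kv} companion is
#'   written alongside.
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, path) {
  writeLines(utils::capture.output(print(report)), path)
  kv <- c(
    sprintf("n_enrolled = %d", report$n_enrolled),
    sprintf("n_accessed = %d", report$n_accessed),
    sprintf("n_views = %d", report$n_views),
    sprintf("n_timed_out = %d", report$n_timed_out),
    sprintf("n_participants_timed_out = %d", report$n_participants_timed_out),
    sprintf("pct_accessed = %.2f", report$pcts$accessed$pct),
    sprintf("pct_timed_out_views = %.2f", report$pcts$timed_out_views$pct),
    sprintf("pct_participants_timed_out = %.2f", report$pcts$participants_timed_out$pct),
    sprintf("median_observed_min = %.15g", report$median_min),
    sprintf("iqr_lo_min = %.15g", report$iqr_min[1]),
    sprintf("iqr_hi_min = %.15g", report$iqr_min[2])
  )
  if (!is.null(report$mi)) {
    kv <- c(kv,
            sprintf("mi_ratio = %.15g", report$mi$pooled$ratio),
            sprintf("mi_ci_lo = %.15g", report$mi$pooled$ratio_ci[1]),
            sprintf("mi_ci_hi = %.15g", report$mi$pooled$ratio_ci[2]),
            sprintf("mi_p_value = %.15g", report$mi$pooled$p_value),
            sprintf("mi_mean_total_min = %.15g", report$mi$mean_total_min),
            sprintf("mi_median_total_min = %.15g", report$mi$median_total_min))
  }
  kvpath <- paste0(path, ".kv")
  writeLines(kv, kvpath)
  invisible(c(path, kvpath))
}

#' Histogram of observed viewing durations
#'
#' Distribution of minutes spent per page view, excluding timed-out views
#' by construction (their durations are missing).
#'
#' @param records viewing records.
#' @param file optional image path (png); if NULL, plots to the active
#'   device.
#' @param max_min right edge of the plotted range, minutes.
#' @return invisibly, the observed durations plotted.
#' @export
plot_duration_histogram <- function(records, file = NULL, max_min = 15) {
  obs <- records$duration_min[!records$timed_out]
  if (!length(obs)) stop("no observed durations to plot")
  if (!is.null(file)) grDevices::png(file, width = 800, height = 500)
  graphics::hist(pmin(obs, max_min), breaks = seq(0, max_min, by = 0.5),
                 main = "Observed time per page view (time-outs excluded)",
                 xlab = "Minutes", col = "grey80", border = "white")
  graphics::abline(v = stats::median(obs), lty = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(obs)
}

#' Sensitivity plot: ratio of means against the assigned constant
#'
#' Point estimate with confidence band for every grid value of the
#' assumed time-out duration, with the multiple-imputation pooled estimate
#' overlaid as a horizontal reference when supplied.
#'
#' @param sens a \code{sensitivity_result} table.
#' @param mi optional \code{mi_analysis} result to overlay.
#' @param file optional png path.
#' @return invisibly, the sensitivity table.
#' @export
plot_sensitivity <- function(sens, mi = NULL, file = NULL) {
  if (!nrow(sens)) stop("empty sensitivity table")
  if (!is.null(file)) grDevices::png(file, width = 800, height = 500)
  ylim <- range(c(sens$ci_lo, sens$ci_hi, 1), na.rm = TRUE)
  graphics::plot(sens$assigned_min, sens$ratio, type = "b", pch = 16, ylim = ylim,
                 xlab = "Minutes assigned to timed-out page views",
                 ylab = "Ratio of mean minutes (motivational : prescriptive)",
                 main = "Sensitivity to the assigned time-out duration")
  graphics::arrows(sens$assigned_min, sens$ci_lo, sens$assigned_min, sens$ci_hi,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  graphics::abline(h = 1, lty = 3)
  if (!is.null(mi)) {
    graphics::abline(h = mi$pooled$ratio, col = "red3", lty = 2)
    graphics::legend("topright", legend = c("constant assignment", "MI pooled"),
                     col = c("black", "red3"), lty = c(1, 2), pch = c(16, NA), bty = "n")
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(sens)
}
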