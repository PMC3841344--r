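# Synthetic cohort generator.
#
# Emulates the exposure-time structure of a two-arm web intervention trial:
# a large never-access zero mass, right-skewed per-page viewing times,
# a fraction of views censored by the inactivity time-out, a binary
# message-tone factor, and a categorical readiness-to-quit randomization
# stratum.  Default marginals are calibrated to a published smoking-cessation
# trial: 63% of enrollees access the site at least once, roughly 10% of page
# views time out, and observed per-view times have median about 1.07 minutes
# (IQR 0.47-2.27), which on the log scale implies sigma about 1.17.

#' Simulation configuration
#'
#' @param n_participants number of enrolled participants.
#' @param p_never_access probability a participant never opens the site
#'   (contributes a structural zero to total time).
#' @param arm_effect_ratio true multiplicative effect of the motivational arm
#'   on per-page viewing time, hence (access being arm-independent) the true
#'   motivational:prescriptive ratio of mean total minutes.
#' @param n_strata number of readiness-to-quit strata.
#' @param pageview_lognormal_mu,pageview_lognormal_sigma log-minute location
#'   and scale of per-page viewing time before covariate effects.
#' @param p_timeout marginal probability that a page view ends in an
#'   inactivity time-out.
#' @param pages_per_visit_mean,visits_mean mean pages per visit and visits per
#'   accessing participant (both at least 1; the excess is Poisson).
#' @param max_views cap on page views per participant, bounding the width of
#'   the wide-format dataset.
#' @param timeout_min inactivity threshold in minutes used by the simulated
#'   logger.
#' @param nmar_inflation multiplier applied to the true duration of censored
#'   views.  1 (default) keeps censoring missing-at-random given covariates;
#'   values above 1 create not-missing-at-random stress tests in which
#'   timed-out views were genuinely longer than the observed-view model
#'   predicts.
#' @param seed integer RNG seed; identical configurations reproduce
#'   byte-identical output.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_participants = 1865,
                       p_never_access = 0.37,
                       arm_effect_ratio = 0.87,
                       n_strata = 3,
                       pageview_lognormal_mu = log(1.07),
                       pageview_lognormal_sigma = 1.17,
                       p_timeout = 0.1036,
                       pages_per_visit_mean = 3.9,
                       visits_mean = 1.44,
                       max_views = 40,
                       timeout_min = 30,
                       nmar_inflation = 1,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    p_never_access = p_never_access,
    arm_effect_ratio = arm_effect_ratio,
    n_strata = as.integer(n_strata),
    pageview_lognormal_mu = pageview_lognormal_mu,
    pageview_lognormal_sigma = pageview_lognormal_sigma,
    p_timeout = p_timeout,
    pages_per_visit_mean = pages_per_visit_mean,
    visits_mean = visits_mean,
    max_views = as.integer(max_views),
    timeout_min = timeout_min,
    nmar_inflation = nmar_inflation,
    seed = as.integer(seed)
  )
  if (cfg$n_participants < 1) stop("n_participants must be positive")
  probs <- c(cfg$p_never_access, cfg$p_timeout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$pageview_lognormal_sigma <= 0) stop("sigma must be > 0")
  if (cfg$arm_effect_ratio <= 0) stop("arm_effect_ratio must be > 0")
  if (cfg$n_strata < 1) stop("n_strata must be >= 1")
  if (cfg$pages_per_visit_mean < 1 || cfg$visits_mean < 1) {
    stop("pages_per_visit_mean and visits_mean must be >= 1")
  }
  if (cfg$nmar_inflation < 1) stop("nmar_inflation must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# Log-scale fixed effects of the true duration model.  Centred so the
# marginal median stays close to exp(pageview_lognormal_mu); they exist so
# that viewing time depends on observed covariates and the imputation
# models have real signal to recover (MAR is constructible).
.pagetype_effect <- c(introduction = -0.25, `core-content` = 0.10, testimonial = -0.15)
.section_effect  <- c(`getting-ready-to-quit` = 0.05, quitting = 0.00, `staying-quit` = -0.05)

#' Generate a synthetic cohort
#'
#' Draws a participant table, a time-stamped page-view event log as written
#' by the intervention platform, and the ground-truth per-view durations.
#' For a view that times out, the event log shows
#' \code{close = open + timeout_min} (the forced logout) while the true
#' duration is retained separately.  The time-out indicator depends on
#' viewing time only through observed covariates (stratum, page type), so
#' censoring is missing at random by construction unless
#' \code{nmar_inflation > 1}.  A true duration at or above the threshold is
#' always censored: the simulated logger cannot record it.
#'
#' @param config a [sim_config()] object.
#' @return list with elements \code{participants} (one row per enrollee:
#'   id, arm (1 = motivational), stratum, age, cigs_per_day),
#'   \code{events} (PageViewEvent log, empty for never-access participants),
#'   and \code{truth} (participant_id, position, true_duration_min,
#'   timed_out).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants

  participants <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    arm           = as.integer(stats::rbinom(n, 1, 0.5)),
    stratum       = sample.int(config$n_strata, n, replace = TRUE),
    age           = round(stats::rnorm(n, 46, 12)),
    cigs_per_day  = stats::rpois(n, 15),
    stringsAsFactors = FALSE
  )
  access <- stats::rbinom(n, 1, 1 - config$p_never_access) == 1

  ev_list <- vector("list", n)
  tr_list <- vector("list", n)
  base_day <- as.POSIXct("2010-01-01 09:00:00", tz = "UTC")

  for (i in which(access)) {
    n_visits <- 1 + stats::rpois(1, config$visits_mean - 1)
    pages <- 1 + stats::rpois(n_visits, config$pages_per_visit_mean - 1)
    total <- cumsum(pages)
    if (total[n_visits] > config$max_views) {
      keep <- which(total <= config$max_views)
      if (!length(keep)) { pages <- config$max_views; n_visits <- 1 }
      else { n_visits <- max(keep); pages <- pages[seq_len(n_visits)] }
    }
    n_views <- sum(pages)
    visit_of <- rep(seq_len(n_visits), pages)
    first_of_visit <- !duplicated(visit_of)

    page_type <- ifelse(first_of_visit, "introduction",
                        sample(c("core-content", "testimonial"), n_views,
                               replace = TRUE, prob = c(0.8, 0.2)))
    sections <- c("getting-ready-to-quit", "quitting", "staying-quit")
    sec_prob <- switch(participants$stratum[i] %% 3 + 1,
                       c(0.5, 0.3, 0.2), c(0.3, 0.4, 0.3), c(0.2, 0.4, 0.4))
    content_section <- sample(sections, n_views, replace = TRUE, prob = sec_prob)
    position <- seq_len(n_views)

    lmu <- config$pageview_lognormal_mu +
      log(config$arm_effect_ratio) * participants$arm[i] +
      0.10 * (participants$stratum[i] - (config$n_strata + 1) / 2) +
      .pagetype_effect[page_type] + .section_effect[content_section] -
      0.01 * (position - 1)
    true_dur <- exp(stats::rnorm(n_views, lmu, config$pageview_lognormal_sigma))
    true_dur <- round(true_dur * 60) / 60  # the logger has second resolution

    p_to <- stats::plogis(stats::qlogis(config$p_timeout) +
                            0.25 * (participants$stratum[i] - (config$n_strata + 1) / 2) +
                            0.20 * (page_type == "core-content") - 0.10)
    timed_out <- stats::runif(n_views) < p_to | true_dur >= config$timeout_min
    true_dur[timed_out] <- round(true_dur[timed_out] * config$nmar_inflation * 60) / 60

    logged_dur <- ifelse(timed_out, config$timeout_min, true_dur)
    # sequential stamps: each visit on its own day, pages back to back
    open <- numeric(n_views)
    t0 <- as.numeric(base_day) + (i - 1) * 86400 * 0.01
    for (v in seq_len(n_visits)) {
      idx <- which(visit_of == v)
      start <- t0 + (v - 1) * 86400 * 3
      # zero-second views still advance the clock so open stamps stay unique
      step <- pmax(1, round(logged_dur[idx] * 60))
      open[idx] <- start + c(0, cumsum(step))[seq_along(idx)]
    }
    close <- open + round(logged_dur * 60)

    ev_list[[i]] <- data.frame(
      participant_id  = participants$participant_id[i],
      visit_index     = visit_of,
      open_time       = format(as.POSIXct(open, origin = "1970-01-01", tz = "UTC"),
                               "%Y-%m-%dT%H:%M:%S"),
      close_time      = format(as.POSIXct(close, origin = "1970-01-01", tz = "UTC"),
                               "%Y-%m-%dT%H:%M:%S"),
      page_type       = page_type,
      content_section = content_section,
      stringsAsFactors = FALSE
    )
    tr_list[[i]] <- data.frame(
      participant_id    = participants$participant_id[i],
      position          = position,
      true_duration_min = true_dur,
      timed_out         = timed_out,
      stringsAsFactors = FALSE
    )
  }

  events <- do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))])
  truth <- do.call(rbind, tr_list[!vapply(tr_list, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(participant_id = character(), visit_index = integer(),
                         open_time = character(), close_time = character(),
                         page_type = character(), content_section = character(),
                         stringsAsFactors = FALSE)
    truth <- data.frame(participant_id = character(), position = integer(),
                        true_duration_min = numeric(), timed_out = logical(),
                        stringsAsFactors = FALSE)
  }
  rownames(events) <- rownames(truth) <- NULL
  list(participants = participants, events = events, truth = truth,
       config = config)
}

#' Ground-truth totals and arm ratio
#'
#' Sums the true per-view durations into per-participant true total minutes
#' (never-access participants contribute 0) and computes the true ratio of
#' arm means (motivational / prescriptive) directly.
#'
#' @param cohort output of [generate_cohort()].
#' @return list with \code{totals} (participant_id, arm, true_total_min) and
#'   \code{true_ratio}.
#' @export
ground_truth_totals <- function(cohort) {
  p <- cohort$participants
  agg <- tapply(cohort$truth$true_duration_min, cohort$truth$participant_id, sum)
  tot <- data.frame(
    participant_id = p$participant_id,
    arm = p$arm,
    true_total_min = as.numeric(agg[p$participant_id]),
    stringsAsFactors = FALSE
  )
  tot$true_total_min[is.na(tot$true_total_min)] <- 0
  m1 <- mean(tot$true_total_min[tot$arm == 1])
  m0 <- mean(tot$true_total_min[tot$arm == 0])
  list(totals = tot, true_ratio = m1 / m0)
}

#' Write a simulated cohort to delimited text files
#'
#' Emits the event log and participant table in the formats the parser
#' reads, plus a ground-truth per-participant total file.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_ev <- file.path(dir, "events.csv")
  f_pt <- file.path(dir, "participants.csv")
  f_gt <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$events, f_ev, row.names = FALSE)
  utils::write.csv(cohort$participants, f_pt, row.names = FALSE)
  gt <- ground_truth_totals(cohort)$totals
  utils::write.csv(gt[, c("participant_id", "true_total_min")], f_gt, row.names = FALSE)
  invisible(c(events = f_ev, participants = f_pt, ground_truth = f_gt))
}

#' Read a participant table
#'
#' @param path CSV with at least \code{participant_id}, \code{arm},
#'   \code{stratum} columns; any further columns are carried as baseline
#'   covariates.
#' @return data.frame.
#' @export
read_participants <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "arm", "stratum")
  miss <- setdiff(needed, names(p))
  if (length(miss)) stop("participant table missing column(s): ", paste(miss, collapse = ", "))
  p$participant_id <- as.character(p$participant_id)
  p
}

#' Read a flat key-value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored.  Values are coerced to numeric where possible.  Recognised keys
#' are the arguments of [sim_config()].
#'
#' @param path file path.
#' @return a [sim_config()] built from the file's entries.
#' @export
read_sim_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(args) <- keys
  unknown <- setdiff(keys, names(formals(sim_config)))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, args)
}
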