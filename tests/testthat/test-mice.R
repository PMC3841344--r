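test_that("nothing to impute yields M identical copies and empty traces", {
  rec <- make_records(c("A", "A", "B"), c(1, 2, 1), c(1, 2, 3),
                      c(FALSE, FALSE, FALSE))
  w <- build_wide(rec, make_participants(c("A", "B"), arm = c(0L, 1L), stratum = c(1L, 2L)))
  out <- mice_impute(w, M = 3, iterations = 5, seed = 1)
  for (m in 1:3) expect_identical(out$imputations[[m]]$t, w$t)
  expect_equal(nrow(diagnose_convergence(out)), 0)
})

test_that("M and basic contracts are honoured on a realistic cohort", {
  sp <- sim_and_parse(seed = 41, n = 400)
  w <- build_wide(sp$records, sp$participants)
  out <- mice_impute(w, M = 5, iterations = 5, seed = 2)
  expect_length(out$imputations, 5)

  obs <- w$mask == "obs"
  imp <- w$mask == "impute"
  str <- w$mask == "structural"
  for (m in 1:5) {
    tm <- out$imputations[[m]]$t
    # observed cells preserved bit-for-bit
    expect_identical(tm[obs], w$t[obs])
    # structural cells stay absent; imputed cells strictly positive
    expect_true(all(is.na(tm[str])))
    expect_true(all(tm[imp] > 0))
  }
  # proper MI: the same cell varies across imputations
  cell_draws <- sapply(out$imputations, function(d) d$t[imp][1:min(20, sum(imp))])
  expect_true(all(apply(cell_draws, 1, stats::var) > 0))
})

test_that("fixed seed reproduces imputations and traces exactly", {
  sp <- sim_and_parse(seed = 43, n = 200)
  w <- build_wide(sp$records, sp$participants)
  a <- mice_impute(w, M = 3, iterations = 4, seed = 9)
  b <- mice_impute(w, M = 3, iterations = 4, seed = 9)
  expect_identical(lapply(a$imputations, `[[`, "t"), lapply(b$imputations, `[[`, "t"))
  expect_identical(diagnose_convergence(a), diagnose_convergence(b))
})

test_that("single-cell imputation matches the closed-form regression oracle", {
  # One missing cell in column 2; column 1 (a core-content page, fully
  # observed) is the only informative predictor.  The mean of many proper
  # draws must sit on the least-squares prediction at that row's t_1.
  set.seed(61)
  n <- 5000
  l1 <- rnorm(n, 0, 0.9)
  l2 <- 0.4 + 0.6 * l1 + rnorm(n, 0, 0.5)
  rec <- make_records(
    ids = rep(sprintf("P%04d", 1:n), each = 2),
    positions = rep(1:2, n),
    durations = as.vector(rbind(exp(l1), exp(l2))),
    timed_out = FALSE
  )
  miss <- rec$position == 2 & rec$participant_id == "P0001"
  rec$duration_min[miss] <- NA
  rec$timed_out[miss] <- TRUE
  part <- make_participants(sprintf("P%04d", 1:n),
                            arm = rep(0:1, length.out = n),
                            stratum = rep(c(1L, 1L, 2L, 2L), length.out = n))
  w <- build_wide(rec, part)

  out <- mice_impute(w, M = 50, iterations = 2, seed = 3)
  draws <- log(vapply(out$imputations, function(d) d$t[1, 2], numeric(1)))

  # closed-form oracle: OLS of observed log t_2 on the full design is
  # dominated by the l1 slope; predict at row 1
  fit <- lm(l2[-1] ~ l1[-1] + part$arm[-1] + factor(part$stratum[-1]))
  pred <- sum(coef(fit) * c(1, l1[1], part$arm[1], part$stratum[1] == 2))
  se_mc <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - pred), 3 * se_mc)
})

test_that("sparse positions are pooled and orphan columns are named errors", {
  # position 2 has a single timed-out view and no observed values at all
  rec <- make_records(c("A", "A", "B"), c(1, 2, 1), c(1.0, NA, 2.0),
                      c(FALSE, TRUE, FALSE))
  w <- build_wide(rec, make_participants(c("A", "B"), arm = c(0L, 1L), stratum = 1L))
  # pooled tail: column 1 observations lend a model; should not error
  out <- mice_impute(w, M = 2, iterations = 2, seed = 5, min_cases = 25)
  expect_true(all(out$imputations[[1]]$t[1, ] > 0))

  # no observed data anywhere -> hard error naming the column
  rec2 <- make_records("A", 1, NA, TRUE)
  w2 <- build_wide(rec2, make_participants("A", arm = 0L, stratum = 1L))
  expect_error(mice_impute(w2, M = 2, iterations = 2, seed = 1),
               "no observed values")
})

test_that("convergence traces are stationary across independent seeds", {
  sp <- sim_and_parse(seed = 47, n = 500)
  w <- build_wide(sp$records, sp$participants)
  last_mean <- function(seed) {
    tr <- diagnose_convergence(mice_impute(w, M = 2, iterations = 6, seed = seed))
    last <- tr[tr$iteration == max(tr$iteration), ]
    c(mean = mean(last$mean), sd = stats::sd(last$mean))
  }
  a <- last_mean(101); b <- last_mean(202)
  pooled_se <- sqrt(a["sd"]^2 + b["sd"]^2) / sqrt(2)
  expect_lt(abs(a["mean"] - b["mean"]), 4 * pooled_se)
})

test_that("truncation switch caps imputed values at the threshold", {
  sp <- sim_and_parse(seed = 53, n = 300)
  w <- build_wide(sp$records, sp$participants)
  out <- mice_impute(w, M = 2, iterations = 3, seed = 7, truncate_at_timeout = TRUE)
  imp <- w$mask == "impute"
  for (m in 1:2) expect_true(all(out$imputations[[m]]$t[imp] <= w$timeout_min + 1e-12))
})

test_that("imputation files and manifest are written", {
  sp <- sim_and_parse(seed = 59, n = 80)
  w <- build_wide(sp$records, sp$participants)
  out <- mice_impute(w, M = 2, iterations = 2, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_imputations(out, dir)
  expect_true(all(file.exists(paths)))
  m1 <- utils::read.csv(paths[1])
  expect_equal(nrow(m1), 80)
  expect_true(any(grepl("^t_", names(m1))))
})
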