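# Chained-equations multiple imputation of timed-out page-view durations.
#
# Each duration column with missing (timed-out) entries gets its own
# log-normal regression imputation model; columns are cycled through from
# least to most missing, several times, replacing working values with draws
# from freshly estimated predictive models.  Imputation is "proper": the
# residual variance is drawn from its scaled chi-square posterior and the
# coefficients from their conditional normal before residual noise is
# added, so between-imputation variance reflects estimation uncertainty
# and Rubin's rules are valid downstream.

#' Multiply impute timed-out page-view durations
#'
#' Runs the chained-equations algorithm on a wide dataset.  Only cells whose
#' mask is \code{"impute"} (a view happened but timed out) are ever filled;
#' observed cells are preserved bit-for-bit and structural cells stay
#' absent.  Durations are modelled as normal on the log-minute scale; each
#' regression uses the fully observed baseline covariates, the randomized
#' arm and stratum, the (working) log minutes on the participant's first
#' core-content page, and the page type and content section of the target
#' view.  Positions with fewer than \code{min_cases} observed values share a
#' pooled tail model with position index as an extra covariate.
#'
#' @param wide a \code{wide_data} object from [build_wide()].
#' @param M number of imputed datasets (>= 2; 5 is the conventional default).
#' @param iterations chained-equation cycles per dataset (default 10).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param min_cases minimum observed cases for a position to get its own
#'   regression; sparser positions are pooled into the tail model.
#' @param floor_min observed durations of 0 (second-resolution stamps allow
#'   them) are floored at this value, in minutes, before the log transform.
#' @param truncate_at_timeout if TRUE, imputed durations are capped at the
#'   time-out threshold.  Off by default: a timed-out view may well have
#'   been abandoned long before the threshold, but nothing in the logging
#'   mechanism bounds the true viewing time above.
#' @return an object of class \code{mice_result}: list with
#'   \code{imputations} (list of M completed \code{wide_data} copies),
#'   \code{traces} (per column-group, per iteration, per m: mean and SD of
#'   imputed log durations), and the settings used.
#' @export
mice_impute <- function(wide, M = 5, iterations = 10, seed = 1L,
                        min_cases = 25, floor_min = 0.005,
                        truncate_at_timeout = FALSE) {
  stopifnot(inherits(wide, "wide_data"))
  if (M < 2) stop("M must be >= 2 (between-imputation variance is undefined otherwise)")
  if (iterations < 1) stop("iterations must be >= 1")
  n <- nrow(wide$t); K <- ncol(wide$t)
  mask <- wide$mask

  if (any(wide$t[mask == "obs"] < 0, na.rm = TRUE)) stop("negative observed duration")

  # --- log-scale working matrix; observed zeros floored before log ---
  L <- matrix(NA_real_, n, K)
  obs_idx <- which(mask == "obs")
  L[obs_idx] <- log(pmax(wide$t[obs_idx], floor_min))
  imp_any <- any(mask == "impute")

  # --- column groups: own model if enough observed cases, else pooled tail ---
  n_obs_col <- colSums(mask == "obs")
  n_imp_col <- colSums(mask == "impute")
  own <- which(n_obs_col >= min_cases)
  tail_cols <- setdiff(seq_len(K), own)
  groups <- lapply(own, function(k) list(cols = k, label = paste0("t_", k)))
  if (length(tail_cols)) {
    groups <- c(groups, list(list(cols = tail_cols, label = "tail")))
  }
  # a column that needs imputation but has no observed data and no partner
  orphan <- which(n_obs_col == 0 & n_imp_col > 0)
  if (length(orphan)) {
    in_tail <- orphan %in% tail_cols
    if (any(in_tail) && sum(n_obs_col[tail_cols]) == 0) {
      stop("no observed values to estimate an imputation model for column(s): ",
           paste0("t_", orphan[in_tail], collapse = ", "))
    }
  }
  # keep only groups with anything to impute or observed data to lend
  g_nimp <- vapply(groups, function(g) sum(n_imp_col[g$cols]), 0)
  g_nobs <- vapply(groups, function(g) sum(n_obs_col[g$cols]), 0)
  active <- which(g_nimp > 0)
  if (length(active) && any(g_nobs[active] == 0)) {
    bad <- groups[[active[which(g_nobs[active] == 0)[1]]]]
    stop("no observed values to estimate an imputation model for ", bad$label)
  }
  # cycling order: least missing first, ties by position
  ord <- active[order(g_nimp[active],
                      vapply(groups[active], function(g) min(g$cols), 0))]

  # --- fixed covariate design (fully observed) ---
  pdat <- wide$participants
  cov_cols <- setdiff(names(pdat), "participant_id")
  pdat2 <- pdat[cov_cols]
  pdat2$stratum <- factor(pdat2$stratum)
  for (nm in names(pdat2)) if (is.character(pdat2[[nm]])) pdat2[[nm]] <- factor(pdat2[[nm]])
  # single-level factors carry no information and break model.matrix
  keep <- vapply(pdat2, function(v) !is.factor(v) || nlevels(droplevels(v)) >= 2,
                 logical(1))
  pdat2 <- droplevels(pdat2[keep])
  Xc <- if (ncol(pdat2)) stats::model.matrix(~ ., data = pdat2)
        else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

  # position of each participant's first core-content page (fixed)
  first_core <- if (K == 0) rep(NA_integer_, n) else
    apply(wide$page_type == "core-content", 1, function(z) {
      w <- which(!is.na(z) & z); if (length(w)) w[1] else NA_integer_
    })

  # per-group precomputed pieces
  gprep <- lapply(groups, function(g) {
    cells_obs <- which(mask[, g$cols, drop = FALSE] == "obs", arr.ind = TRUE)
    cells_imp <- which(mask[, g$cols, drop = FALSE] == "impute", arr.ind = TRUE)
    fix <- function(cells) {
      if (!nrow(cells)) return(NULL)
      i <- cells[, 1]; k <- g$cols[cells[, 2]]
      pt <- factor(wide$page_type[cbind(i, k)],
                   levels = sort(unique(wide$page_type[cbind(
                     c(cells_obs[, 1], cells_imp[, 1]),
                     g$cols[c(cells_obs[, 2], cells_imp[, 2])])])))
      cs <- factor(wide$content_section[cbind(i, k)],
                   levels = sort(unique(wide$content_section[cbind(
                     c(cells_obs[, 1], cells_imp[, 1]),
                     g$cols[c(cells_obs[, 2], cells_imp[, 2])])])))
      X <- Xc[i, , drop = FALSE]
      dm <- function(f, pre) {
        lv <- levels(f)
        if (length(lv) < 2) return(NULL)
        m <- matrix(vapply(lv[-1], function(l) as.numeric(f == l),
                           numeric(length(f))),
                    nrow = length(f),
                    dimnames = list(NULL, paste0(pre, lv[-1])))
        m
      }
      X <- cbind(X, dm(pt, "ptype."), dm(cs, "csec."))
      if (length(g$cols) > 1) X <- cbind(X, position = k)
      # placeholders for the first-core-page predictor, updated every cycle
      X <- cbind(X, fcore = 0, fcore_na = 0)
      list(i = i, k = k, X = X)
    }
    list(obs = fix(cells_obs), imp = fix(cells_imp))
  })

  # fill the working first-core predictor into a group design matrix
  fill_fcore <- function(part, fvals, fbar) {
    if (is.null(part)) return(NULL)
    f <- fvals[part$i]
    # a cell may not use itself as predictor: mask rows whose target IS the
    # participant's first core page
    self <- !is.na(first_core[part$i]) & first_core[part$i] == part$k
    f[self] <- NA
    na <- is.na(f)
    part$X[, "fcore"] <- ifelse(na, fbar, f)
    part$X[, "fcore_na"] <- as.numeric(na)
    part$X
  }

  # proper Bayesian draw from one linear model, with design fallbacks for
  # small fitting sets
  draw_group <- function(Xf, yf, Xp) {
    p_full <- ncol(Xf)
    keep_try <- list(seq_len(p_full),                       # full design
                     which(!grepl("^(ptype|csec)\\.", colnames(Xf))),  # no page meta
                     1L)                                    # intercept only
    for (cols in keep_try) {
      if (nrow(Xf) >= length(cols) + 3 || identical(cols, 1L)) {
        Xf2 <- Xf[, cols, drop = FALSE]; Xp2 <- Xp[, cols, drop = FALSE]
        q <- qr(Xf2)
        kp <- q$pivot[seq_len(q$rank)]
        Xf2 <- Xf2[, kp, drop = FALSE]; Xp2 <- Xp2[, kp, drop = FALSE]
        p <- ncol(Xf2)
        fit <- stats::.lm.fit(Xf2, yf)
        df <- nrow(Xf2) - p
        sse <- sum(fit$residuals^2)
        sigma2 <- if (df >= 3) sse / stats::rchisq(1, df) else sse / max(df, 1)
        sigma2 <- max(sigma2, 1e-10)
        XtXinv <- chol2inv(chol(crossprod(Xf2) + diag(1e-8, p)))
        U <- chol(sigma2 * (XtXinv + diag(1e-12, p)))
        beta <- fit$coefficients + drop(t(U) %*% stats::rnorm(p))
        return(drop(Xp2 %*% beta) + stats::rnorm(nrow(Xp2), 0, sqrt(sigma2)))
      }
    }
    stop("unreachable")
  }

  set.seed(as.integer(seed))
  imputations <- vector("list", M)
  tr <- list()

  for (m in seq_len(M)) {
    Lw <- L
    # naive initialization: observed-group median on the log scale
    for (gi in ord) {
      g <- groups[[gi]]; pp <- gprep[[gi]]
      if (is.null(pp$imp)) next
      med <- stats::median(L[cbind(pp$obs$i, pp$obs$k)])
      Lw[cbind(pp$imp$i, pp$imp$k)] <- med
    }
    n_it <- if (imp_any) iterations else 0
    for (it in seq_len(n_it)) {
      # current working first-core predictor
      fvals <- rep(NA_real_, n)
      has <- !is.na(first_core)
      fvals[has] <- Lw[cbind(which(has), first_core[has])]
      fbar <- mean(fvals, na.rm = TRUE)
      if (!is.finite(fbar)) fbar <- 0
      for (gi in ord) {
        pp <- gprep[[gi]]
        if (is.null(pp$imp)) next
        Xf <- fill_fcore(pp$obs, fvals, fbar)
        Xp <- fill_fcore(pp$imp, fvals, fbar)
        yf <- L[cbind(pp$obs$i, pp$obs$k)]
        draws <- draw_group(Xf, yf, Xp)
        if (truncate_at_timeout) draws <- pmin(draws, log(wide$timeout_min))
        Lw[cbind(pp$imp$i, pp$imp$k)] <- draws
        # refresh fcore values touched by this update
        upd <- has & first_core %in% unique(pp$imp$k)
        if (any(upd)) fvals[upd] <- Lw[cbind(which(upd), first_core[upd])]
        tr[[length(tr) + 1]] <- data.frame(
          m = m, iteration = it, column = groups[[gi]]$label,
          mean = mean(draws), sd = stats::sd(draws))
      }
    }
    # back to minutes; only impute-mask cells are touched
    done <- wide
    ii <- which(mask == "impute")
    done$t[ii] <- exp(Lw[ii])
    done$m <- m
    imputations[[m]] <- done
  }

  traces <- if (length(tr)) do.call(rbind, tr) else
    data.frame(m = integer(), iteration = integer(), column = character(),
               mean = numeric(), sd = numeric())
  structure(
    list(imputations = imputations, traces = traces, M = M,
         iterations = iterations, seed = as.integer(seed),
         min_cases = min_cases, floor_min = floor_min,
         truncate_at_timeout = truncate_at_timeout,
         n_imputed_cells = sum(mask == "impute")),
    class = "mice_result"
  )
}

#' @export
print.mice_result <- function(x, ...) {
  cat(sprintf("mice_result: M=%d imputations, %d iterations, %d cells imputed (seed %d)\n",
              x$M, x$iterations, x$n_imputed_cells, x$seed))
  invisible(x)
}

#' Convergence diagnostics for the imputation chains
#'
#' Returns the per-column-group mean and SD of the imputed log durations at
#' every iteration of every chain, for inspection or plotting.  Stable
#' traces across iterations indicate the chained equations have stabilized.
#'
#' @param result a \code{mice_result}.
#' @return data.frame with columns m, iteration, column, mean, sd (empty if
#'   nothing was imputed).
#' @export
diagnose_convergence <- function(result) {
  stopifnot(inherits(result, "mice_result"))
  result$traces
}

#' Write completed datasets and a manifest
#'
#' One delimited file per imputation (participant covariates plus completed
#' duration columns and an imputation index \code{m}) and a plain-text
#' manifest recording the settings for auditability.
#'
#' @param result a \code{mice_result}.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_imputations <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(result$M)
  for (m in seq_len(result$M)) {
    w <- result$imputations[[m]]
    df <- cbind(m = m, w$participants, as.data.frame(w$t))
    paths[m] <- file.path(dir, sprintf("imputed_%02d.csv", m))
    utils::write.csv(df, paths[m], row.names = FALSE, na = "")
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c(
    sprintf("M = %d", result$M),
    sprintf("iterations = %d", result$iterations),
    sprintf("seed = %d", result$seed),
    sprintf("min_cases = %d", result$min_cases),
    sprintf("floor_min = %g", result$floor_min),
    sprintf("truncate_at_timeout = %s", result$truncate_at_timeout),
    sprintf("n_imputed_cells = %d", result$n_imputed_cells),
    "model = linear regression on log(minutes); proper draws (scaled chi-square variance, conditional normal coefficients, residual noise)"
  ), manifest)
  invisible(c(paths, manifest))
}
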