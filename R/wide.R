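# Wide-format construction: one row per participant, successive page views
# as successive columns, with a mask separating "timed out, impute" cells
# from "no such view, leave absent" cells.

#' Build the wide-format dataset
#'
#' Reshapes viewing records into one row per participant with duration
#' columns \code{t_1 ... t_K} (K = maximum observed position), page-metadata
#' matrices aligned with those columns, and a mask classifying every absent
#' duration either as \code{"impute"} (the view happened but timed out) or
#' \code{"structural"} (the participant never reached that position).
#' Participants with zero views appear as all-structural rows, so the
#' never-access zero mass is preserved for the downstream count model.
#'
#' @param records viewing records from [compute_durations()].
#' @param participants participant table; must contain \code{participant_id},
#'   \code{arm}, \code{stratum}, plus optional fully observed baseline
#'   covariates (any further columns).
#' @return an object of class \code{wide_data}: list with \code{participants}
#'   (row-aligned), \code{t} (n x K numeric matrix, NA where absent),
#'   \code{mask} (n x K character matrix in {"obs","impute","structural"}),
#'   \code{page_type} and \code{content_section} (n x K character matrices),
#'   and \code{timeout_min}.
#' @export
build_wide <- function(records, participants) {
  if (any(is.na(participants[setdiff(names(participants), "participant_id")]))) {
    stop("participant covariates must be fully observed")
  }
  unknown <- setdiff(unique(records$participant_id), participants$participant_id)
  if (length(unknown)) {
    stop("participant(s) in records but not in participant table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  n <- nrow(participants)
  K <- if (nrow(records)) max(records$position) else 0L

  t_mat <- matrix(NA_real_, n, K)
  mask <- matrix("structural", n, K)
  ptype <- matrix(NA_character_, n, K)
  csec <- matrix(NA_character_, n, K)
  if (K > 0) {
    colnames(t_mat) <- paste0("t_", seq_len(K))
    ri <- match(records$participant_id, participants$participant_id)
    idx <- cbind(ri, records$position)
    t_mat[idx] <- records$duration_min
    mask[idx] <- ifelse(records$timed_out, "impute", "obs")
    ptype[idx] <- records$page_type
    csec[idx] <- records$content_section
  }
  structure(
    list(participants = participants, t = t_mat, mask = mask,
         page_type = ptype, content_section = csec,
         timeout_min = attr(records, "timeout_min") %||% 30),
    class = "wide_data"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wide_data <- function(x, ...) {
  cat(sprintf("wide_data: %d participants x %d positions; %d observed, %d to impute\n",
              nrow(x$t), ncol(x$t), sum(x$mask == "obs"), sum(x$mask == "impute")))
  invisible(x)
}
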