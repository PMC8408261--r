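#' Participant selection by ordering performance
#'
#' Flags participants whose ordering performance is compatible with random
#' responding. For two-item sessions participants with fewer than 10 of 15
#' correct orderings are excluded; for three-item sessions those with 6 or
#' fewer correct orderings are excluded. Single-item sessions have no
#' ordering, so nobody is excluded. For session lengths other than 15
#' trials the thresholds scale proportionally (10/15 and 7/15 of trials).
#'
#' @param records Trial records ([simulate_session()] schema).
#' @param experiment_id One of `experiment_ids()`; determines the rule
#'   (exp1/exp4_1: none; exp2/exp4_2: >= 10/15; exp3: >= 7/15).
#' @return A data.frame with one row per participant: `participant_id`,
#'   `n_trials`, `n_correct` (fractional under ties, `NA` for single-item
#'   sessions), `included`.
#' @export
select_participants <- function(records, experiment_id) {
  experiment_id <- match.arg(experiment_id, experiment_ids())
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  n_int <- experiment_spec(experiment_id)$n_intermediate
  ids <- sort(unique(records$participant_id))

  if (n_int < 2L) {
    n_tr <- vapply(ids, function(p)
      length(unique(records$trial_index[records$participant_id == p])),
      integer(1))
    return(data.frame(participant_id = ids, n_trials = n_tr,
                      n_correct = NA_real_, included = TRUE,
                      stringsAsFactors = FALSE, row.names = NULL))
  }

  frac <- if (n_int == 2L) 10 / 15 else 7 / 15
  res <- lapply(ids, function(p) {
    st <- empirical_order_stats(records[records$participant_id == p, ])
    data.frame(participant_id = p, n_trials = st$n_trials,
               n_correct = st$n_correct,
               included = st$n_correct >= frac * st$n_trials - 1e-9,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Histogram of per-participant correct orderings
#'
#' Counts participants per number of correctly ordered trials
#' (0 .. `n_trials` bins); a bimodal shape with one mode near chance is
#' the signature of a random-responder subpopulation.
#'
#' @param qc A [select_participants()] result.
#' @param n_trials Number of trials per session (default: max observed,
#'   or 15 for empty input).
#' @return Named integer vector of counts over `0:n_trials` correct
#'   orderings (fractional credits rounded to the nearest integer).
#' @export
qc_histogram <- function(qc, n_trials = NULL) {
  stopifnot(is.data.frame(qc))
  if (is.null(n_trials))
    n_trials <- if (nrow(qc) == 0L) 15L else max(qc$n_trials)
  counts <- integer(n_trials + 1L)
  names(counts) <- 0:n_trials
  if (nrow(qc) > 0L && !all(is.na(qc$n_correct))) {
    k <- round(qc$n_correct[!is.na(qc$n_correct)])
    k <- pmin(pmax(k, 0L), n_trials)
    tab <- table(factor(k, levels = 0:n_trials))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Keep only included participants' records
#'
#' @param records Trial records.
#' @param qc A [select_participants()] result.
#' @return The subset of `records` from included participants.
#' @export
apply_selection <- function(records, qc) {
  keep <- qc$participant_id[qc$included]
  records[records$participant_id %in% keep, , drop = FALSE]
}
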