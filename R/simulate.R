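#' Report-noise profile for the synthetic generator
#'
#' Minimal generative family reproducing the qualitative shape of observed
#' single-item report distributions: wide around most slots, tight at the
#' trial beginning, middle and end, plus two contaminant participant types.
#' A *quantizer* participant retains only ordinal information and reports
#' rank-determined times; a *random responder* reports uniformly over the
#' trial and carries no information at all.
#'
#' @param base_sd Report SD (seconds) for non-anchor slots. Default 2.5.
#' @param anchor_sd Report SD (seconds) for anchor slots. Default 0.5.
#'   Must satisfy `base_sd >= anchor_sd >= 0`.
#' @param anchor_slots Slot indices with tightened noise; `NULL` (default)
#'   means first, middle and last slot of the grid in use.
#' @param quantizer_fraction Probability a participant is a quantizer.
#'   Default 0.10.
#' @param random_responder_fraction Probability a participant is a random
#'   responder. Default 0.25.
#' @return An object of class `noise_profile`.
#' @export
noise_profile <- function(base_sd = 2.5, anchor_sd = 0.5, anchor_slots = NULL,
                          quantizer_fraction = 0.10,
                          random_responder_fraction = 0.25) {
  if (!is.finite(base_sd) || !is.finite(anchor_sd) ||
      base_sd < anchor_sd || anchor_sd < 0)
    stop("need base_sd >= anchor_sd >= 0")
  for (p in c(quantizer_fraction, random_responder_fraction))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("fractions must be probabilities in [0, 1]")
  if (quantizer_fraction + random_responder_fraction > 1)
    stop("quantizer_fraction + random_responder_fraction must be <= 1")
  structure(
    list(base_sd = base_sd, anchor_sd = anchor_sd, anchor_slots = anchor_slots,
         quantizer_fraction = quantizer_fraction,
         random_responder_fraction = random_responder_fraction),
    class = "noise_profile"
  )
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf(
    "<noise_profile> base_sd %g s, anchor_sd %g s, quantizer %g, random %g\n",
    x$base_sd, x$anchor_sd, x$quantizer_fraction,
    x$random_responder_fraction))
  invisible(x)
}

# default anchors: first, middle, last slot
resolve_anchor_slots <- function(noise, grid) {
  if (!is.null(noise$anchor_slots)) return(as.integer(noise$anchor_slots))
  c(1L, as.integer(ceiling(grid$n_slots / 2)), grid$n_slots)
}

# Truncated-normal draws on [lo, hi] via inverse CDF; sd = 0 collapses to mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  z <- sd <= 0
  out[z] <- mean[z]
  if (any(!z)) {
    a <- stats::pnorm(lo, mean[!z], sd[!z])
    b <- stats::pnorm(hi, mean[!z], sd[!z])
    u <- stats::runif(sum(!z), a, b)
    out[!z] <- stats::qnorm(u, mean[!z], sd[!z])
  }
  pmin(pmax(out, lo), hi)
}

# Rank-determined report times of a pure-quantizer participant: the mean
# intermediate-slot index of the i-th of n order statistics of a uniform
# draw without replacement from m slots is i * (m + 1) / (n + 1); reports
# sit at the onset of that (fractional) slot.
quantizer_times <- function(n_items, grid) {
  m <- length(intermediate_slots(grid))
  idx <- seq_len(n_items) * (m + 1) / (n_items + 1)     # 1..m scale
  idx * grid$slot_duration                              # onset of slot 1+idx
}

# Draw an internal-order permutation: identity w.p. 1 - p, otherwise
# uniform over the n! - 1 wrong permutations.
draw_order_permutation <- function(n, p, perms = permutations(n)) {
  if (n == 1L || stats::runif(1) >= p) return(seq_len(n))
  wrong <- which(rowSums(perms != rep(seq_len(n), each = nrow(perms))) > 0L)
  perms[wrong[sample.int(length(wrong), 1L)], ]
}

#' Simulate synthetic behavioral sessions
#'
#' Generates trial-level report records with the statistical structure the
#' downstream analyses assume. Each participant is independently a random
#' responder (uniform reports), a quantizer (deterministic rank-only
#' reports), or a regular reporter whose per-item internal times are
#' truncated-Gaussian around the true slot onsets. The internal order is
#' corrupted with probability `order_error` (wrong permutations
#' equiprobable) and reports are assigned to items so that their order
#' always matches the internal order: the sorted internal times are dealt
#' out according to the drawn permutation.
#'
#' @param experiment_id One of `experiment_ids()`.
#' @param n_participants Number of simulated participants.
#' @param n_trials Trials per participant (default 15).
#' @param grid A [slot_grid()].
#' @param noise A [noise_profile()].
#' @param order_error Probability that a trial's internal order is a
#'   mistake. Default 0.
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   datasets.
#' @param participant_prefix Prefix for generated participant IDs.
#' @return A data.frame of trial records with columns `participant_id`,
#'   `trial_index`, `experiment_id`, `item_rank`, `presented_slot`,
#'   `reported_time_s` (one row per reported intermediate item).
#' @examples
#' rec <- simulate_session("exp2", n_participants = 3, seed = 1)
#' head(rec)
#' @export
simulate_session <- function(experiment_id, n_participants, n_trials = 15L,
                             grid = slot_grid(), noise = noise_profile(),
                             order_error = 0, seed = NULL,
                             participant_prefix = "P") {
  experiment_id <- match.arg(experiment_id, experiment_ids())
  stopifnot(inherits(grid, "slot_grid"), inherits(noise, "noise_profile"))
  if (n_trials < 1L) stop("`n_trials` must be >= 1")
  if (!is.finite(order_error) || order_error < 0 || order_error > 1)
    stop("`order_error` must be a probability")
  if (!is.null(seed)) set.seed(seed)

  n_int <- experiment_spec(experiment_id)$n_intermediate
  total <- total_duration(grid)
  anchors <- resolve_anchor_slots(noise, grid)
  perms <- permutations(n_int)
  q_times <- quantizer_times(n_int, grid)

  rows <- vector("list", n_participants * n_trials)
  k <- 0L
  for (p in seq_len(n_participants)) {
    pid <- sprintf("%s%04d", participant_prefix, p)
    u <- stats::runif(1)
    type <- if (u < noise$random_responder_fraction) "random"
            else if (u < noise$random_responder_fraction +
                       noise$quantizer_fraction) "quantizer"
            else "regular"
    for (tr in seq_len(n_trials)) {
      sched <- make_schedule(experiment_id, grid)
      slots <- sched$intermediate_slots
      reported <- switch(type,
        random = stats::runif(n_int, 0, total),
        quantizer = {
          sigma_hat <- draw_order_permutation(n_int, order_error, perms)
          q_times[sigma_hat]
        },
        regular = {
          sd <- ifelse(slots %in% anchors, noise$anchor_sd, noise$base_sd)
          y <- rtruncnorm(n_int, slot_onset(slots, grid), sd, 0, total)
          sigma_hat <- draw_order_permutation(n_int, order_error, perms)
          sort(y)[sigma_hat]
        })
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = pid, trial_index = tr,
        experiment_id = experiment_id,
        item_rank = seq_len(n_int), presented_slot = slots,
        reported_time_s = reported,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write trial-record CSV files
#'
#' The on-disk schema is one row per reported item with header
#' `participant_id,trial_index,experiment_id,item_rank,presented_slot,reported_time_s`,
#' UTF-8, `.` decimal separator; times are written with 6 decimal places.
#'
#' @param records A record data.frame as produced by [simulate_session()].
#' @param path File path.
#' @return `read_records()` returns the record data.frame;
#'   `write_records()` returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records[, c("participant_id", "trial_index", "experiment_id",
                     "item_rank", "presented_slot", "reported_time_s")]
  out$reported_time_s <- sprintf("%.6f", out$reported_time_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "trial_index", "experiment_id",
              "item_rank", "presented_slot", "reported_time_s")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop("malformed records file, missing columns: ",
         paste(missing, collapse = ", "))
  rec$item_rank <- as.integer(rec$item_rank)
  rec$presented_slot <- as.integer(rec$presented_slot)
  rec$trial_index <- as.integer(rec$trial_index)
  rec
}
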