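#' Naive independent-encoding flip probability
#'
#' Probability that independently drawn single-item reports for two
#' presented slots come out in the wrong order: the prediction for
#' ordering accuracy if each item's time were encoded and reported
#' independently, with no separate order memory. Exact ties count as a
#' half error. Computed exhaustively over all stored sample pairs when
#' their number is at most `max_exhaustive`, else by seeded Monte Carlo.
#'
#' @param likelihood A [estimate_likelihood()] result.
#' @param slot_i,slot_j Presented slots with `slot_i < slot_j`.
#' @param n_mc Monte-Carlo draws when exhaustive enumeration is too large.
#' @param seed Optional seed for the Monte-Carlo path.
#' @param max_exhaustive Pair-count threshold for exhaustive enumeration.
#' @return Probability in `[0, 1]`.
#' @export
naive_flip_probability <- function(likelihood, slot_i, slot_j,
                                   n_mc = 100000L, seed = NULL,
                                   max_exhaustive = 1e6) {
  assert_likelihood(likelihood)
  if (!(slot_i < slot_j)) stop("need slot_i < slot_j")
  xi <- slot_samples(likelihood, slot_i)
  xj <- slot_samples(likelihood, slot_j)
  if (as.double(length(xi)) * length(xj) <= max_exhaustive) {
    d <- outer(xj, xi, "-")
    mean((d < 0) + 0.5 * (d == 0))
  } else {
    if (!is.null(seed)) set.seed(seed)
    a <- xi[sample.int(length(xi), n_mc, replace = TRUE)]
    b <- xj[sample.int(length(xj), n_mc, replace = TRUE)]
    mean((b < a) + 0.5 * (b == a))
  }
}

#' Naive flip-probability matrix over all slot pairs
#'
#' @inheritParams naive_flip_probability
#' @return A data.frame with columns `slot_i`, `slot_j` (`slot_i < slot_j`)
#'   and `flip_prob`.
#' @export
naive_flip_matrix <- function(likelihood, n_mc = 100000L, seed = NULL,
                              max_exhaustive = 1e6) {
  assert_likelihood(likelihood)
  slots <- intermediate_slots(likelihood$grid)
  pairs <- t(utils::combn(slots, 2L))
  if (!is.null(seed)) set.seed(seed)
  flip <- vapply(seq_len(nrow(pairs)), function(k)
    naive_flip_probability(likelihood, pairs[k, 1L], pairs[k, 2L],
                           n_mc = n_mc, max_exhaustive = max_exhaustive),
    numeric(1))
  data.frame(slot_i = pairs[, 1L], slot_j = pairs[, 2L], flip_prob = flip)
}

#' Naive permutation table for three independently reported items
#'
#' Distribution over the 6 rank patterns of three independent single-item
#' report draws at the given presented slots; ties are shared equally over
#' tie-consistent patterns. Exhaustive over stored sample triples when
#' feasible, else seeded Monte Carlo.
#'
#' @param likelihood A [estimate_likelihood()] result.
#' @param slots Three distinct presented slots in item (presentation)
#'   order, so pattern "123" is the correct ordering.
#' @param n_mc Monte-Carlo draws for the sampling path.
#' @param seed Optional seed.
#' @param max_exhaustive Triple-count threshold for exhaustive enumeration.
#' @return Named probability vector over rank-pattern labels
#'   ("123", "132", ...), summing to 1.
#' @export
naive_permutation_table <- function(likelihood, slots, n_mc = 100000L,
                                    seed = NULL, max_exhaustive = 1e6) {
  assert_likelihood(likelihood)
  if (length(slots) != 3L || anyDuplicated(slots))
    stop("`slots` must be three distinct presented slots")
  xs <- lapply(slots, function(s) slot_samples(likelihood, s))
  perms <- permutations(3L)
  n_comb <- prod(vapply(xs, function(s) as.double(length(s)), numeric(1)))
  triples <- if (n_comb <= max_exhaustive) {
    as.matrix(expand.grid(xs[[1L]], xs[[2L]], xs[[3L]],
                          KEEP.OUT.ATTRS = FALSE))
  } else {
    if (!is.null(seed)) set.seed(seed)
    vapply(xs, function(s)
      s[sample.int(length(s), n_mc, replace = TRUE)], numeric(n_mc))
  }
  w <- pattern_counts_3(triples, perms) / nrow(triples)
  names(w) <- apply(perms, 1L, perm_label)
  w
}

# Vectorized rank-pattern tally for a matrix of report triples (rows).
# Tie-free rows are ranked by pairwise comparisons; the rare tied rows
# fall back to the shared fractional-credit rule.
pattern_counts_3 <- function(x, perms = permutations(3L)) {
  x1 <- x[, 1L]; x2 <- x[, 2L]; x3 <- x[, 3L]
  tied <- x1 == x2 | x1 == x3 | x2 == x3
  w <- numeric(nrow(perms))
  if (any(!tied)) {
    r1 <- 1L + (x1 > x2) + (x1 > x3)
    r2 <- 1L + (x2 > x1) + (x2 > x3)
    r3 <- 1L + (x3 > x1) + (x3 > x2)
    # pattern id in lexicographic order of (r1, r2, r3)
    code <- (r1[!tied] - 1L) * 9L + (r2[!tied] - 1L) * 3L + r3[!tied] - 1L
    perm_code <- (perms[, 1L] - 1L) * 9L + (perms[, 2L] - 1L) * 3L +
      perms[, 3L] - 1L
    tab <- table(factor(code, levels = perm_code))
    w <- w + as.numeric(tab)
  }
  if (any(tied)) {
    # tied rows recur (discrete resampled values): tally unique rows once
    key <- paste(x1[tied], x2[tied], x3[tied])
    mult <- table(key)
    first <- which(tied)[!duplicated(key)]
    for (k in first)
      w <- w + rank_pattern_weights(x[k, ], perms) *
        as.numeric(mult[[paste(x1[k], x2[k], x3[k])]])
  }
  w
}

#' Empirical ordering statistics of trial records
#'
#' Determines, per complete trial, whether the reported times of the
#' intermediate items respect their true presentation order. Trials whose
#' rank set is incomplete are skipped with a warning. Exact report ties
#' receive fractional credit shared over tie-consistent orderings.
#'
#' @param records Trial records ([simulate_session()] schema).
#' @return An `order_stats` list: `trials` (per-trial data.frame with
#'   `participant_id`, `trial_index`, `slots`, `credit`, `pattern`),
#'   `n_trials`, `n_correct` (sum of credits), `accuracy`, and — depending
#'   on the item count — `flip_matrix` (ordering-error probability per
#'   ordered slot pair, n = 2) or `permutation_table` (probability per
#'   rank pattern, n = 3).
#' @export
empirical_order_stats <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  n_items <- max(records$item_rank)
  if (n_items < 2L)
    stop("ordering statistics need at least two intermediate items")
  perms <- permutations(n_items)
  labels <- apply(perms, 1L, perm_label)
  id_row <- perm_index(seq_len(n_items), perms)

  key <- interaction(records$participant_id, records$trial_index, drop = TRUE)
  idx <- split(seq_len(nrow(records)), key)
  complete <- vapply(idx, function(i)
    length(i) == n_items &&
      setequal(records$item_rank[i], seq_len(n_items)), logical(1))
  if (any(!complete))
    warning(sum(!complete), " trial(s) with incomplete rank sets skipped")
  idx <- idx[complete]
  if (length(idx) == 0L) stop("no complete trials")

  G <- length(idx)
  credit <- numeric(G)
  pattern <- character(G)
  slots_i <- integer(G); slots_j <- integer(G)
  slot_str <- character(G)
  pid <- character(G); tri <- integer(G)
  perm_sum <- numeric(nrow(perms))
  for (g in seq_len(G)) {
    i <- idx[[g]][order(records$item_rank[idx[[g]]])]
    x <- records$reported_time_s[i]
    w <- rank_pattern_weights(x, perms)
    perm_sum <- perm_sum + w
    credit[g] <- w[id_row]
    pattern[g] <- labels[which.max(w)]
    s <- records$presented_slot[i]
    slot_str[g] <- paste(s, collapse = ",")
    if (n_items == 2L) { slots_i[g] <- s[1L]; slots_j[g] <- s[2L] }
    pid[g] <- records$participant_id[i[1L]]
    tri[g] <- records$trial_index[i[1L]]
  }
  trials <- data.frame(participant_id = pid, trial_index = tri,
                       slots = slot_str, credit = credit, pattern = pattern,
                       stringsAsFactors = FALSE)

  out <- list(trials = trials,
              n_trials = G,
              n_correct = sum(credit),
              accuracy = mean(credit),
              n_items = n_items)
  if (n_items == 2L) {
    err <- stats::aggregate(list(flip_prob = 1 - credit, n = rep(1L, G)),
                            by = list(slot_i = slots_i, slot_j = slots_j),
                            FUN = sum)
    err$flip_prob <- err$flip_prob / err$n
    out$flip_matrix <- err[order(err$slot_i, err$slot_j),
                           c("slot_i", "slot_j", "flip_prob", "n")]
    rownames(out$flip_matrix) <- NULL
  } else if (n_items == 3L) {
    w <- perm_sum / G
    names(w) <- labels
    out$permutation_table <- w
  }
  class(out) <- "order_stats"
  out
}

#' @export
print.order_stats <- function(x, ...) {
  cat(sprintf(
    "<order_stats> %d trials of %d items; correct-order accuracy %.3f\n",
    x$n_trials, x$n_items, x$accuracy))
  invisible(x)
}

#' Estimate the order-mistake probability from records
#'
#' Under the order-corruption model (wrong permutations equiprobable and
#' reports consistent with the internal order) the probability a trial's
#' reported order is wrong equals `p_sigma`, so its moment estimator is
#' one minus the observed ordering accuracy.
#'
#' @param records Trial records, or an [empirical_order_stats()] result.
#' @return Estimated `p_sigma`.
#' @export
fit_p_sigma <- function(records) {
  st <- if (inherits(records, "order_stats")) records
        else empirical_order_stats(records)
  1 - st$accuracy
}

#' Compare two ordering accuracies (Fisher exact test)
#'
#' Two-sided Fisher exact test on the 2x2 correct/incorrect table, used to
#' compare measured ordering accuracy against the naive independent-
#' encoding prediction.
#'
#' @param correct_a,total_a Correct and total trial counts, group A.
#' @param correct_b,total_b Same for group B.
#' @return Two-sided p-value.
#' @export
compare_accuracies <- function(correct_a, total_a, correct_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("totals must be positive")
  if (correct_a < 0 || correct_b < 0 || correct_a > total_a ||
      correct_b > total_b)
    stop("counts out of range")
  tab <- matrix(round(c(correct_a, total_a - correct_a,
                        correct_b, total_b - correct_b)), 2L, 2L)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Expected correct orderings under random responding
#'
#' A random responder orders `n_items` items correctly with probability
#' `1 / n_items!`, so over `n_trials` trials the expected number of
#' correct orderings is `n_trials / n_items!` — 7.5 for two items and 2.5
#' for three items over 15 trials.
#'
#' @param n_trials Number of trials (>= 0).
#' @param n_items Number of ordered items (>= 2).
#' @return Expected count of correctly ordered trials.
#' @export
expected_correct_under_random <- function(n_trials, n_items) {
  if (n_items < 2L) stop("`n_items` must be >= 2")
  if (n_trials < 0) stop("`n_trials` must be >= 0")
  n_trials / factorial(n_items)
}
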