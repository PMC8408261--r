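#' Internal order-error model
#'
#' The internal representation of the relative order of the n intermediate
#' items is correct with probability `1 - p_sigma`; otherwise it is one of
#' the `n! - 1` wrong permutations, each equally likely. Defaults used for
#' the two- and three-item simulations are 0.08 and 0.1 respectively
#' (see [default_p_sigma()]).
#'
#' @param p_sigma Probability of an order-representation mistake, in
#'   `[0, 1]`.
#' @param n_items Number of intermediate items (>= 1).
#' @return An object of class `order_error_model`.
#' @export
order_error_model <- function(p_sigma, n_items) {
  n_items <- as.integer(n_items)
  if (!is.finite(p_sigma) || p_sigma < 0 || p_sigma > 1)
    stop("`p_sigma` must be a probability in [0, 1]")
  if (is.na(n_items) || n_items < 1L)
    stop("`n_items` must be a positive integer")
  structure(list(p_sigma = p_sigma, n_items = n_items),
            class = "order_error_model")
}

#' @export
print.order_error_model <- function(x, ...) {
  cat(sprintf("<order_error_model> n = %d items, p_sigma = %g\n",
              x$n_items, x$p_sigma))
  invisible(x)
}

#' Default order-mistake probability per item count
#'
#' 0.08 for two intermediate items and 0.1 for three, the values used to
#' simulate the two- and three-item experiments.
#'
#' @param n_items Number of intermediate items.
#' @return A probability.
#' @export
default_p_sigma <- function(n_items) {
  switch(as.character(n_items), "2" = 0.08, "3" = 0.1, 0.1)
}

# true order (rank pattern) of a slot tuple; slots must be distinct
true_order <- function(true_slots) {
  if (anyDuplicated(true_slots))
    stop("`true_slots` must be distinct (order undefined for ties)")
  as.integer(rank(true_slots))
}

#' Likelihood of an internal order representation
#'
#' `P(sigma_hat | true order) = (1 - p_sigma)` when `sigma_hat` equals the
#' true order, and `p_sigma / (n! - 1)` for each wrong permutation.
#'
#' @param sigma_hat Integer permutation of `1:n` (rank pattern: entry i is
#'   the believed rank of item i).
#' @param true_slots Distinct presented slots of the items, in item order.
#' @param model An [order_error_model()].
#' @return A probability.
#' @examples
#' m <- order_error_model(0.1, 3)
#' order_likelihood(c(1, 2, 3), c(3, 5, 8), m)  # 0.9
#' order_likelihood(c(2, 1, 3), c(3, 5, 8), m)  # 0.1 / 5 = 0.02
#' @export
order_likelihood <- function(sigma_hat, true_slots, model) {
  stopifnot(inherits(model, "order_error_model"))
  n <- model$n_items
  if (length(sigma_hat) != n || length(true_slots) != n)
    stop("`sigma_hat` and `true_slots` must have length n_items")
  if (!setequal(sigma_hat, seq_len(n)))
    stop("`sigma_hat` is not a permutation of 1..n")
  sigma <- true_order(true_slots)
  if (all(sigma_hat == sigma)) 1 - model$p_sigma
  else if (n < 2L) 0
  else model$p_sigma / (factorial(n) - 1)
}

#' Sample an internal representation of a trial
#'
#' Internal times are drawn independently per item by bootstrap resampling
#' of the stored single-item reports ([sample_internal_time()]); the
#' internal order equals the true order with probability `1 - p_sigma`,
#' otherwise a uniformly drawn wrong permutation.
#'
#' @param true_slots Distinct presented slots, in item order.
#' @param likelihood A [estimate_likelihood()] result covering those slots.
#' @param model An [order_error_model()].
#' @return An `internal_rep`: list with `t_hat` (seconds, length n) and
#'   `sigma_hat` (integer rank pattern).
#' @export
sample_internal_rep <- function(true_slots, likelihood, model) {
  assert_likelihood(likelihood)
  stopifnot(inherits(model, "order_error_model"))
  n <- model$n_items
  if (length(true_slots) != n)
    stop("`true_slots` must have length n_items")
  sigma <- true_order(true_slots)
  t_hat <- vapply(true_slots, function(s)
    sample_internal_time(likelihood, s, 1L), numeric(1))
  perms <- permutations(n)
  sigma_hat <- if (n == 1L || stats::runif(1) >= model$p_sigma) sigma else {
    wrong <- which(rowSums(perms != rep(sigma, each = nrow(perms))) > 0L)
    perms[wrong[sample.int(length(wrong), 1L)], ]
  }
  structure(list(t_hat = t_hat, sigma_hat = as.integer(sigma_hat)),
            class = "internal_rep")
}

# ---- posterior support ----------------------------------------------------

# All ordered tuples of n distinct intermediate slots: rows of an integer
# matrix (tuple x item). Cached per (grid, n) within a call chain.
posterior_support <- function(grid, n) {
  slots <- intermediate_slots(grid)
  if (n == 1L) return(matrix(slots, ncol = 1L))
  g <- as.matrix(expand.grid(rep(list(slots), n), KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- NULL
  keep <- apply(g, 1L, anyDuplicated) == 0L
  g[keep, , drop = FALSE]
}

# Decoder workspace: everything about the posterior that does not depend
# on the sampled internal representation, precomputed once per
# (likelihood, model) pair so Monte-Carlo loops stay cheap.
decoder_workspace <- function(likelihood, model) {
  assert_likelihood(likelihood)
  n <- model$n_items
  grid <- likelihood$grid
  support <- posterior_support(grid, n)
  slots <- intermediate_slots(grid)
  row_of_slot <- match(support, slots)            # vectorized over matrix
  dim(row_of_slot) <- dim(support)
  perms <- permutations(n)
  rank_idx <- apply(support, 1L, function(s) perm_index(as.integer(rank(s)), perms))
  list(n = n, grid = grid, support = support, row_idx = row_of_slot,
       onsets = matrix(slot_onset(support, grid), nrow(support), n),
       perms = perms, rank_idx = rank_idx,
       matrix = likelihood$matrix, p_sigma = model$p_sigma)
}

posterior_from_workspace <- function(ws, t_hat, sigma_hat) {
  bins <- time_to_bin(t_hat, ws$grid)
  w <- rep(1, nrow(ws$support))
  for (i in seq_len(ws$n))
    w <- w * ws$matrix[ws$row_idx[, i], bins[i]]
  if (ws$n > 1L) {
    perm_w <- rep(ws$p_sigma / (factorial(ws$n) - 1), nrow(ws$perms))
    perm_w[perm_index(as.integer(sigma_hat), ws$perms)] <- 1 - ws$p_sigma
    w <- w * perm_w[ws$rank_idx]
  }
  tot <- sum(w)
  if (tot <= 0)
    stop("degenerate posterior: all tuples have zero likelihood ",
         "(consider a positive pseudocount in estimate_likelihood)")
  unname(w / tot)
}

#' Posterior over presentation-slot tuples
#'
#' Given an internal representation (noisy times plus internal order), the
#' posterior over the ordered tuples of distinct intermediate slots is
#' proportional to the product of the per-item binned report likelihoods
#' times the order-representation likelihood, under a uniform prior over
#' tuples (the experimental schedule draws slots uniformly without
#' replacement). Internal times enter through their slot bin.
#'
#' @param rep An `internal_rep` from [sample_internal_rep()], or a list
#'   with numeric `t_hat` and integer `sigma_hat`.
#' @param likelihood A [estimate_likelihood()] result.
#' @param model An [order_error_model()].
#' @return A `posterior_table`: list with `support` (tuple x item integer
#'   matrix of slots) and `mass` (probabilities summing to 1).
#' @export
posterior <- function(rep, likelihood, model) {
  stopifnot(inherits(model, "order_error_model"))
  if (length(rep$t_hat) != model$n_items)
    stop("`rep$t_hat` must have length n_items")
  if (!setequal(rep$sigma_hat, seq_len(model$n_items)))
    stop("`rep$sigma_hat` is not a permutation of 1..n")
  total <- total_duration(likelihood$grid)
  if (any(rep$t_hat < 0 | rep$t_hat > total))
    stop("internal times outside [0, total_duration]")
  ws <- decoder_workspace(likelihood, model)
  mass <- posterior_from_workspace(ws, rep$t_hat, rep$sigma_hat)
  structure(list(support = ws$support, mass = mass, grid = ws$grid),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("<posterior_table> %d tuples of %d slots; top mass %.3g\n",
              nrow(x$support), ncol(x$support), max(x$mass)))
  invisible(x)
}

#' Posterior-mean time reports
#'
#' The model's reported time for each item is the expectation of that
#' item's presentation time (slot onset) under the posterior.
#'
#' @param post A [posterior()] result.
#' @return Numeric vector of reported times (seconds), one per item.
#' @export
posterior_mean_reports <- function(post) {
  stopifnot(inherits(post, "posterior_table"))
  onsets <- matrix(slot_onset(post$support, post$grid),
                   nrow(post$support), ncol(post$support))
  as.numeric(crossprod(onsets, post$mass))
}

#' Monte-Carlo report distributions for one slot configuration
#'
#' Repeats sample internal representation -> posterior -> posterior-mean
#' reports, for a fixed tuple of presented slots, and summarizes the
#' induced report distributions and ordering-error rates of the model.
#' Ties between mean reports are credited half (n = 2) or fractionally
#' over tie-consistent permutations.
#'
#' @param true_slots Distinct presented slots, in item order.
#' @param likelihood A [estimate_likelihood()] result.
#' @param model An [order_error_model()].
#' @param n_samples Number of Monte-Carlo samples (>= 1).
#' @param seed Optional integer seed.
#' @return List with `reports` (`n_samples` x n matrix of posterior-mean
#'   reports), `mean_reports`, `flip_rate` (probability the reported order
#'   of any item pair reverses the true order; for n = 2 the probability
#'   that the rank-2 report precedes the rank-1 report), and
#'   `permutation_probs` (named over rank-pattern labels).
#' @export
simulate_reports <- function(true_slots, likelihood, model,
                             n_samples = 10000L, seed = NULL) {
  stopifnot(inherits(model, "order_error_model"))
  if (n_samples < 1L) stop("`n_samples` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_items
  sigma <- true_order(true_slots)
  ws <- decoder_workspace(likelihood, model)
  perms <- ws$perms
  reports <- matrix(NA_real_, n_samples, n)
  perm_w <- numeric(nrow(perms))
  for (k in seq_len(n_samples)) {
    rep_k <- sample_internal_rep(true_slots, likelihood, model)
    mass <- posterior_from_workspace(ws, rep_k$t_hat, rep_k$sigma_hat)
    reports[k, ] <- as.numeric(crossprod(ws$onsets, mass))
    perm_w <- perm_w + rank_pattern_weights(reports[k, ], perms)
  }
  perm_w <- perm_w / n_samples
  names(perm_w) <- apply(perms, 1L, perm_label)
  flip <- 1 - perm_w[[perm_label(sigma)]]
  if (n == 1L) flip <- 0
  list(reports = reports,
       mean_reports = colMeans(reports),
       flip_rate = flip,
       permutation_probs = perm_w)
}

#' Bayesian-simulated experiment records
#'
#' Simulates whole sessions of the Bayesian observer: for each trial a
#' schedule is drawn as in the experiment, one internal representation is
#' sampled, and the posterior-mean reports become the trial's reported
#' times. The output uses the same record schema as [simulate_session()],
#' so every empirical analysis runs unchanged on model output.
#'
#' @param experiment_id One of `experiment_ids()`.
#' @param likelihood A [estimate_likelihood()] result.
#' @param n_trials Total number of simulated trials.
#' @param p_sigma Order-mistake probability; default [default_p_sigma()]
#'   for the experiment's item count.
#' @param trials_per_participant Trials grouped per synthetic participant
#'   ID (affects only grouping, default 15).
#' @param seed Optional integer seed.
#' @return A record data.frame (see [simulate_session()]).
#' @export
simulate_experiment_records <- function(experiment_id, likelihood,
                                        n_trials = 10000L,
                                        p_sigma = NULL,
                                        trials_per_participant = 15L,
                                        seed = NULL) {
  experiment_id <- match.arg(experiment_id, experiment_ids())
  assert_likelihood(likelihood)
  if (!is.null(seed)) set.seed(seed)
  grid <- likelihood$grid
  n <- experiment_spec(experiment_id)$n_intermediate
  if (is.null(p_sigma)) p_sigma <- default_p_sigma(n)
  model <- order_error_model(p_sigma, n)
  ws <- decoder_workspace(likelihood, model)
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sched <- make_schedule(experiment_id, grid)
    slots <- sched$intermediate_slots
    rep_k <- sample_internal_rep(slots, likelihood, model)
    mass <- posterior_from_workspace(ws, rep_k$t_hat, rep_k$sigma_hat)
    rows[[k]] <- data.frame(
      participant_id = sprintf("B%05d", (k - 1L) %/% trials_per_participant + 1L),
      trial_index = (k - 1L) %% trials_per_participant + 1L,
      experiment_id = experiment_id,
      item_rank = seq_len(n), presented_slot = slots,
      reported_time_s = as.numeric(crossprod(ws$onsets, mass)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
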