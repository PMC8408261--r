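# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (explicit loops, closed forms),
# kept separate from the package's computation paths.

# Build a report_likelihood by hand from a matrix and per-slot samples.
toy_likelihood <- function(matrix, samples_by_slot, grid = slot_grid()) {
  stopifnot(nrow(matrix) == length(intermediate_slots(grid)))
  dimnames(matrix) <- list(slot = intermediate_slots(grid),
                           bin = seq_len(ncol(matrix)))
  names(samples_by_slot) <- intermediate_slots(grid)[
    seq_along(samples_by_slot)]
  structure(list(grid = grid, matrix = matrix,
                 samples_by_slot = samples_by_slot),
            class = "report_likelihood")
}

# Uniform likelihood over all report bins, one arbitrary stored sample
# per slot (at the slot onset).
uniform_likelihood <- function(grid = slot_grid()) {
  slots <- intermediate_slots(grid)
  m <- matrix(1 / grid$n_slots, length(slots), grid$n_slots)
  toy_likelihood(m, as.list(slot_onset(slots, grid)), grid)
}

# Random row-stochastic likelihood with matching random samples.
random_likelihood <- function(grid = slot_grid(), n_samples_per_slot = 5L) {
  slots <- intermediate_slots(grid)
  m <- matrix(stats::rexp(length(slots) * grid$n_slots),
              length(slots), grid$n_slots)
  m <- m / rowSums(m)
  samples <- lapply(slots, function(s)
    stats::runif(n_samples_per_slot, 0, total_duration(grid)))
  toy_likelihood(m, samples, grid)
}

# Brute-force posterior over ordered tuples of distinct intermediate
# slots: explicit loops over the support, no shared code with the
# package's decoder internals.
oracle_posterior <- function(t_hat, sigma_hat, likelihood, p_sigma) {
  grid <- likelihood$grid
  slots <- intermediate_slots(grid)
  n <- length(t_hat)
  bins <- floor(t_hat / grid$slot_duration) + 1
  bins <- pmin(pmax(bins, 1), grid$n_slots)
  tuples <- as.matrix(expand.grid(rep(list(slots), n)))
  tuples <- tuples[apply(tuples, 1, function(r) !any(duplicated(r))), ,
                   drop = FALSE]
  w <- numeric(nrow(tuples))
  for (k in seq_len(nrow(tuples))) {
    p <- 1
    for (i in seq_len(n))
      p <- p * likelihood$matrix[as.character(tuples[k, i]),
                                 as.character(bins[i])]
    if (n >= 2) {
      sig <- rank(tuples[k, ])
      p <- p * if (all(sig == sigma_hat)) 1 - p_sigma
               else p_sigma / (factorial(n) - 1)
    }
    w[k] <- p
  }
  list(support = tuples, mass = w / sum(w))
}

# Match an oracle posterior's tuples against a package posterior_table.
align_oracle_mass <- function(oracle, post) {
  key <- function(m) apply(m, 1, paste, collapse = ",")
  oracle$mass[match(key(post$support), key(oracle$support))]
}

# Welch two-sample t statistic / df / p by the textbook formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# One-way ANOVA F by the sums-of-squares formulas.
oracle_anova_F <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(statistic = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more probable than the
# observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Records table built directly from (participant, trial, slots, reports).
records_from_trials <- function(trials, experiment_id = "exp2") {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(participant_id = tr$participant_id,
               trial_index = tr$trial_index,
               experiment_id = experiment_id,
               item_rank = seq_along(tr$slots),
               presented_slot = tr$slots,
               reported_time_s = tr$reports,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Clean noise profile: regular reporters only.
clean_noise <- function(base_sd = 2.5, anchor_sd = 0.5) {
  noise_profile(base_sd = base_sd, anchor_sd = anchor_sd,
                quantizer_fraction = 0, random_responder_fraction = 0)
}
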