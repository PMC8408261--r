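# Toy grid with three intermediate slots (2, 3, 4) for enumeration checks.
toy_grid <- slot_grid(n_slots = 5, slot_duration = 1.5)

toy3_likelihood <- function() {
  m <- rbind(c(0.10, 0.40, 0.20, 0.20, 0.10),
             c(0.05, 0.15, 0.50, 0.20, 0.10),
             c(0.10, 0.10, 0.25, 0.30, 0.25))
  toy_likelihood(m, list(2.2, 3.7, 5.2), toy_grid)
}

test_that("order likelihood follows the discrete mistake model", {
  m2 <- order_error_model(0.08, 2)
  expect_equal(order_likelihood(c(1, 2), c(4, 7), m2), 0.92)
  expect_equal(order_likelihood(c(2, 1), c(4, 7), m2), 0.08)
  m3 <- order_error_model(0.1, 3)
  expect_equal(order_likelihood(c(1, 2, 3), c(3, 5, 8), m3), 0.9)
  expect_equal(order_likelihood(c(2, 1, 3), c(3, 5, 8), m3), 0.02)  # 0.1 / 5
  m0 <- order_error_model(0, 2)
  expect_equal(order_likelihood(c(2, 1), c(4, 7), m0), 0)
  # argsort convention: the true order need not be the identity
  expect_equal(order_likelihood(c(2, 1), c(7, 4), m2), 0.92)
  expect_error(order_likelihood(c(1, 2), c(4, 4), m2), "distinct")
  expect_error(order_likelihood(c(1, 1), c(4, 7), m2), "permutation")
})

test_that("internal-order samples hit each wrong permutation equally", {
  lik <- toy3_likelihood()
  m0 <- order_error_model(0, 3)
  set.seed(41)
  for (k in 1:20)
    expect_equal(sample_internal_rep(c(2, 3, 4), lik, m0)$sigma_hat, 1:3)
  m1 <- order_error_model(1, 2)
  for (k in 1:20)
    expect_equal(sample_internal_rep(c(2, 3), lik,
                                     order_error_model(1, 2))$sigma_hat,
                 c(2L, 1L))
  set.seed(42)
  n <- 50000
  m <- order_error_model(0.1, 3)
  draws <- replicate(n, paste(sample_internal_rep(c(2, 3, 4), lik,
                                                  m)$sigma_hat,
                              collapse = ""))
  freq <- table(draws) / n
  wrong <- setdiff(names(freq), "123")
  expect_equal(length(wrong), 5L)
  se <- sqrt(0.02 * 0.98 / n)
  for (lbl in wrong) expect_lt(abs(freq[[lbl]] - 0.02), 3 * se)
  expect_lt(abs(freq[["123"]] - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})

test_that("uniform likelihood with P_sigma = 0 spreads mass over the 36 ordered pairs", {
  lik <- uniform_likelihood()
  m <- order_error_model(0, 2)
  post <- posterior(list(t_hat = c(5, 9), sigma_hat = c(1L, 2L)), lik, m)
  increasing <- post$support[, 1] < post$support[, 2]
  expect_equal(sum(increasing), 36L)
  expect_equal(unname(post$mass[increasing]), rep(1 / 36, 36))
  expect_equal(sum(post$mass[!increasing]), 0)
})

test_that("posterior matches brute-force enumeration on toy grids", {
  lik <- toy3_likelihood()
  for (n in 2:3) {
    model <- order_error_model(0.13, n)
    set.seed(50 + n)
    for (rep_i in 1:10) {
      slots <- sort(sample(2:4, n))
      t_hat <- runif(n, 0, total_duration(toy_grid))
      perms <- permutations(n)
      sigma_hat <- perms[sample.int(nrow(perms), 1), ]
      rep_obj <- list(t_hat = t_hat, sigma_hat = as.integer(sigma_hat))
      post <- posterior(rep_obj, lik, model)
      oracle <- oracle_posterior(t_hat, sigma_hat, lik, 0.13)
      expect_equal(post$mass, align_oracle_mass(oracle, post),
                   tolerance = 1e-12)
      # and the posterior means agree with direct expectation over tuples
      mu <- posterior_mean_reports(post)
      onsets <- (oracle$support - 1) * toy_grid$slot_duration
      expect_equal(mu, as.numeric(t(onsets) %*% oracle$mass),
                   tolerance = 1e-12)
    }
  }
})

test_that("posterior matches enumeration on the full 9-slot grid", {
  set.seed(60)
  lik <- random_likelihood()
  for (n in 2:3) {
    model <- order_error_model(0.08, n)
    slots <- sort(sample(2:10, n))
    rep_obj <- sample_internal_rep(slots, lik, model)
    post <- posterior(rep_obj, lik, model)
    oracle <- oracle_posterior(rep_obj$t_hat, rep_obj$sigma_hat, lik, 0.08)
    expect_equal(post$mass, align_oracle_mass(oracle, post),
                 tolerance = 1e-12)
  }
})

test_that("every posterior normalizes to one under randomized likelihoods", {
  set.seed(61)
  for (k in 1:25) {
    lik <- random_likelihood()
    n <- sample(2:3, 1)
    model <- order_error_model(runif(1), n)
    rep_obj <- sample_internal_rep(sort(sample(2:10, n)), lik, model)
    post <- posterior(rep_obj, lik, model)
    expect_lt(abs(sum(post$mass) - 1), 1e-10)
    expect_true(all(post$mass >= 0))
    expect_true(all(apply(post$support, 1, anyDuplicated) == 0))
  }
})

test_that("P_sigma = 0 restricts support to the internal order and orders the means", {
  set.seed(62)
  for (k in 1:10) {
    lik <- random_likelihood()
    n <- sample(2:3, 1)
    model <- order_error_model(0, n)
    perms <- permutations(n)
    sigma_hat <- perms[sample.int(nrow(perms), 1), ]
    rep_obj <- list(t_hat = runif(n, 0, 16.5),
                    sigma_hat = as.integer(sigma_hat))
    post <- posterior(rep_obj, lik, model)
    consistent <- apply(post$support, 1, function(s)
      all(rank(s) == sigma_hat))
    expect_equal(sum(post$mass[!consistent]), 0)
    mu <- posterior_mean_reports(post)
    expect_true(all(diff(mu[order(sigma_hat)]) >= -1e-12))
  }
})

test_that("flat order term reduces to independent per-item decoding", {
  set.seed(63)
  for (n in 2:3) {
    lik <- random_likelihood()
    p_flat <- (factorial(n) - 1) / factorial(n)
    model <- order_error_model(p_flat, n)
    slots <- sort(sample(2:10, n))
    t_hat <- runif(n, 0, 16.5)
    perms <- permutations(n)
    sigma_hat <- as.integer(perms[sample.int(nrow(perms), 1), ])
    post <- posterior(list(t_hat = t_hat, sigma_hat = sigma_hat), lik, model)
    # oracle: product of single-item posteriors, renormalized on the
    # distinct-tuple support
    bins <- time_to_bin(t_hat, lik$grid)
    w <- rep(1, nrow(post$support))
    for (i in seq_len(n)) {
      rowp <- lik$matrix[, bins[i]]
      rowp <- rowp / sum(rowp)
      w <- w * rowp[match(post$support[, i], 2:10)]
    }
    expect_equal(post$mass, unname(w / sum(w)), tolerance = 1e-10)
  }
})

test_that("time reversal maps mean reports to their mirror image", {
  set.seed(64)
  g <- slot_grid()
  total <- total_duration(g)
  for (k in 1:5) {
    lik <- random_likelihood()
    n <- sample(2:3, 1)
    model <- order_error_model(0.15, n)
    # reversed likelihood: slots and bins both mirrored
    rm <- lik$matrix[rev(seq_len(nrow(lik$matrix))),
                     rev(seq_len(ncol(lik$matrix)))]
    rlik <- toy_likelihood(unname(rm), lik$samples_by_slot, g)
    slots <- sort(sample(2:10, n))
    # internal times at bin centers so reversal preserves the bin map
    bins <- sample(1:11, n, replace = TRUE)
    t_hat <- (bins - 0.5) * g$slot_duration
    perms <- permutations(n)
    sigma_hat <- as.integer(perms[sample.int(nrow(perms), 1), ])
    mu <- posterior_mean_reports(
      posterior(list(t_hat = t_hat, sigma_hat = sigma_hat), lik, model))
    mu_rev <- posterior_mean_reports(
      posterior(list(t_hat = total - t_hat,
                     sigma_hat = as.integer(n + 1L - sigma_hat)),
                rlik, model))
    # mirrored onsets: slot onset k maps to onset of slot n_slots + 1 - k,
    # i.e. t -> total - slot_duration - t
    expect_equal(mu_rev, total - g$slot_duration - mu, tolerance = 1e-9)
  }
})

test_that("higher order-mistake rates shrink the rank gap at a shared slot", {
  lik <- toy3_likelihood()
  gaps <- vapply(c(0, 0.2, 0.4, 0.6), function(p) {
    model <- order_error_model(p, 2)
    # exact expectation over the enumerable internal representations:
    # single stored sample per slot, two internal orders
    gap <- 0
    for (slots in list(c(2, 3), c(2, 4), c(3, 4))) {
      t_hat <- vapply(slots, function(s)
        lik$samples_by_slot[[as.character(s)]][1], numeric(1))
      for (sig in list(c(1L, 2L), c(2L, 1L))) {
        w <- if (all(sig == c(1L, 2L))) 1 - p else p
        mu <- posterior_mean_reports(
          posterior(list(t_hat = t_hat, sigma_hat = sig), lik, model))
        gap <- gap + w * (mu[2] - mu[1]) / 3
      }
    }
    gap
  }, numeric(1))
  expect_true(all(diff(gaps) < 1e-12))
  expect_gt(gaps[1], 0)
})

test_that("degenerate all-zero posteriors are reported as errors", {
  g <- slot_grid()
  m <- matrix(0, 9, 11); m[, 1] <- 1   # all mass in bin 1
  lik <- toy_likelihood(m, as.list(rep(0.1, 9)), g)
  model <- order_error_model(0, 2)
  expect_error(
    posterior(list(t_hat = c(8, 9), sigma_hat = c(1L, 2L)), lik, model),
    "degenerate")
  expect_error(
    posterior(list(t_hat = c(20, 9), sigma_hat = c(1L, 2L)),
              uniform_likelihood(), model), "total_duration")
})

test_that("Monte-Carlo reports: zero order error means zero flips", {
  set.seed(65)
  lik <- random_likelihood()
  sr <- simulate_reports(c(4, 7), lik, order_error_model(0, 2),
                         n_samples = 300, seed = 66)
  expect_equal(unname(sr$flip_rate), 0)
  expect_true(all(sr$reports[, 1] <= sr$reports[, 2] + 1e-12))
})

test_that("quantized limit: reports depend only on rank, not presented slot", {
  lik <- uniform_likelihood()
  model <- order_error_model(0, 2)
  sr_a <- simulate_reports(c(2, 3), lik, model, n_samples = 50, seed = 67)
  sr_b <- simulate_reports(c(8, 10), lik, model, n_samples = 50, seed = 68)
  # posterior is independent of the internal times, so every sample gives
  # the same rank-determined posterior means
  expect_equal(max(abs(sweep(sr_a$reports, 2, sr_a$mean_reports))), 0)
  expect_equal(sr_a$mean_reports, sr_b$mean_reports, tolerance = 1e-12)
})

test_that("Bayesian session records reproduce and respect the schema", {
  set.seed(69)
  lik <- random_likelihood(n_samples_per_slot = 10)
  a <- simulate_experiment_records("exp2", lik, 60, seed = 70)
  b <- simulate_experiment_records("exp2", lik, 60, seed = 70)
  expect_identical(a, b)
  expect_equal(nrow(a), 120L)
  v <- validate_records(a)
  expect_equal(v$n_issues, 0L)
})
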