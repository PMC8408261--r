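two_slot_likelihood <- function(si, sj, slot_i = 4, slot_j = 7) {
  g <- slot_grid()
  samples <- as.list(slot_onset(2:10, g))
  samples[[slot_i - 1]] <- si
  samples[[slot_j - 1]] <- sj
  toy_likelihood(matrix(1 / 11, 9, 11), samples, g)
}

test_that("naive flip probability on hand-enumerable sample sets", {
  # identical distributions: symmetry with the half-tie rule gives 1/2
  lik <- two_slot_likelihood(c(1, 2, 3), c(1, 2, 3))
  expect_equal(naive_flip_probability(lik, 4, 7), 0.5)
  # disjoint supports in the correct order never flip
  lik <- two_slot_likelihood(c(1, 2), c(5, 6))
  expect_equal(naive_flip_probability(lik, 4, 7), 0)
  # {1,3} vs {2,4}: only the (3,2) pair flips -> 1/4
  lik <- two_slot_likelihood(c(1, 3), c(2, 4))
  expect_equal(naive_flip_probability(lik, 4, 7), 0.25)
  expect_error(naive_flip_probability(lik, 7, 4), "slot_i < slot_j")
})

test_that("exhaustive and Monte-Carlo flip estimates agree", {
  set.seed(81)
  lik <- two_slot_likelihood(rnorm(40, 4.5, 2), rnorm(40, 9, 2))
  exact <- naive_flip_probability(lik, 4, 7)
  mc <- naive_flip_probability(lik, 4, 7, n_mc = 20000, seed = 82,
                               max_exhaustive = 10)
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 20000))
})

test_that("naive permutation table on delta, exchangeable and toy samples", {
  g <- slot_grid()
  # delta likelihood: all mass on the correct pattern
  lik <- toy_likelihood(matrix(1 / 11, 9, 11),
                        as.list(slot_onset(2:10, g)), g)
  pt <- naive_permutation_table(lik, c(3, 5, 8))
  expect_equal(unname(pt["123"]), 1)
  expect_equal(sum(pt), 1, tolerance = 1e-10)

  # i.i.d. draws (every slot shares one sample pool): every pattern 1/6
  set.seed(83)
  pool <- runif(200, 0, 16.5)
  lik <- toy_likelihood(matrix(1 / 11, 9, 11), rep(list(pool), 9), g)
  pt <- naive_permutation_table(lik, c(3, 5, 8), n_mc = 30000, seed = 84,
                                max_exhaustive = 10)
  se <- sqrt((1 / 6) * (5 / 6) / 30000)
  expect_true(all(abs(pt - 1 / 6) < 3.5 * se))

  # two-point toy: exhaustive enumeration by hand over the 8 triples
  lik <- toy_likelihood(matrix(1 / 11, 9, 11),
                        c(list(c(1, 6)), list(c(2, 5)), list(c(3, 4)),
                          as.list(slot_onset(5:10, g))), g)
  pt <- naive_permutation_table(lik, c(2, 3, 4))
  hand <- c("123" = 0, "132" = 0, "213" = 0, "231" = 0, "312" = 0, "321" = 0)
  for (a in c(1, 6)) for (b in c(2, 5)) for (cc in c(3, 4)) {
    lbl <- paste(rank(c(a, b, cc)), collapse = "")
    hand[lbl] <- hand[lbl] + 1 / 8
  }
  expect_equal(pt[names(hand)], hand)
})

test_that("empirical ordering statistics on constructed trials", {
  # noiseless data is always correctly ordered
  rec <- simulate_session("exp2", 10, grid = slot_grid(),
                          noise = clean_noise(0, 0), seed = 85)
  expect_equal(empirical_order_stats(rec)$accuracy, 1)

  # hand-built trials incl. an exact tie (half credit) and a flip
  trials <- list(
    list(participant_id = "A", trial_index = 1, slots = c(3, 6),
         reports = c(2, 8)),                    # correct
    list(participant_id = "A", trial_index = 2, slots = c(4, 7),
         reports = c(9, 5)),                    # flipped
    list(participant_id = "A", trial_index = 3, slots = c(2, 9),
         reports = c(6, 6)))                    # tie -> 1/2
  st <- empirical_order_stats(records_from_trials(trials))
  expect_equal(st$n_trials, 3L)
  expect_equal(st$n_correct, 1.5)
  expect_equal(st$accuracy, 0.5)
  fm <- st$flip_matrix
  expect_equal(fm$flip_prob[fm$slot_i == 4 & fm$slot_j == 7], 1)
  expect_equal(fm$flip_prob[fm$slot_i == 2 & fm$slot_j == 9], 0.5)

  # incomplete trials are skipped with a warning
  rec2 <- records_from_trials(trials)
  rec2 <- rec2[-2, ]  # drop rank 2 of trial 1
  expect_warning(st2 <- empirical_order_stats(rec2), "incomplete")
  expect_equal(st2$n_trials, 2L)
})

test_that("three-item permutation table sums to one and finds the flip", {
  trials <- list(
    list(participant_id = "A", trial_index = 1, slots = c(3, 5, 8),
         reports = c(2, 6, 9)),                 # 123
    list(participant_id = "A", trial_index = 2, slots = c(2, 6, 9),
         reports = c(5, 3, 10)))                # 213
  st <- empirical_order_stats(records_from_trials(trials, "exp3"))
  expect_equal(sum(st$permutation_table), 1, tolerance = 1e-10)
  expect_equal(unname(st$permutation_table["123"]), 0.5)
  expect_equal(unname(st$permutation_table["213"]), 0.5)
})

test_that("generator round-trip recovers the order-corruption rate", {
  rec <- simulate_session("exp2", 200, 15, noise = clean_noise(1.5, 0.5),
                          order_error = 0.1, seed = 86)
  p_hat <- fit_p_sigma(rec)
  se <- sqrt(0.1 * 0.9 / 3000)
  expect_lt(abs(p_hat - 0.1), 3 * se)
})

test_that("Fisher comparison matches hypergeometric enumeration", {
  expect_equal(compare_accuracies(8, 16, 8, 16), 1)
  p <- compare_accuracies(10, 10, 0, 10)
  expect_equal(p, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  # group order does not matter
  expect_equal(compare_accuracies(30, 50, 11, 40),
               compare_accuracies(11, 40, 30, 50), tolerance = 1e-12)
  expect_equal(compare_accuracies(30, 50, 11, 40),
               oracle_fisher_p(30, 20, 11, 29), tolerance = 1e-10)
  expect_error(compare_accuracies(1, 0, 1, 2), "positive")
})

test_that("chance-level expectations use 1 / n! per trial", {
  expect_equal(expected_correct_under_random(15, 3), 2.5)
  expect_equal(expected_correct_under_random(15, 2), 7.5)
  expect_equal(expected_correct_under_random(0, 4), 0)
  expect_error(expected_correct_under_random(15, 1), "n_items")
})

test_that("naive flip probability falls with slot separation for unimodal noise", {
  g <- slot_grid()
  set.seed(87)
  samples <- lapply(2:10, function(s)
    pmin(pmax(rnorm(400, slot_onset(s, g), 2), 0), 16.5))
  lik <- toy_likelihood(matrix(1 / 11, 9, 11), samples, g)
  fm <- naive_flip_matrix(lik)
  sep <- fm$slot_j - fm$slot_i
  by_sep <- tapply(fm$flip_prob, sep, mean)
  expect_true(all(diff(by_sep) < 0))
  expect_gt(by_sep[["1"]], 0.25)
  expect_lt(by_sep[["8"]], 0.05)
})
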