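test_that("the DP match-count distribution equals brute-force enumeration on toys", {
  # hand-set 4-disk toy: one certain match, one impossible, two coin flips
  p_toy <- c(1, 0, 0.5, 0.5)
  expect_equal(unname(subset_match_pmf(p_toy, 2)), enum_match_pmf(p_toy, 2),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:8) {
    n <- sample(3:6, 1)
    N <- sample(seq_len(n), 1)
    p <- runif(n)
    expect_equal(unname(subset_match_pmf(p, N)), enum_match_pmf(p, N),
                 tolerance = 1e-12)
  }
})

test_that("the full-set case reduces to the Poisson-binomial distribution", {
  tr <- make_trial("uniform", 9, 6)
  params <- subsampling_params(36, 5)
  d <- signed_offset(tr$test_hue, tr$disk_hues)
  p <- match_probability(d, params$sigma)
  expect_equal(unname(match_count_distribution(tr, params))[1:37],
               poisson_binomial_pmf(p)[1:37], tolerance = 1e-10)
})

test_that("with vanishing noise the match count is the true count", {
  tr <- make_trial("gaussian", 0, 0)
  md <- match_count_distribution(tr, subsampling_params(36, 1e-4))
  expect_equal(unname(md[["8"]]), 1, tolerance = 1e-9)
})

test_that("the response PMF mixes the multiplier correctly and conserves mass", {
  # point mass at k = 3 with N = 9 -> multiplier 1..4 gives 3, 6, 8, 8
  toy <- c(0, 0, 0, 1, rep(0, 6))
  pmf <- ffreport:::multiplier_mix_pmf(toy, 4L)
  expect_equal(unname(pmf[c("3", "6", "8")]), c(0.25, 0.25, 0.5))
  expect_equal(sum(pmf), 1)
  # N = 36: multiplier is 1, pmf is the clipped match-count distribution
  tr <- make_trial("bimodal", 30, -12)
  params <- subsampling_params(36, 3)
  md <- match_count_distribution(tr, params)
  pm <- response_pmf(tr, params)
  expect_equal(unname(pm), c(md[1:8], sum(md[9:37])), ignore_attr = TRUE,
               tolerance = 1e-12)
  # conservation across random parameter draws
  set.seed(6)
  for (i in 1:5) {
    params <- subsampling_params(sample(36, 1), runif(1, 0.5, 10))
    tr <- make_trial(sample(ffr_conditions(), 1), sample(0:47, 1),
                     sample(test_offsets(), 1))
    expect_equal(sum(response_pmf(tr, params)), 1, tolerance = 1e-9)
  }
})

test_that("DP distribution matches Monte-Carlo frequencies of the generative observer", {
  set.seed(31)
  nmc <- 30000
  for (i in 1:2) {
    tr <- make_trial(sample(ffr_conditions(), 1), sample(0:47, 1),
                     sample(test_offsets(), 1))
    params <- subsampling_params(sample(5:36, 1), runif(1, 1, 8))
    md <- match_count_distribution(tr, params)
    draws <- simulate_subsampling_response(tr, params, n = nmc,
                                           use_multiplier = FALSE)
    # compare clipped match counts (simulation clips at 8)
    clipped <- c(md[1:8], sum(md[9:length(md)]))
    emp <- tabulate(draws + 1L, 9) / nmc
    se <- sqrt(clipped * (1 - clipped) / nmc)
    expect_true(all(abs(emp - clipped) <= 3 * se + 1e-12))
  }
})

test_that("the negative log-likelihood is zero for certain data and additive", {
  s <- generate_session(20, seed = 13)
  s$response <- NA_integer_
  s <- simulate_dataset(s, subsampling_params(36, 0.08), seed = 14)
  # near-deterministic observer: keep only offset-0 trials whose pmf is ~1
  params <- subsampling_params(36, 0.08)
  sub <- s[s$test_offset == 0 & s$condition == "gaussian", , drop = FALSE]
  if (nrow(sub) > 0) {
    expect_equal(negative_log_likelihood(sub, params), 0, tolerance = 1e-4)
  }
  full <- simulate_dataset(generate_session(40, seed = 15),
                           subsampling_params(20, 4), seed = 16)
  p1 <- full[1:20, ]
  p2 <- full[21:40, ]
  pp <- subsampling_params(20, 4)
  expect_equal(negative_log_likelihood(full, pp),
               negative_log_likelihood(p1, pp) +
                 negative_log_likelihood(p2, pp),
               tolerance = 1e-8)
  empty <- full[0, ]
  expect_error(negative_log_likelihood(empty, pp), class = "ffr_error")
})

test_that("the likelihood prefers the generating parameters over distant ones", {
  set.seed(17)
  wins <- 0L
  for (i in 1:10) {
    s <- simulate_dataset(generate_session(150), subsampling_params(28, 5))
    good <- negative_log_likelihood(s, subsampling_params(28, 5))
    bad <- negative_log_likelihood(s, subsampling_params(6, 1.5))
    wins <- wins + (good < bad)
  }
  expect_gte(wins, 9)
})

test_that("maximum-likelihood fitting is self-consistent at large n", {
  s <- simulate_dataset(generate_session(5000, seed = 18),
                        subsampling_params(30, 5), seed = 19)
  f <- fit_mle(s)
  expect_s3_class(f, "ffr_fit")
  expect_lte(abs(f$params_hat$N - 30), 3)
  expect_lte(abs(f$params_hat$sigma - 5), 0.5)
  expect_equal(nrow(f$profile), 36)
  expect_true(all(is.finite(f$profile$nll)))
  # the profile is consistent with the reported optimum
  expect_equal(min(f$profile$nll), f$nll)
})

test_that("near-noiseless data recover the full sample size with small noise", {
  s <- simulate_dataset(generate_session(400, seed = 20),
                        subsampling_params(36, 0.3), seed = 21)
  f <- fit_mle(s)
  expect_equal(f$params_hat$N, 36L)
  expect_lt(f$params_hat$sigma, 1)
})

test_that("parameter recovery improves with session length", {
  short <- parameter_recovery(n_runs = 15, trials_per_run = 10, seed = 22)
  long <- parameter_recovery(n_runs = 15, trials_per_run = 300, seed = 22)
  expect_true(all(abs(c(short$r_N, short$r_sigma, short$r_cross)) <= 1))
  expect_lt(short$r_sigma, long$r_sigma)
  expect_lt(short$r_N, long$r_N)
  expect_equal(nrow(long$runs), 15)
  # reproducibility from the seed
  again <- parameter_recovery(n_runs = 15, trials_per_run = 10, seed = 22)
  expect_identical(short$runs, again$runs)
  expect_error(parameter_recovery(n_runs = 1), class = "ffr_domain_error")
})
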