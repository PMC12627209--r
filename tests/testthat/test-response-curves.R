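test_that("true presented counts per signed offset", {
  expect_equal(true_count(distribution_spec("gaussian"), 0), 8L)
  expect_equal(true_count(distribution_spec("gaussian"), 12), 1L)
  expect_equal(true_count(distribution_spec("uniform"), 15), 0L)
  expect_equal(true_count(distribution_spec("bimodal"), 9), 6L)
  expect_error(true_count(distribution_spec("uniform"), 5),
               class = "ffr_domain_error")
  expect_error(true_count(distribution_spec("uniform"), 24),
               class = "ffr_domain_error")
})

test_that("folding averages the two signed offsets and keeps offset 0 separate", {
  s <- data.frame(
    observer_id = "o1", trial_index = 1:16,
    condition = "uniform",
    mean_hue = 0L,
    test_offset = c(3, -3, rep(c(0, 6, -6, 9, -9, 12, 15, -15, 18, -18, 21,
                                 -21, -12, 0), 1)),
    response = c(5L, 3L, rep(2L, 14))
  )
  class(s) <- c("ffr_session", "data.frame")
  folded <- fold_and_average(s)
  expect_s3_class(folded, "ffr_folded")
  expect_equal(folded$mean_response[folded$abs_offset == 3], 4) # (5+3)/2
  expect_equal(folded$n_trials[folded$abs_offset == 3], 2)
  expect_equal(folded$n_trials[folded$abs_offset == 0], 2)
  expect_equal(nrow(folded), 8) # one observer x condition
})

test_that("a zero-noise veridical observer reproduces the ground-truth curves", {
  sess <- make_experiment(1, 300, veridical_params(0), seed = 5)
  folded <- fold_and_average(sess)
  for (i in seq_len(nrow(folded))) {
    expect_equal(
      folded$mean_response[i],
      true_count(distribution_spec(folded$condition[i]), folded$abs_offset[i])
    )
  }
})

test_that("empty folded cells are reported explicitly", {
  s <- generate_session(40, seed = 6)
  s$response <- 1L
  s <- s[abs(s$test_offset) != 9, ]
  err <- tryCatch(fold_and_average(s), error = identity)
  expect_s3_class(err, "ffr_empty_cell_error")
  expect_match(conditionMessage(err), "offset 9")
})

test_that("aggregation across observers gives means, SEMs, and order invariance", {
  f <- function(obs, resp) {
    data.frame(observer_id = obs, condition = "gaussian",
               abs_offset = folded <- c(0, 3, 6, 9, 12, 15, 18, 21),
               mean_response = resp, n_trials = 5L)
  }
  two <- rbind(f("a", c(4, rep(2, 7))), f("b", c(6, rep(2, 7))))
  agg <- aggregate_curves(two)
  expect_equal(agg$mean_response[agg$abs_offset == 0], 5)
  expect_equal(agg$sem[agg$abs_offset == 0], 1) # sd = sqrt(2), /sqrt(2)
  expect_equal(agg$sem[agg$abs_offset == 6], 0)
  # identical curves -> SEM 0 everywhere
  ten <- do.call(rbind, lapply(letters[1:10], function(o) f(o, rep(3, 8))))
  expect_true(all(aggregate_curves(ten)$sem == 0))
  # permutation invariance in observer order
  perm <- two[sample(nrow(two)), ]
  expect_equal(aggregate_curves(perm), agg)
  expect_error(aggregate_curves(f("a", rep(1, 8))), class = "ffr_domain_error")
})

test_that("mean-vs-offset paired tests match the textbook oracle and flag degeneracy", {
  diffs <- c(2, 0, 1, 1, 2, 0, 1, 1, 2, 0)
  base <- 3
  folded <- do.call(rbind, lapply(1:10, function(o) {
    data.frame(observer_id = sprintf("o%02d", o), condition = "gaussian",
               abs_offset = c(0, 3, 6, 9, 12, 15, 18, 21),
               mean_response = c(base + diffs[o], base, base - 1, base - 1,
                                 base - 2, base - 2, base - 2, base + diffs[o]),
               n_trials = 10L)
  }))
  res <- compare_mean_vs_offsets(folded)
  or <- t_oracle(diffs)
  row3 <- res[res$abs_offset == 3, ]
  expect_equal(row3$t, or$t, tolerance = 1e-12) # ~3.873
  expect_equal(row3$cohens_d, or$d, tolerance = 1e-12) # ~1.225
  expect_equal(row3$df, 9)
  expect_equal(row3$p, 2 * pt(-abs(or$t), 9), tolerance = 1e-12)
  # offset 21 differences are identically zero -> flagged, not an error
  row21 <- res[res$abs_offset == 21, ]
  expect_true(is.na(row21$t))
  expect_match(row21$note, "zero-variance")
  # d and t share a sign; p decreases with |t| at fixed df
  rows <- res[!is.na(res$t) & res$t != 0, ]
  expect_true(all(sign(rows$t) == sign(rows$cohens_d)))
  o <- order(abs(rows$t))
  expect_true(all(diff(rows$p[o]) <= 1e-15))
})
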