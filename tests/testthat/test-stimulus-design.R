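test_that("signed circular offsets take the shorter arc and break ties positively", {
  w <- color_wheel()
  expect_equal(signed_offset(46, 10, w), 12)
  expect_equal(signed_offset(5, 5, w), 0)
  expect_equal(signed_offset(0, 24, w), 24) # antipodal tie -> positive

  # enumeration oracle: shortest displacement among both directions
  set.seed(1)
  a <- sample(0:47, 200, replace = TRUE)
  b <- sample(0:47, 200, replace = TRUE)
  raw <- (b - a) %% 48
  oracle <- ifelse(raw > 24, raw - 48, raw)
  expect_equal(signed_offset(a, b, w), oracle)

  # antisymmetry except at the antipodal tie
  d_ab <- signed_offset(a, b, w)
  d_ba <- signed_offset(b, a, w)
  tie <- abs(d_ab) == 24
  expect_equal(d_ab[!tie], -d_ba[!tie])
  expect_true(all(d_ab > -24 & d_ab <= 24))

  expect_error(signed_offset(48, 0, w), class = "ffr_domain_error")
  expect_error(signed_offset(-1, 0, w), class = "ffr_domain_error")
})

test_that("the three distribution specs match the fixed exemplar counts", {
  g <- distribution_spec("gaussian")
  u <- distribution_spec("uniform")
  b <- distribution_spec("bimodal")
  for (spec in list(g, u, b)) {
    expect_equal(sum(spec$counts), 36)
    # symmetric counts and offsets within +/-12 JND in steps of 3
    expect_equal(unname(spec$counts[as.character(spec$offsets)]),
                 unname(spec$counts[as.character(-spec$offsets)]))
    expect_true(all(spec$offsets %in% c(0, -3, 3, -6, 6, -9, 9, -12, 12)))
    # matched mean offset of zero
    expect_equal(sum(spec$offsets * spec$counts), 0)
  }
  expect_equal(unname(g$counts[c("0", "3", "6", "9", "12")]), c(8, 7, 4, 2, 1))
  expect_true(all(u$counts == 4))
  expect_equal(unname(b$counts[c("0", "3", "6", "9", "12")]), c(0, 2, 3, 6, 7))
})

test_that("displays realize the exemplar counts exactly around any mean hue", {
  w <- color_wheel()
  for (cond in ffr_conditions()) {
    spec <- distribution_spec(cond)
    for (mean_hue in c(0, 17, 40, 47)) {
      hues <- build_display(spec, mean_hue, w)
      expect_length(hues, 36)
      offs <- table(signed_offset(mean_hue, hues, w))
      expect_equal(offs[as.character(spec$offsets[spec$counts > 0])],
                   table(rep(spec$offsets, spec$counts))[
                     as.character(spec$offsets[spec$counts > 0])],
                   ignore_attr = TRUE)
    }
  }
  # bimodal wraps around the wheel: 7 disks at (40 + 12) mod 48 = 4, none at 40
  hues <- build_display(distribution_spec("bimodal"), 40, w)
  expect_equal(sum(hues == 4), 7)
  expect_equal(sum(hues == 40), 0)
})

test_that("test offsets are drawn from the 15 signed values, reproducibly and uniformly", {
  expect_setequal(test_offsets(), c(0, 3, 6, 9, 12, 15, 18, 21,
                                    -3, -6, -9, -12, -15, -18, -21))
  set.seed(7)
  draws <- sample_test_offset(15000)
  expect_setequal(unique(draws), test_offsets())
  # chi-square goodness of fit against the uniform scheme
  obs <- table(factor(draws, levels = test_offsets()))
  chisq <- sum((obs - 1000)^2 / 1000)
  expect_lt(chisq, qchisq(0.999, df = 14))
  # seed determinism
  set.seed(7)
  expect_identical(sample_test_offset(15000), draws)
  expect_error(sample_test_offset(5, prob = rep(-1, 15)),
               class = "ffr_domain_error")
})

test_that("generated sessions are valid, balanced across conditions, and seed-reproducible", {
  s <- generate_session(3, seed = 1)
  expect_s3_class(s, "ffr_session")
  expect_equal(nrow(s), 3)
  for (i in 1:3) {
    hues <- build_display(distribution_spec(s$condition[i]), s$mean_hue[i])
    expect_length(hues, 36)
  }
  # balanced blocks of 3: proportions exact to within one block over 3000
  big <- generate_session(3000, seed = 2)
  expect_true(all(abs(table(big$condition) - 1000) <= 1))
  expect_true(all(big$test_offset %in% test_offsets()))
  expect_true(all(big$mean_hue %in% 0:47))
  # determinism
  expect_identical(generate_session(50, seed = 9),
                   generate_session(50, seed = 9))
  expect_error(generate_session(0), class = "ffr_domain_error")
  expect_error(generate_session(-3), class = "ffr_domain_error")
})

test_that("session CSV round-trips and schema violations name the rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- generate_session(30, seed = 3)
  write_session(s, path)
  r <- read_session(path)
  expect_equal(as.data.frame(r), as.data.frame(s), ignore_attr = TRUE)

  bad <- as.data.frame(s)
  bad$condition[4] <- "triangular"
  bad$mean_hue[7] <- 90
  write.csv(bad, path, row.names = FALSE, na = "")
  err <- tryCatch(read_session(path), error = identity)
  expect_s3_class(err, "ffr_schema_error")
  expect_match(conditionMessage(err), "condition.*rows 4")
  expect_match(conditionMessage(err), "mean_hue.*\\(rows 7\\)")
})
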