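# Independent oracles used across test files.

# Brute-force match-count distribution: enumerate every size-N subset and
# convolve the Bernoulli match indicators within it.
enum_match_pmf <- function(p, N) {
  n <- length(p)
  out <- numeric(N + 1)
  subs <- utils::combn(n, N)
  for (j in seq_len(ncol(subs))) {
    d <- 1
    for (i in subs[, j]) {
      d <- convolve(d, rev(c(1 - p[i], p[i])), type = "open")
    }
    out <- out + d
  }
  out / ncol(subs)
}

# Poisson-binomial PMF by direct convolution (full-set case).
poisson_binomial_pmf <- function(p) {
  d <- 1
  for (pi in p) d <- convolve(d, rev(c(1 - pi, pi)), type = "open")
  pmax(d, 0)
}

# RSS-profile grid search for the break point.
grid_search_psi <- function(x, y, grid) {
  rss <- vapply(grid, function(ps) {
    sum(.lm.fit(cbind(1, x, pmax(x - ps, 0)), y)$residuals^2)
  }, numeric(1))
  grid[which.min(rss)]
}

# Textbook one-sample t statistic and Cohen's d.
t_oracle <- function(v) {
  n <- length(v)
  list(t = mean(v) / (sd(v) / sqrt(n)), d = mean(v) / sd(v), df = n - 1)
}

# Multi-observer simulated experiment.
make_experiment <- function(n_observers, n_trials, model, seed) {
  sessions <- ffreport:::with_seed(seed, {
    lapply(seq_len(n_observers), function(o) {
      s <- generate_session(n_trials, sprintf("obs%02d", o))
      simulate_dataset(s, model)
    })
  })
  out <- do.call(rbind, lapply(sessions, as.data.frame))
  attr(out, "wheel") <- color_wheel()
  class(out) <- c("ffr_session", "data.frame")
  out
}
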