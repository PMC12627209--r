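#' Parameter-recovery study for the sub-sampling model
#'
#' Draws random (N, sigma) pairs, simulates one full session from each with
#' the generative sub-sampling observer, refits by maximum likelihood, and
#' correlates true with fitted values. Good recovery (r near 1 for both
#' parameters, near-zero correlation between the fitted parameters)
#' establishes that the fitting procedure is identifiable and unbiased.
#'
#' @param n_runs Number of simulated parameter pairs (default 400).
#' @param trials_per_run Trials per simulated session (default 450, the
#'   session default).
#' @param N_range Integer range to draw `N` from uniformly (default 1..36).
#' @param sigma_range Range to draw `sigma` from uniformly, in JND
#'   (default 0.5..10, covering typical fitted values).
#' @param seed Optional RNG seed; the whole study is reproducible from it.
#' @param verbose If `TRUE`, log progress to stderr every 25 runs.
#' @param wheel A [color_wheel()].
#' @return An object of class `ffr_recovery`: `runs` (data frame with
#'   columns `run`, `true_N`, `true_sigma`, `fit_N`, `fit_sigma`, `nll`),
#'   `r_N`, `r_sigma` (Pearson correlations true vs fitted), `r_cross`
#'   (correlation between fitted N and fitted sigma), and `n_runs`.
#' @export
parameter_recovery <- function(n_runs = 400L, trials_per_run = 450L,
                               N_range = c(1L, 36L), sigma_range = c(0.5, 10),
                               seed = NULL, verbose = FALSE,
                               wheel = color_wheel()) {
  if (length(n_runs) != 1L || !is_whole(n_runs) || n_runs < 2) {
    ffr_stop("`n_runs` must be an integer >= 2", "ffr_domain_error")
  }
  n_runs <- as.integer(n_runs)
  with_seed(seed, {
    true_N <- sample(seq.int(N_range[1], N_range[2]), n_runs, replace = TRUE)
    true_sigma <- runif(n_runs, sigma_range[1], sigma_range[2])
    runs <- data.frame(run = seq_len(n_runs), true_N = true_N,
                       true_sigma = true_sigma, fit_N = NA_integer_,
                       fit_sigma = NA_real_, nll = NA_real_)
    for (r in seq_len(n_runs)) {
      sess <- generate_session(trials_per_run,
                               observer_id = sprintf("run%04d", r),
                               wheel = wheel)
      sess <- simulate_dataset(sess, subsampling_params(true_N[r],
                                                        true_sigma[r]),
                               wheel = wheel)
      fit <- fit_mle(sess, wheel = wheel)
      runs$fit_N[r] <- fit$params_hat$N
      runs$fit_sigma[r] <- fit$params_hat$sigma
      runs$nll[r] <- fit$nll
      if (verbose && r %% 25L == 0L) {
        message(sprintf("parameter recovery: %d / %d runs", r, n_runs))
      }
    }
    out <- list(
      runs = runs,
      r_N = cor(runs$true_N, runs$fit_N),
      r_sigma = cor(runs$true_sigma, runs$fit_sigma),
      r_cross = cor(runs$fit_N, runs$fit_sigma),
      n_runs = n_runs,
      trials_per_run = as.integer(trials_per_run)
    )
    class(out) <- "ffr_recovery"
    out
  })
}

#' @export
print.ffr_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d runs x %d trials\n",
              x$n_runs, x$trials_per_run))
  cat(sprintf("  r(true N, fitted N)         = %.4f\n", x$r_N))
  cat(sprintf("  r(true sigma, fitted sigma) = %.4f\n", x$r_sigma))
  cat(sprintf("  r(fitted N, fitted sigma)   = %.4f\n", x$r_cross))
  invisible(x)
}
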