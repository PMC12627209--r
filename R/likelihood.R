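# Exact likelihood of the sub-sampling observer.
#
# For a trial, disk i matches the probed hue with probability
# p_i = match_probability(d_i, sigma) where d_i is the disk's offset from
# the probe. The number of matches in a uniformly random size-N subset has
# an exact distribution computed by dynamic programming (hypergeometric
# weighting of selections, Bernoulli matches); the response PMF mixes that
# distribution over the uniform integer multiplier and clips to the slider.
# Trials with the same condition and test offset share the PMF, so a
# session reduces to at most 3 x 15 = 45 profiles.

#' Exact match-count distribution for a random subset
#'
#' Low-level combinatorial kernel: the distribution of the number of
#' matching disks in a uniformly random size-`N` subset of `length(p)`
#' disks, where disk `i` matches independently with probability `p[i]`.
#' With `N = length(p)` this is the Poisson-binomial distribution of `p`.
#'
#' @param p Vector of per-disk match probabilities in `[0, 1]`.
#' @param N Subset size; integer in `[1, length(p)]`.
#' @return Numeric vector of probabilities for 0 to `N` matches (sums to 1).
#' @export
subset_match_pmf <- function(p, N) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    ffr_stop("`p` must be probabilities in [0, 1]", "ffr_domain_error")
  }
  if (length(N) != 1L || !is_whole(N) || N < 1 || N > length(p)) {
    ffr_stop("`N` must be an integer in [1, length(p)]", "ffr_domain_error")
  }
  out <- cpp_match_count_dist(as.numeric(p), as.integer(N))
  names(out) <- 0:N
  out
}

#' Match-count distribution for a trial
#'
#' @param trial An [make_trial()] object.
#' @param params A [subsampling_params()] object.
#' @return Named numeric vector: probability of 0 to `N` matches.
#' @export
match_count_distribution <- function(trial, params) {
  stopifnot(inherits(trial, "ffr_trial"), inherits(params, "subsampling_params"))
  d <- signed_offset(trial$test_hue, trial$disk_hues, trial$wheel)
  p <- match_probability(d, params$sigma, trial$wheel)
  subset_match_pmf(p, params$N)
}

multiplier_mix_pmf <- function(match_pmf, M) {
  out <- cpp_multiplier_mix(as.numeric(match_pmf), as.integer(M))
  names(out) <- 0:8
  out
}

#' Predicted response distribution of the sub-sampling observer
#'
#' Mixes the exact match-count distribution over the uniform integer
#' multiplier `m` in `1:floor(36 / N)`, mapping each product `k * m`
#' through clipping to the slider range `[0, 8]`.
#'
#' @inheritParams match_count_distribution
#' @return Named numeric vector of probabilities for responses 0 to 8
#'   (sums to 1).
#' @export
response_pmf <- function(trial, params) {
  md <- match_count_distribution(trial, params)
  multiplier_mix_pmf(md, length(trial$disk_hues) %/% params$N)
}

# Precompute per-session structures shared by every (N, sigma) evaluation:
# distinct disk-vs-probe offsets, the 36 x G index matrix mapping disks to
# those offsets per profile, and the 9 x G response count matrix.
session_profiles <- function(session, wheel = attr(session, "wheel") %||%
                               color_wheel()) {
  validate_session(session, wheel = wheel, require_responses = TRUE)
  if (nrow(session) == 0L) {
    ffr_stop("session has no trials", "ffr_domain_error")
  }
  key <- paste(session$condition, session$test_offset)
  groups <- unique(data.frame(condition = session$condition,
                              test_offset = session$test_offset,
                              key = key, stringsAsFactors = FALSE))
  dlist <- lapply(seq_len(nrow(groups)), function(g) {
    spec <- distribution_spec(groups$condition[g])
    disk_off <- rep(spec$offsets, spec$counts) # offsets from the mean, JND
    d <- disk_off - groups$test_offset[g]      # offsets from the probe
    period <- wheel$n_hues * wheel$jnd_per_step
    d - period * round(d / period)
  })
  dvals <- sort(unique(unlist(dlist)))
  didx <- vapply(dlist, function(d) match(d, dvals), integer(36L))
  counts <- vapply(seq_len(nrow(groups)), function(g) {
    r <- session$response[key == groups$key[g]]
    tabulate(r + 1L, nbins = 9L)
  }, integer(9L))
  list(dvals = dvals, didx = didx, counts = matrix(counts, nrow = 9L),
       n_trials = nrow(session), wheel = wheel)
}

nll_from_profiles <- function(profiles, N, sigma, eps = 1e-12) {
  p <- match_probability(profiles$dvals, sigma, profiles$wheel)
  cpp_session_nll(p, profiles$didx, profiles$counts, as.integer(N),
                  nrow(profiles$didx) %/% as.integer(N), eps)
}

#' Negative log-likelihood of the sub-sampling model for a session
#'
#' `-sum(log(pmf[response] + eps))` over trials, with a small floor `eps`
#' inside the logarithm guarding responses the model deems (numerically)
#' impossible, e.g. lapses in human data.
#'
#' @param session An `ffr_session` with all responses filled.
#' @param params A [subsampling_params()] object.
#' @param eps Likelihood floor (default `1e-12`).
#' @param wheel A [color_wheel()]; defaults to the session's wheel.
#' @return A single number.
#' @export
negative_log_likelihood <- function(session, params, eps = 1e-12,
                                    wheel = attr(session, "wheel") %||%
                                      color_wheel()) {
  stopifnot(inherits(params, "subsampling_params"))
  profiles <- session_profiles(session, wheel)
  nll_from_profiles(profiles, params$N, params$sigma, eps)
}

#' Maximum-likelihood fit of the sub-sampling model
#'
#' Exhaustive search over the sample size `N` in `1:36`; for each `N` a
#' bounded one-dimensional minimization of the exact negative
#' log-likelihood over `sigma` (default bounds `[0.05, 20]` JND, tolerance
#' `1e-3`). Ties across `N` are broken toward the smaller `N`. The fit is
#' deterministic given the data.
#'
#' @param session An `ffr_session` with all responses filled.
#' @param sigma_bounds Lower and upper bounds for the noise search, in JND.
#' @param sigma_tol Tolerance of the one-dimensional search.
#' @param eps Likelihood floor, see [negative_log_likelihood()].
#' @param wheel A [color_wheel()].
#' @return An object of class `ffr_fit`: `params_hat`
#'   (a [subsampling_params()]), `nll` at the optimum, and `profile`
#'   (a data frame with the best `sigma` and NLL for every candidate `N`).
#' @export
fit_mle <- function(session, sigma_bounds = c(0.05, 20), sigma_tol = 1e-3,
                    eps = 1e-12,
                    wheel = attr(session, "wheel") %||% color_wheel()) {
  profiles <- session_profiles(session, wheel)
  Ns <- 1:36
  prof <- data.frame(N = Ns, sigma = NA_real_, nll = NA_real_)
  for (i in seq_along(Ns)) {
    o <- tryCatch(
      optimize(function(s) nll_from_profiles(profiles, Ns[i], s, eps),
               interval = sigma_bounds, tol = sigma_tol),
      error = function(e) NULL
    )
    if (!is.null(o)) {
      prof$sigma[i] <- o$minimum
      prof$nll[i] <- o$objective
    }
  }
  if (all(is.na(prof$nll))) {
    ffr_stop("sigma optimization failed for every candidate N",
             "ffr_nonconvergence")
  }
  ok <- which(is.finite(prof$nll))
  best <- ok[order(prof$nll[ok], prof$N[ok])][1]
  out <- list(
    params_hat = subsampling_params(prof$N[best], prof$sigma[best]),
    nll = prof$nll[best],
    profile = prof,
    n_trials = profiles$n_trials
  )
  class(out) <- "ffr_fit"
  out
}

#' @export
print.ffr_fit <- function(x, ...) {
  cat("Sub-sampling model maximum-likelihood fit\n")
  cat(sprintf("  N = %d, sigma = %.3f JND  (NLL = %.3f over %d trials)\n",
              x$params_hat$N, x$params_hat$sigma, x$nll, x$n_trials))
  invisible(x)
}
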