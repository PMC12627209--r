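#' Sub-sampling observer parameters
#'
#' The sub-sampling observer perceives each of the 36 disks with independent
#' Gaussian hue noise (SD `sigma`, in JND), selects `N` disks uniformly
#' without replacement, counts how many of those match the probed hue, and
#' extrapolates by a uniform random integer multiplier in
#' `1:floor(36 / N)`.
#'
#' @param N Sample size; integer in `[1, 36]`.
#' @param sigma Perceptual noise SD in JND; positive.
#' @return An object of class `subsampling_params`.
#' @export
subsampling_params <- function(N, sigma) {
  if (length(N) != 1L || !is_whole(N) || N < 1 || N > 36) {
    ffr_stop("`N` must be an integer in [1, 36]", "ffr_domain_error")
  }
  if (length(sigma) != 1L || !is.numeric(sigma) || !is.finite(sigma) ||
      sigma <= 0) {
    ffr_stop("`sigma` must be a positive number", "ffr_domain_error")
  }
  structure(list(N = as.integer(N), sigma = as.numeric(sigma)),
            class = "subsampling_params")
}

#' @export
print.subsampling_params <- function(x, ...) {
  cat(sprintf("<subsampling_params: N = %d, sigma = %.3g JND>\n", x$N, x$sigma))
  invisible(x)
}

#' Veridical-noisy observer parameters
#'
#' A test-fixture observer that reports the true presented count plus
#' additive Gaussian response noise (rounded and clipped to the slider).
#' With `response_noise_sd = 0` it reproduces the ground-truth counts
#' exactly, which makes it the reference input for the analysis stages.
#'
#' @param response_noise_sd SD of the additive response noise in slider
#'   units; non-negative.
#' @return An object of class `veridical_params`.
#' @export
veridical_params <- function(response_noise_sd = 0) {
  if (length(response_noise_sd) != 1L || !is.numeric(response_noise_sd) ||
      !is.finite(response_noise_sd) || response_noise_sd < 0) {
    ffr_stop("`response_noise_sd` must be a non-negative number",
             "ffr_domain_error")
  }
  structure(list(response_noise_sd = as.numeric(response_noise_sd)),
            class = "veridical_params")
}

#' Probability that a noised disk matches the probed hue
#'
#' A disk at signed offset `d` JND from the probed hue is perceived at its
#' true hue plus Gaussian noise (SD `sigma`); it counts as a match when the
#' noised value rounds to the probed hue on the wheel, i.e. falls within
#' half a wheel step. Wrap-around on the circle is accounted for, so the
#' per-hue match probabilities over all `n_hues` hues sum to exactly 1.
#'
#' @param d Signed offset(s) of the disk from the probed hue, in JND.
#' @param sigma Perceptual noise SD in JND; positive.
#' @param wheel A [color_wheel()].
#' @return Numeric vector of match probabilities in (0, 1).
#' @examples
#' match_probability(0, 5) # ~0.0797
#' @export
match_probability <- function(d, sigma, wheel = color_wheel()) {
  if (length(sigma) != 1L || !is.numeric(sigma) || !is.finite(sigma) ||
      sigma <= 0) {
    ffr_stop("`sigma` must be a positive number", "ffr_domain_error")
  }
  s <- wheel$jnd_per_step
  period <- wheel$n_hues * s
  d <- d - period * round(d / period) # canonical representative
  wraps <- ceiling(6 * sigma / period) + 1L
  shift <- (-wraps:wraps) * period
  upper <- outer(-d + s / 2, shift, "+") / sigma
  lower <- outer(-d - s / 2, shift, "+") / sigma
  p <- rowSums(pnorm(upper) - pnorm(lower))
  pmin(pmax(p, 0), 1)
}

#' Construct a single FFR trial
#'
#' @param condition Distribution condition name.
#' @param mean_hue Integer hue index of the distribution mean.
#' @param test_offset Signed probe offset in JND; one of [test_offsets()].
#' @param wheel A [color_wheel()].
#' @return An object of class `ffr_trial`: condition, mean hue, the 36 disk
#'   hues, the signed test offset and the probed hue index.
#' @export
make_trial <- function(condition, mean_hue, test_offset,
                       wheel = color_wheel()) {
  spec <- distribution_spec(condition)
  mean_hue <- assert_hue(mean_hue, wheel, "mean_hue")
  if (!(test_offset %in% test_offsets())) {
    ffr_stop("`test_offset` must be one of the 15 tested values",
             "ffr_domain_error")
  }
  steps <- test_offset / wheel$jnd_per_step
  structure(
    list(condition = spec$name, mean_hue = mean_hue,
         disk_hues = build_display(spec, mean_hue, wheel),
         test_offset = test_offset,
         test_hue = as.integer((mean_hue + round(steps)) %% wheel$n_hues),
         wheel = wheel),
    class = "ffr_trial"
  )
}

#' Simulate sub-sampling observer responses to one trial
#'
#' Generative model: add independent Gaussian hue noise (SD `sigma` JND) to
#' every disk, round each noised hue to the wheel (circularly), select `N`
#' of the 36 disks uniformly without replacement, count matches to the
#' probed hue among them, multiply by a uniform random integer in
#' `1:floor(36 / N)` (identically 1 for N >= 19), and clip to the slider
#' range `[0, 8]`.
#'
#' @param trial An [make_trial()] object.
#' @param params A [subsampling_params()] object.
#' @param n Number of independent simulated responses.
#' @param use_multiplier If `FALSE`, skip the extrapolation multiplier and
#'   return the clipped match count itself (used for checks against the
#'   exact match-count distribution).
#' @return Integer vector of `n` responses in `[0, 8]`.
#' @export
simulate_subsampling_response <- function(trial, params, n = 1L,
                                          use_multiplier = TRUE) {
  stopifnot(inherits(trial, "ffr_trial"), inherits(params, "subsampling_params"))
  wheel <- trial$wheel
  n <- as.integer(n)
  ndisk <- length(trial$disk_hues)
  noise_steps <- matrix(
    rnorm(ndisk * n, mean = 0, sd = params$sigma / wheel$jnd_per_step),
    nrow = ndisk
  )
  noised <- round(trial$disk_hues + noise_steps) %% wheel$n_hues
  match <- noised == trial$test_hue
  N <- params$N
  if (N == ndisk) {
    k <- colSums(match)
  } else {
    k <- vapply(seq_len(n),
                function(i) sum(match[sample.int(ndisk, N), i]),
                integer(1))
  }
  M <- ndisk %/% N
  m <- if (use_multiplier && M > 1L) sample.int(M, n, replace = TRUE) else 1L
  as.integer(pmin(k * m, 8L))
}

#' Simulate veridical-noisy observer responses to one trial
#'
#' Reports the true count of disks at the probed hue plus additive Gaussian
#' response noise, rounded and clipped to `[0, 8]`.
#'
#' @inheritParams simulate_subsampling_response
#' @param params A [veridical_params()] object.
#' @return Integer vector of `n` responses in `[0, 8]`.
#' @export
simulate_veridical_response <- function(trial, params, n = 1L) {
  stopifnot(inherits(trial, "ffr_trial"), inherits(params, "veridical_params"))
  spec <- distribution_spec(trial$condition)
  k0 <- true_count(spec, abs(trial$test_offset))
  noise <- if (params$response_noise_sd > 0) {
    rnorm(n, 0, params$response_noise_sd)
  } else 0
  as.integer(pmin(pmax(round(k0 + noise), 0L), 8L))
}

#' Fill a session with simulated responses
#'
#' @param session An `ffr_session` with empty responses.
#' @param model A [subsampling_params()] or [veridical_params()] object.
#' @param seed Optional RNG seed; identical seeds give identical responses.
#' @param wheel A [color_wheel()]; defaults to the session's wheel.
#' @return The session with its `response` column filled.
#' @export
simulate_dataset <- function(session, model, seed = NULL,
                             wheel = attr(session, "wheel") %||% color_wheel()) {
  validate_session(session, wheel = wheel)
  if (any(!is.na(session$response))) {
    ffr_stop("session already has responses; refusing to overwrite",
             "ffr_state_error")
  }
  simulate_one <- if (inherits(model, "subsampling_params")) {
    function(tr) simulate_subsampling_response(tr, model)
  } else if (inherits(model, "veridical_params")) {
    function(tr) simulate_veridical_response(tr, model)
  } else {
    ffr_stop("`model` must be subsampling_params or veridical_params",
             "ffr_domain_error")
  }
  with_seed(seed, {
    session$response <- vapply(seq_len(nrow(session)), function(i) {
      tr <- make_trial(session$condition[i], session$mean_hue[i],
                       session$test_offset[i], wheel)
      simulate_one(tr)
    }, integer(1))
    session
  })
}
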