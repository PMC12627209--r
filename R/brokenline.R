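# Two-segment (broken-line) regression:
#   y = beta0 + beta1 * x + beta2 * (x - psi)_+ + error
# with the break point psi estimated by Muggeo's iterative linearization:
# given a working psi, refit including the "gap" covariate
# V = -I(x > psi); the update is psi <- psi + gamma_hat / beta2_hat, with
# step halving so the residual sum of squares never increases.

ols_fit <- function(X, y) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  coef <- drop(backsolve(R, forwardsolve(t(R), crossprod(X, y))))
  res <- drop(y - X %*% coef)
  rss <- sum(res^2)
  dfres <- length(y) - ncol(X)
  list(coef = coef, rss = rss, df = dfres,
       vcov = chol2inv(R) * rss / dfres)
}

rss_at_psi <- function(x, y, psi) {
  f <- ols_fit(cbind(1, x, pmax(x - psi, 0)), y)
  if (is.null(f)) Inf else f$rss
}

admissible_range <- function(x, min_side = 2L) {
  ux <- sort(unique(x))
  if (length(ux) < 2L * min_side + 1L) {
    ffr_stop(sprintf("need at least %d distinct x values", 2L * min_side + 1L),
             "ffr_domain_error")
  }
  c(ux[min_side], ux[length(ux) - min_side + 1L])
}

muggeo_iterate <- function(x, y, start, lims, max_iter, tol) {
  psi <- start
  rss_old <- Inf
  scale_tol <- 1e-10 * (sd(y) + .Machine$double.eps) / diff(range(x))
  for (it in seq_len(max_iter)) {
    U <- pmax(x - psi, 0)
    V <- -as.numeric(x > psi)
    f <- ols_fit(cbind(1, x, U, V), y)
    if (is.null(f)) return(list(ok = FALSE, psi = psi, iter = it,
                                reason = "singular design"))
    beta2 <- f$coef[3]
    gam <- f$coef[4]
    if (!is.finite(beta2) || abs(beta2) < scale_tol) {
      return(list(ok = FALSE, psi = psi, iter = it,
                  reason = "slope change indistinguishable from zero",
                  unidentified = TRUE))
    }
    step <- gam / beta2
    psi_new <- NA_real_
    rss_new <- Inf
    for (h in 0:12) {
      cand <- psi + step / 2^h
      cand <- min(max(cand, lims[1] + 1e-8), lims[2] - 1e-8)
      r <- rss_at_psi(x, y, cand)
      if (r <= rss_old + 1e-12 * (1 + rss_old)) {
        psi_new <- cand
        rss_new <- r
        break
      }
    }
    if (!is.finite(psi_new)) {
      # The RSS profile is piecewise smooth with kinks at the data x values;
      # when psi sits at a kink minimum no step along the Muggeo direction
      # can decrease the RSS. Treat a stalled halving as convergence there.
      if (is.finite(rss_old)) {
        return(list(ok = TRUE, psi = psi, iter = it, rss = rss_old))
      }
      return(list(ok = FALSE, psi = psi, iter = it,
                  reason = "no RSS-decreasing step"))
    }
    done <- abs(psi_new - psi) < tol
    psi <- psi_new
    rss_old <- rss_new
    if (done) return(list(ok = TRUE, psi = psi, iter = it, rss = rss_old))
  }
  list(ok = FALSE, psi = psi, iter = max_iter, reason = "max iterations")
}

#' Fit a two-segment broken-line regression
#'
#' Estimates `y = beta0 + beta1*x + beta2*(x - psi)_+` with the break point
#' `psi` found by Muggeo's iterative linearization (with step halving so the
#' RSS is monotone). Slopes are reported as `b1 = beta1` (before the break)
#' and `b2 = beta1 + beta2` (after). 95% confidence intervals use the
#' delta method: `SE(psi) = SE(gamma) / |beta2|` from the final working
#' model, and Wald intervals for the slopes.
#'
#' Starts are the midpoint of the x range, then the 25% and 75% quantiles
#' of the distinct x values if an earlier start fails. Exactly linear data
#' (no detectable slope change) raise an `ffr_unidentified_break` error;
#' non-convergence raises `ffr_nonconvergence` carrying the last iterate.
#'
#' @param x Predictor (here: absolute tested offset in JND).
#' @param y Response (per-trial slider responses, or per-offset means).
#' @param psi_init Optional starting break point(s).
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   break-point update.
#' @param level Confidence level for the intervals.
#' @param davies_k Number of candidate break points for the Davies test.
#' @param davies If `TRUE` (default) compute the Davies p-value for the
#'   existence of a break.
#' @return An object of class `broken_line_fit`: `psi`, `ci_psi`,
#'   `intercept`, `b1`, `b2`, `ci_b1`, `ci_b2`, `davies_p`, plus standard
#'   errors, RSS, iteration count and sample size.
#' @examples
#' x <- rep(seq(0, 21, 3), each = 5)
#' y <- 4 - 0.25 * pmax(x - 12, 0) + rnorm(length(x), 0, 0.1)
#' fit_broken_line(x, y)
#' @export
fit_broken_line <- function(x, y, psi_init = NULL, max_iter = 50L,
                            tol = 1e-7, level = 0.95, davies_k = 10L,
                            davies = TRUE) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  lims <- admissible_range(x)
  starts <- psi_init %||% {
    ux <- sort(unique(x))
    c(mean(range(x)),
      unname(stats::quantile(ux, 0.25)), unname(stats::quantile(ux, 0.75)))
  }
  starts <- pmin(pmax(starts, lims[1] + 1e-6), lims[2] - 1e-6)
  last <- NULL
  res <- NULL
  for (s in starts) {
    r <- muggeo_iterate(x, y, s, lims, max_iter, tol)
    if (r$ok) {
      # keep the best converged solution across starts (the RSS profile can
      # have several local minima between kinks)
      if (is.null(res) || r$rss < res$rss) res <- r
    } else if (isTRUE(r$unidentified) && is.null(res)) {
      ffr_stop("break point unidentified: data show no slope change",
               "ffr_unidentified_break", last_iterate = r)
    } else {
      last <- r
    }
  }
  if (is.null(res)) {
    ffr_stop(sprintf("broken-line fit did not converge (%s)", last$reason),
             "ffr_nonconvergence", last_iterate = last)
  }
  psi <- res$psi
  U <- pmax(x - psi, 0)
  V <- -as.numeric(x > psi)
  f4 <- ols_fit(cbind(1, x, U, V), y)
  f3 <- ols_fit(cbind(1, x, U), y)
  b0 <- f3$coef[1]; b1 <- f3$coef[2]; beta2 <- f3$coef[3]
  b2 <- b1 + beta2
  se_b1 <- sqrt(f3$vcov[2, 2])
  se_b2 <- sqrt(f3$vcov[2, 2] + f3$vcov[3, 3] + 2 * f3$vcov[2, 3])
  se_psi <- sqrt(f4$vcov[4, 4]) / abs(f4$coef[3])
  tq <- qt(1 - (1 - level) / 2, f3$df)
  tq4 <- qt(1 - (1 - level) / 2, f4$df)
  out <- list(
    psi = psi,
    ci_psi = c(psi - tq4 * se_psi, psi + tq4 * se_psi),
    intercept = b0,
    b1 = b1, b2 = b2,
    ci_b1 = c(b1 - tq * se_b1, b1 + tq * se_b1),
    ci_b2 = c(b2 - tq * se_b2, b2 + tq * se_b2),
    se_psi = se_psi, se_b1 = se_b1, se_b2 = se_b2,
    davies_p = if (davies) davies_test(x, y, k = davies_k) else NA_real_,
    rss = f3$rss, n = length(y), iter = res$iter, level = level,
    converged = TRUE
  )
  class(out) <- "broken_line_fit"
  out
}

#' @export
print.broken_line_fit <- function(x, ...) {
  cat("Two-segment broken-line fit\n")
  cat(sprintf("  break point psi = %.3f JND, %d%% CI [%.3f, %.3f]\n",
              x$psi, round(100 * x$level), x$ci_psi[1], x$ci_psi[2]))
  cat(sprintf("  slope before    = %+.4f, CI [%.4f, %.4f]\n",
              x$b1, x$ci_b1[1], x$ci_b1[2]))
  cat(sprintf("  slope after     = %+.4f, CI [%.4f, %.4f]\n",
              x$b2, x$ci_b2[1], x$ci_b2[2]))
  if (is.finite(x$davies_p)) {
    cat(sprintf("  Davies test for a break: p = %.4g\n", x$davies_p))
  }
  cat(sprintf("  n = %d, RSS = %.4g, %d iteration(s)\n", x$n, x$rss, x$iter))
  invisible(x)
}

#' Davies test for the existence of a slope change
#'
#' The break point is only identified under the alternative, so an ordinary
#' test of `beta2 = 0` at the fitted break is invalid. Following Davies
#' (1987), the slope-change t statistic is evaluated at `k` evenly spaced
#' interior candidate break points; the adjusted upper bound
#' `p <= Phi(-M) + V * exp(-M^2/2) / sqrt(8*pi)` (doubled for the two-sided
#' alternative) uses the maximum statistic `M` and the total variation `V`
#' of the statistic across candidates. The bound is conservative.
#'
#' @param x,y Data, as in [fit_broken_line()].
#' @param k Number of candidate break points (>= 2; default 10).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Upper-bound p-value, with the extremal statistic and candidate
#'   grid attached as attributes.
#' @export
davies_test <- function(x, y, k = 10L,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1L || !is_whole(k) || k < 2) {
    ffr_stop("`k` must be an integer >= 2", "ffr_domain_error")
  }
  stopifnot(length(x) == length(y))
  lims <- admissible_range(x, min_side = 1L)
  cand <- seq(lims[1], lims[2], length.out = k)
  tstat <- vapply(cand, function(ps) {
    f <- ols_fit(cbind(1, x, pmax(x - ps, 0)), y)
    if (is.null(f)) return(NA_real_)
    f$coef[3] / sqrt(f$vcov[3, 3])
  }, numeric(1))
  tstat <- tstat[is.finite(tstat)]
  if (length(tstat) < 2) {
    ffr_stop("Davies test: fewer than 2 usable candidate break points",
             "ffr_domain_error")
  }
  stat <- switch(alternative,
    two.sided = max(abs(tstat)),
    greater = max(tstat),
    less = max(-tstat)
  )
  tv <- switch(alternative,
    two.sided = sum(abs(diff(abs(tstat)))),
    greater = sum(abs(diff(tstat))),
    less = sum(abs(diff(-tstat)))
  )
  p <- pnorm(-stat) + tv * exp(-stat^2 / 2) / sqrt(8 * pi)
  if (alternative == "two.sided") p <- 2 * p
  p <- min(max(p, 0), 1)
  attr(p, "statistic") <- stat
  attr(p, "candidates") <- cand
  p
}

#' Slopes of a broken line at a fixed break point
#'
#' Ordinary least squares of `y` on `x` and `(x - psi)_+` with `psi` fixed
#' (supplied externally, typically from a fit to aggregated data). Returns
#' the slope before and after the break.
#'
#' @param x,y Data.
#' @param psi Fixed break point; must lie strictly inside the range of `x`.
#' @return Named numeric vector `c(b1, b2)`.
#' @export
slopes_at_fixed_break <- function(x, y, psi) {
  stopifnot(length(x) == length(y))
  if (length(psi) != 1L || !is.finite(psi) ||
      psi <= min(x) || psi >= max(x)) {
    ffr_stop("`psi` must lie strictly inside the range of x",
             "ffr_domain_error")
  }
  f <- ols_fit(cbind(1, x, pmax(x - psi, 0)), y)
  if (is.null(f)) ffr_stop("singular design in fixed-break fit", "ffr_error")
  c(b1 = unname(f$coef[2]), b2 = unname(f$coef[2] + f$coef[3]))
}

#' One-sample t-test of per-observer slopes against zero
#'
#' Cohen's d is `|mean| / sd` of the slopes. Zero-variance slope sets are
#' flagged (t undefined) rather than raising an error.
#'
#' @param slopes Numeric vector of per-observer slopes (length >= 2).
#' @param alternative Tail of the test; two-sided by default.
#' @return List with `t`, `df`, `p`, `cohens_d` and a `note` (non-empty when
#'   flagged).
#' @export
group_slope_test <- function(slopes,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(slopes) < 2 || !is.numeric(slopes)) {
    ffr_stop("need at least 2 slopes", "ffr_domain_error")
  }
  res <- one_sample_t(slopes, alternative)
  res$cohens_d <- abs(res$cohens_d)
  res
}
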