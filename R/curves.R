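folded_offsets <- function() c(0, 3, 6, 9, 12, 15, 18, 21)

#' Fold responses by absolute tested offset
#'
#' All three stimulus distributions are symmetric around their mean, so
#' responses at +k and -k JND are averaged together ("folding"). Offset 0
#' uses only the offset-0 trials (it is not double-counted).
#'
#' @param session An `ffr_session` with all responses filled.
#' @return Data frame of class `ffr_folded` with one row per
#'   observer x condition x absolute offset: columns `observer_id`,
#'   `condition`, `abs_offset`, `mean_response`, `n_trials`. Every folded
#'   offset (0, 3, ..., 21) must have at least one trial in every
#'   observer x condition cell; empty cells are an error listing the cells.
#' @export
fold_and_average <- function(session) {
  validate_session(session, require_responses = TRUE)
  df <- as.data.frame(session)
  df$abs_offset <- abs(df$test_offset)
  agg <- aggregate(response ~ observer_id + condition + abs_offset,
                   data = df, FUN = mean)
  ntr <- aggregate(response ~ observer_id + condition + abs_offset,
                   data = df, FUN = length)
  names(agg)[names(agg) == "response"] <- "mean_response"
  agg$n_trials <- ntr$response
  # every observer x condition pair present in the data must cover the grid
  cells <- unique(df[, c("observer_id", "condition")])
  full <- merge(cells, data.frame(abs_offset = folded_offsets()))
  have <- paste(agg$observer_id, agg$condition, agg$abs_offset)
  missing <- full[!(paste(full$observer_id, full$condition, full$abs_offset)
                    %in% have), , drop = FALSE]
  if (nrow(missing)) {
    ffr_stop(paste0(
      "no trials in folded cell(s):\n  - ",
      paste(sprintf("%s / %s / offset %g", missing$observer_id,
                    missing$condition, missing$abs_offset),
            collapse = "\n  - ")),
      "ffr_empty_cell_error")
  }
  agg <- agg[order(agg$observer_id, agg$condition, agg$abs_offset), ]
  rownames(agg) <- NULL
  class(agg) <- c("ffr_folded", "data.frame")
  agg
}

#' Aggregate folded curves across observers
#'
#' @param folded An `ffr_folded` data frame from [fold_and_average()].
#' @return Data frame with one row per condition x absolute offset:
#'   `mean_response` (mean across observers), `sem` (SD across observers
#'   divided by sqrt of the observer count) and `n_observers`.
#' @export
aggregate_curves <- function(folded) {
  stopifnot(is.data.frame(folded))
  n_obs <- length(unique(folded$observer_id))
  if (n_obs < 2) {
    ffr_stop("at least 2 observers are required to aggregate (SEM undefined)",
             "ffr_domain_error")
  }
  m <- aggregate(mean_response ~ condition + abs_offset, data = folded,
                 FUN = mean)
  s <- aggregate(mean_response ~ condition + abs_offset, data = folded,
                 FUN = sd)
  n <- aggregate(mean_response ~ condition + abs_offset, data = folded,
                 FUN = length)
  m$sem <- s$mean_response / sqrt(n$mean_response)
  m$n_observers <- n$mean_response
  m <- m[order(m$condition, m$abs_offset), ]
  rownames(m) <- NULL
  m
}

one_sample_t <- function(v, alternative = "two.sided") {
  n <- length(v)
  m <- mean(v)
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, cohens_d = NA_real_,
                note = "zero-variance: t undefined"))
  }
  tval <- m / (s / sqrt(n))
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(tval), n - 1),
    greater = pt(tval, n - 1, lower.tail = FALSE),
    less = pt(tval, n - 1)
  )
  list(t = tval, df = n - 1L, p = p, cohens_d = m / s, note = "")
}

#' Paired comparisons of the mean offset against every other offset
#'
#' For each absolute offset k > 0, a paired t-test across observers of
#' `mean_response[0] - mean_response[k]`. Under a summary-statistics
#' account the probed value at the mean should always receive the highest
#' rating; the per-condition pattern of these tests probes that prediction.
#' Cohen's d is the mean of the paired differences divided by their SD.
#'
#' @param folded An `ffr_folded` data frame (>= 2 observers, complete
#'   curves).
#' @param conditions Conditions to test; defaults to all present.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Data frame with columns `condition`, `abs_offset`, `t`, `df`,
#'   `p`, `cohens_d`, `note`. Zero-variance differences are flagged in
#'   `note` with `NA` statistics.
#' @export
compare_mean_vs_offsets <- function(folded, conditions = NULL,
                                    alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(folded))
  if (length(unique(folded$observer_id)) < 2) {
    ffr_stop("at least 2 observers are required", "ffr_domain_error")
  }
  conditions <- conditions %||% unique(folded$condition)
  out <- list()
  for (cond in conditions) {
    sub <- folded[folded$condition == cond, ]
    wide <- tapply(sub$mean_response, list(sub$observer_id, sub$abs_offset),
                   identity)
    if (anyNA(wide)) {
      ffr_stop(sprintf("incomplete folded curves in condition '%s'", cond),
               "ffr_empty_cell_error")
    }
    for (k in setdiff(folded_offsets(), 0)) {
      diffs <- wide[, "0"] - wide[, as.character(k)]
      tt <- one_sample_t(diffs, alternative)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, abs_offset = k, t = tt$t, df = tt$df, p = tt$p,
        cohens_d = tt$cohens_d, note = tt$note, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
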