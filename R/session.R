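#' Signed test offsets probed in an FFR session
#'
#' The probed hue is 0, +/-3, ..., +/-12 JND from the mean (a presented
#' color) or 15, 18 or 21 JND outside the range on either side.
#'
#' @return Sorted numeric vector of the 15 signed offsets in JND.
#' @export
test_offsets <- function() {
  sort(c(0, 3, 6, 9, 12, 15, 18, 21, -3, -6, -9, -12, -15, -18, -21))
}

#' Draw signed test offsets
#'
#' Samples from the 15 signed test offsets. The sampling probabilities are
#' configurable; the default is uniform.
#'
#' @param n Number of draws.
#' @param prob Optional vector of 15 probabilities (in the order of
#'   [test_offsets()]); defaults to uniform.
#' @return Numeric vector of `n` signed offsets in JND.
#' @export
sample_test_offset <- function(n = 1L, prob = NULL) {
  offs <- test_offsets()
  if (!is.null(prob)) {
    if (length(prob) != length(offs) || any(!is.finite(prob)) ||
        any(prob < 0) || sum(prob) <= 0) {
      ffr_stop("`prob` must be 15 non-negative weights with positive sum",
               "ffr_domain_error")
    }
  }
  offs[sample.int(length(offs), n, replace = TRUE, prob = prob)]
}

#' Generate an FFR stimulus session
#'
#' One row per trial: a uniformly random mean hue, a condition, and a signed
#' test offset. Conditions are intermixed: within consecutive blocks of
#' three trials each condition appears exactly once, in random order. The
#' `response` column is `NA` until filled by [simulate_dataset()] (or by
#' real data).
#'
#' @param n_trials Number of trials (default 450, about 30 per folded
#'   offset x condition cell under uniform offset sampling).
#' @param observer_id Observer label stored with each trial.
#' @param seed Optional RNG seed; the session is fully reproducible from it.
#'   `NULL` uses (and advances) the current RNG stream.
#' @param wheel A [color_wheel()].
#' @param offset_prob Optional test-offset sampling weights, see
#'   [sample_test_offset()].
#' @param conditions Conditions to intermix (default all three).
#' @return A data frame of class `ffr_session` with columns `observer_id`,
#'   `trial_index`, `condition`, `mean_hue`, `test_offset`, `response`.
#'   The wheel and seed are attached as attributes.
#' @examples
#' s <- generate_session(9, seed = 1)
#' table(s$condition)
#' @export
generate_session <- function(n_trials = 450L, observer_id = "obs01",
                             seed = NULL, wheel = color_wheel(),
                             offset_prob = NULL,
                             conditions = ffr_conditions()) {
  if (length(n_trials) != 1L || !is_whole(n_trials) || n_trials < 1) {
    ffr_stop("`n_trials` must be a positive integer", "ffr_domain_error")
  }
  n_trials <- as.integer(n_trials)
  conditions <- match.arg(conditions, ffr_conditions(), several.ok = TRUE)
  with_seed(seed, {
    mean_hue <- sample.int(wheel$n_hues, n_trials, replace = TRUE) - 1L
    nb <- ceiling(n_trials / length(conditions))
    cond <- unlist(lapply(seq_len(nb), function(i) sample(conditions)),
                   use.names = FALSE)[seq_len(n_trials)]
    off <- sample_test_offset(n_trials, prob = offset_prob)
    out <- data.frame(
      observer_id = observer_id,
      trial_index = seq_len(n_trials),
      condition = cond,
      mean_hue = mean_hue,
      test_offset = off,
      response = NA_integer_,
      stringsAsFactors = FALSE
    )
    attr(out, "wheel") <- wheel
    attr(out, "seed") <- seed
    class(out) <- c("ffr_session", "data.frame")
    out
  })
}

session_columns <- function() {
  c("observer_id", "trial_index", "condition", "mean_hue", "test_offset",
    "response")
}

#' Write a session to CSV
#'
#' Comma-separated, UTF-8, header row, no row names; unfilled responses are
#' written as empty cells.
#'
#' @param session An `ffr_session` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session, require_responses = FALSE)
  write.csv(session[, session_columns()], path, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' Read a session from CSV
#'
#' Validates the schema; violations are reported with the offending row
#' numbers.
#'
#' @param path CSV file path.
#' @param wheel A [color_wheel()] used for range checks.
#' @return An `ffr_session` data frame.
#' @export
read_session <- function(path, wheel = color_wheel()) {
  if (!file.exists(path)) {
    ffr_stop(sprintf("session file not found: %s", path), "ffr_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_session(df, wheel = wheel, require_responses = FALSE)
  df$response <- as.integer(df$response)
  attr(df, "wheel") <- wheel
  class(df) <- c("ffr_session", "data.frame")
  df
}

validate_session <- function(df, wheel = attr(df, "wheel") %||% color_wheel(),
                             require_responses = FALSE) {
  missing_cols <- setdiff(session_columns(), names(df))
  if (length(missing_cols)) {
    ffr_stop(sprintf("session is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "ffr_schema_error")
  }
  probs <- character(0)
  row_msg <- function(bad, what) {
    if (any(bad)) {
      sprintf("%s (rows %s)", what,
              paste(utils::head(which(bad), 10), collapse = ", "))
    } else character(0)
  }
  probs <- c(probs,
    row_msg(!(df$condition %in% ffr_conditions()),
            "invalid `condition` value"),
    row_msg(!is_whole(df$mean_hue) | df$mean_hue < 0 |
              df$mean_hue >= wheel$n_hues,
            sprintf("`mean_hue` outside [0, %d)", wheel$n_hues)),
    row_msg(!(df$test_offset %in% test_offsets()),
            "`test_offset` not one of the 15 tested values")
  )
  resp <- suppressWarnings(as.numeric(df$response))
  filled <- !is.na(resp)
  probs <- c(probs,
    row_msg(filled & (!is_whole(resp) | resp < 0 | resp > 8),
            "`response` must be an integer in [0, 8]"))
  if (require_responses) {
    probs <- c(probs, row_msg(!filled, "`response` is empty"))
  }
  if (length(probs)) {
    ffr_stop(paste0("invalid session:\n  - ",
                    paste(probs, collapse = "\n  - ")),
             "ffr_schema_error")
  }
  invisible(df)
}

#' @export
print.ffr_session <- function(x, ...) {
  cat(sprintf("<ffr_session: %d trials, %d observer(s), responses %s>\n",
              nrow(x), length(unique(x$observer_id)),
              if (all(is.na(x$response))) "empty"
              else sprintf("filled (%d/%d)", sum(!is.na(x$response)), nrow(x))))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more trials\n", nrow(x) - 4L))
  invisible(x)
}
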