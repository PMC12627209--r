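#' Names of the three stimulus distribution conditions
#' @return Character vector `c("gaussian", "uniform", "bimodal")`.
#' @export
ffr_conditions <- function() c("gaussian", "uniform", "bimodal")

#' Fixed exemplar-count distribution of a stimulus condition
#'
#' Each FFR display contains exactly 36 disks whose hues realize a fixed,
#' symmetric count profile around a random mean hue. Counts are indexed by
#' signed offset from the mean in JND (multiples of 3 within +/-12):
#' \describe{
#'   \item{gaussian}{8 at the mean, 7 at each of +/-3, 4 at +/-6, 2 at +/-9,
#'     1 at +/-12.}
#'   \item{uniform}{4 at every offset 0, +/-3, ..., +/-12.}
#'   \item{bimodal}{0 at the mean, 2 at +/-3, 3 at +/-6, 6 at +/-9, 7 at
#'     +/-12.}
#' }
#' All three conditions share the total count (36), the offset range
#' (+/-12 JND) and a mean offset of zero, so they are matched on the summary
#' statistics that a mean-plus-variance account would rely on.
#'
#' @param name One of `"gaussian"`, `"uniform"`, `"bimodal"`.
#' @return An object of class `distribution_spec`: a list with `name`,
#'   `offsets` (signed JND offsets, one entry per offset present) and
#'   `counts` (named integer vector, names are the signed offsets).
#' @examples
#' distribution_spec("gaussian")$counts
#' @export
distribution_spec <- function(name) {
  name <- match.arg(name, ffr_conditions())
  half <- switch(name,
    gaussian = c(`0` = 8L, `3` = 7L, `6` = 4L, `9` = 2L, `12` = 1L),
    uniform  = c(`0` = 4L, `3` = 4L, `6` = 4L, `9` = 4L, `12` = 4L),
    bimodal  = c(`0` = 0L, `3` = 2L, `6` = 3L, `9` = 6L, `12` = 7L)
  )
  offsets <- c(-12L, -9L, -6L, -3L, 0L, 3L, 6L, 9L, 12L)
  counts <- half[as.character(abs(offsets))]
  names(counts) <- offsets
  stopifnot(sum(counts) == 36L)
  structure(list(name = name, offsets = offsets, counts = counts),
            class = "distribution_spec")
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(sprintf("<distribution_spec: %s, %d disks>\n", x$name, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Realize a display as a multiset of hue indices
#'
#' Places the condition's fixed exemplar counts around `mean_hue` on the
#' wheel. The result is deterministic given the inputs (up to list order):
#' a display is fully characterized by its hue multiset, since the frequency
#' report depends only on hue counts.
#'
#' @param spec A [distribution_spec()].
#' @param mean_hue Integer hue index of the distribution mean.
#' @param wheel A [color_wheel()].
#' @return Integer vector of 36 hue indices.
#' @examples
#' table(build_display(distribution_spec("uniform"), 0))
#' @export
build_display <- function(spec, mean_hue, wheel = color_wheel()) {
  stopifnot(inherits(spec, "distribution_spec"))
  mean_hue <- assert_hue(mean_hue, wheel, "mean_hue")
  steps <- spec$offsets / wheel$jnd_per_step
  if (!all(is_whole(steps))) {
    ffr_stop("distribution offsets are not whole wheel steps for this wheel",
             "ffr_domain_error")
  }
  hues <- (mean_hue + rep(round(steps), spec$counts)) %% wheel$n_hues
  as.integer(hues)
}

#' True presented count at an absolute offset
#'
#' Number of disks presented at a single signed offset of the given absolute
#' magnitude (0 for offsets beyond the +/-12 JND range). This is the
#' "ground truth" curve that a noiseless veridical observer would report.
#'
#' @param spec A [distribution_spec()].
#' @param abs_offset Absolute offset in JND; a multiple of 3 in `[0, 21]`.
#' @return Integer count.
#' @examples
#' true_count(distribution_spec("bimodal"), 9) # 6
#' @export
true_count <- function(spec, abs_offset) {
  stopifnot(inherits(spec, "distribution_spec"))
  if (length(abs_offset) != 1L || !is_whole(abs_offset / 3) ||
      abs_offset < 0 || abs_offset > 21) {
    ffr_stop("`abs_offset` must be a multiple of 3 JND in [0, 21]",
             "ffr_domain_error")
  }
  if (abs_offset > 12) return(0L)
  unname(spec$counts[[as.character(abs_offset)]])
}
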