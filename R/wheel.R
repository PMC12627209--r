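#' Circular color wheel
#'
#' The stimulus space is a circular wheel of equally spaced hues; neighboring
#' hues are separated by approximately one just-noticeable difference (JND).
#' All hue arithmetic in the package is circular (modulo `n_hues`), and all
#' offsets and noise magnitudes are expressed in JND.
#'
#' @param n_hues Number of hues on the wheel; must be an even integer >= 2.
#'   Default 48, the wheel used in the FFR paradigm.
#' @param jnd_per_step JND distance between neighboring hues (default 1).
#' @return An object of class `color_wheel` with elements `n_hues` and
#'   `jnd_per_step`.
#' @examples
#' w <- color_wheel()
#' signed_offset(46, 10, w) # +12 JND the short way around
#' @export
color_wheel <- function(n_hues = 48L, jnd_per_step = 1) {
  if (length(n_hues) != 1L || !is_whole(n_hues) || n_hues < 2 ||
      as.integer(n_hues) %% 2L != 0L) {
    ffr_stop("`n_hues` must be a single even integer >= 2", "ffr_domain_error")
  }
  if (!is.numeric(jnd_per_step) || length(jnd_per_step) != 1L ||
      !is.finite(jnd_per_step) || jnd_per_step <= 0) {
    ffr_stop("`jnd_per_step` must be a single positive number",
             "ffr_domain_error")
  }
  structure(
    list(n_hues = as.integer(n_hues), jnd_per_step = as.numeric(jnd_per_step)),
    class = "color_wheel"
  )
}

#' @export
print.color_wheel <- function(x, ...) {
  cat(sprintf("<color_wheel: %d hues, %g JND between neighbors>\n",
              x$n_hues, x$jnd_per_step))
  invisible(x)
}

assert_hue <- function(hue, wheel, arg = "hue") {
  bad <- !is_whole(hue) | hue < 0 | hue >= wheel$n_hues
  if (any(bad)) {
    ffr_stop(
      sprintf("`%s` must contain integer hue indices in [0, %d); offending value(s): %s",
              arg, wheel$n_hues,
              paste(utils::head(hue[bad], 5), collapse = ", ")),
      "ffr_domain_error"
    )
  }
  invisible(as.integer(round(hue)))
}

#' Signed circular offset between two hues
#'
#' Shortest signed displacement from `hue_a` to `hue_b` going around the
#' wheel, in JND. The result lies in `(-n_hues/2, +n_hues/2] * jnd_per_step`;
#' the antipodal tie is resolved to the positive direction.
#'
#' @param hue_a,hue_b Integer hue indices in `[0, n_hues)`; recycled to a
#'   common length.
#' @param wheel A [color_wheel()].
#' @return Numeric vector of signed offsets in JND.
#' @examples
#' signed_offset(5, 5)   # 0
#' signed_offset(0, 24)  # +24: antipodal tie goes positive
#' @export
signed_offset <- function(hue_a, hue_b, wheel = color_wheel()) {
  assert_hue(hue_a, wheel, "hue_a")
  assert_hue(hue_b, wheel, "hue_b")
  d <- (hue_b - hue_a) %% wheel$n_hues
  d <- ifelse(d > wheel$n_hues / 2, d - wheel$n_hues, d)
  d * wheel$jnd_per_step
}
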