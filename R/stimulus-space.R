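#' Stimulus-space conventions for the five fingers
#'
#' The one-dimensional somatosensory stimulus space spans \[-12.5, +12.5\]
#' units, split into five equal 5-unit intervals, one per finger, with D1
#' (thumb) occupying the lowest interval.  These helpers convert between
#' digit indices and stimulus-space positions.
#'
#' @return `digit_centers()` returns the five interval centres
#'   (-10, -5, 0, 5, 10); `digit_to_position(d)` maps digit indices to
#'   centres; `position_to_digit(x)` maps positions to digit indices
#'   1-5 (boundary values go to the higher digit, positions outside the
#'   space are clamped).
#' @name stimulus_space
NULL

#' @rdname stimulus_space
#' @export
digit_centers <- function() c(-10, -5, 0, 5, 10)

#' @rdname stimulus_space
#' @param d Integer vector of digit indices in 1..5.
#' @export
digit_to_position <- function(d) {
  stopifnot(all(d %in% 1:5))
  digit_centers()[d]
}

#' @rdname stimulus_space
#' @param x Numeric vector of stimulus-space positions.
#' @export
position_to_digit <- function(x) {
  stopifnot(is.numeric(x))
  d <- floor((x + 12.5) / 5) + 1
  as.integer(pmin(5, pmax(1, d)))
}

digit_labels <- function() paste0("D", 1:5)
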