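#' BOLD time-series container
#'
#' A thin container for a volumes x vertices BOLD matrix plus its
#' repetition time.  Rows are time points, columns are surface vertices
#' (or finger ROIs for resting-state simulations).
#'
#' @param data Numeric matrix, volumes x vertices.
#' @param tr_s Repetition time in seconds.
#' @param x Object to test or print.
#' @return `somato_ts()` returns a `somato_ts` object.
#' @export
somato_ts <- function(data, tr_s) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), tr_s > 0)
  structure(list(data = data, tr_s = tr_s), class = "somato_ts")
}

#' @rdname somato_ts
#' @export
is_somato_ts <- function(x) inherits(x, "somato_ts")

#' @export
print.somato_ts <- function(x, ...) {
  cat(sprintf("<somato_ts> %d volumes x %d vertices, TR=%gs\n",
              nrow(x$data), ncol(x$data), x$tr_s))
  invisible(x)
}

## coerce matrix-or-somato_ts to somato_ts
as_somato_ts <- function(x, tr_s = NULL) {
  if (is_somato_ts(x)) return(x)
  if (is.null(tr_s)) stop("tr_s required when passing a bare matrix")
  somato_ts(x, tr_s)
}
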