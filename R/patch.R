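#' Synthetic cortical patch with ground-truth finger tuning
#'
#' Builds a triangulated rectangular surface patch (1 mm vertex spacing,
#' flat in z) standing in for the finger-map region of area 3b.  Each
#' vertex carries a ground-truth 1D Gaussian tuning: a preferred
#' stimulus-space position, a tuning width (sigma), a response gain in %
#' signal, and a raw-intensity baseline.  The `linear_gradient` layout
#' assigns preferred positions monotonically along the rows, spanning
#' the full stimulus space \[-12.5, +12.5\], emulating an orderly
#' somatotopic gradient.
#'
#' @param grid_shape Integer vector `c(n_rows, n_cols)`, both >= 2.
#' @param map_layout `"linear_gradient"` or `"custom"` (supply
#'   `preferred_position` yourself).
#' @param sigma_range Length-2 numeric range from which per-vertex tuning
#'   widths are drawn uniformly; must be >= 0.5 (the minimal pRF size,
#'   one tenth of a fingertip's 5-unit interval).
#' @param gain Response gain in % signal (recycled per vertex).
#' @param baseline Raw baseline intensity (recycled per vertex).
#' @param seed Integer seed for the sigma draw.
#' @param preferred_position Optional per-vertex positions for
#'   `map_layout = "custom"`.
#' @return A `cortex_patch`: list with `vertices` (n x 3 mm), `faces`
#'   (m x 3, 1-based vertex triples), `preferred_position`,
#'   `tuning_sigma`, `gain`, `baseline`, `grid_shape`.
#' @export
#' @examples
#' p <- make_cortex_patch(c(10, 10), seed = 1)
#' nrow(p$vertices)  # 100
#' nrow(p$faces)     # 162
make_cortex_patch <- function(grid_shape = c(10, 10),
                              map_layout = c("linear_gradient", "custom"),
                              sigma_range = c(1, 3), gain = 2,
                              baseline = 100, seed = 1,
                              preferred_position = NULL) {
  map_layout <- match.arg(map_layout)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 2))
  if (any(sigma_range < 0.5))
    stop("tuning_sigma below 0.5 (the minimal pRF width) is not allowed")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  n_vert <- nr * nc
  ## vertex (i, j) -> index (i - 1) * nc + j, row-major, 1 mm spacing
  ij <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  vertices <- cbind(x = ij$row - 1, y = ij$col - 1, z = 0)
  faces <- matrix(0L, 2 * (nr - 1) * (nc - 1), 3)
  k <- 0L
  for (i in seq_len(nr - 1)) {
    for (j in seq_len(nc - 1)) {
      v00 <- (i - 1L) * nc + j
      v01 <- v00 + 1L
      v10 <- v00 + nc
      v11 <- v10 + 1L
      faces[k + 1L, ] <- c(v00, v10, v01)
      faces[k + 2L, ] <- c(v01, v10, v11)
      k <- k + 2L
    }
  }
  row_of <- rep(seq_len(nr), each = nc)
  if (map_layout == "linear_gradient") {
    row_pos <- -12.5 + 25 * (seq_len(nr) - 0.5) / nr
    preferred_position <- row_pos[row_of]
  } else {
    if (is.null(preferred_position) || length(preferred_position) != n_vert)
      stop("custom layout needs one preferred_position per vertex")
  }
  local_rng(seed)
  tuning_sigma <- stats::runif(n_vert, sigma_range[1], sigma_range[2])
  structure(
    list(vertices = vertices, faces = faces,
         preferred_position = preferred_position,
         tuning_sigma = tuning_sigma,
         gain = rep_len(gain, n_vert),
         baseline = rep_len(baseline, n_vert),
         grid_shape = c(nr, nc)),
    class = "cortex_patch")
}

#' @export
print.cortex_patch <- function(x, ...) {
  cat(sprintf("<cortex_patch> %d vertices, %d faces, positions [%.1f, %.1f]\n",
              nrow(x$vertices), nrow(x$faces),
              min(x$preferred_position), max(x$preferred_position)))
  invisible(x)
}

## undirected edge list (2-column matrix) of a triangle mesh, deduplicated
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}
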