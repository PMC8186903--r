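#' Read and write time-series, meshes and trial tables
#'
#' Plain-text interchange: time series as tab-delimited matrices
#' (volumes x vertices, TR recorded in a header comment), meshes in OFF
#' format, behavioural trial tables as CSV with a
#' (stimulated_digit, reported_digit, trial) header.
#'
#' @param ts A [somato_ts].
#' @param path File path.
#' @name somatomap_io
NULL

#' @rdname somatomap_io
#' @export
write_timeseries <- function(ts, path) {
  ts <- as_somato_ts(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# somato_ts tr_s=%g", ts$tr_s), con)
  utils::write.table(ts$data, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname somatomap_io
#' @export
read_timeseries <- function(path) {
  header <- readLines(path, n = 1)
  tr <- suppressWarnings(as.numeric(sub(".*tr_s=", "", header)))
  if (!grepl("somato_ts", header) || is.na(tr))
    stop("not a somato_ts file: ", path)
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(m) <- NULL
  somato_ts(m, tr)
}

#' @rdname somatomap_io
#' @param patch A `cortex_patch` (or any list with `vertices`, `faces`).
#' @export
write_mesh_off <- function(patch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(patch$vertices), nrow(patch$faces)),
             con)
  utils::write.table(patch$vertices, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(3L, patch$faces - 1L), con, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname somatomap_io
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  vertices <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                     nv, 3, byrow = TRUE)
  fraw <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 nf, 4, byrow = TRUE)
  list(vertices = vertices, faces = fraw[, 2:4, drop = FALSE] + 1L)
}

#' @rdname somatomap_io
#' @param trials A behavioural trial table.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials[, c("stimulated_digit", "reported_digit",
                              "trial")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname somatomap_io
#' @export
read_trials_csv <- function(path) {
  out <- utils::read.csv(path)
  stopifnot(all(c("stimulated_digit", "reported_digit") %in% names(out)))
  out
}
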