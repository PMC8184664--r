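#' Per-cell fluorescence time series
#'
#' A `trace_matrix` holds one mean-fluorescence time series per imaged cell
#' (ROI), sampled on a uniform frame grid, together with preprocessing flags
#' recording whether the traces have been smoothed and/or normalised to F0.
#'
#' @param values numeric matrix of fluorescence values, one row per frame and
#'   one column per cell. Column names are used as cell ids when `cell_ids`
#'   is not given.
#' @param frame_times_s numeric vector of frame times in seconds, uniformly
#'   spaced (relative tolerance 1e-9). Defaults to `0, dt, 2*dt, ...` with
#'   `dt = frame_interval_s`.
#' @param cell_ids character vector of unique cell identifiers.
#' @param frame_interval_s frame interval in seconds used to build
#'   `frame_times_s` when it is not supplied. Default 2 s (0.5 Hz).
#' @param flags list of preprocessing flags; filled with defaults
#'   (`smoothed = FALSE`, `normalised = FALSE`) when omitted.
#'
#' @return An object of class `trace_matrix`: a list with elements
#'   `cell_ids`, `frame_times_s`, `values` (frames x cells matrix) and
#'   `flags`.
#' @examples
#' tm <- trace_matrix(matrix(rnorm(20), 10, 2), frame_interval_s = 2)
#' tm
#' @export
trace_matrix <- function(values, frame_times_s = NULL, cell_ids = NULL,
                         frame_interval_s = 2, flags = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("trace values must be numeric")
  n_frames <- nrow(values)
  n_cells <- ncol(values)
  if (n_frames < 1L || n_cells < 1L) stopf("trace matrix must be non-empty")
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values) %||% paste0("cell_", seq_len(n_cells))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n_cells) {
    stopf("got %d cell ids for %d trace columns", length(cell_ids), n_cells)
  }
  if (anyDuplicated(cell_ids)) {
    stopf("duplicate cell ids: %s",
          paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  }
  if (is.null(frame_times_s)) {
    if (!is_number(frame_interval_s) || frame_interval_s <= 0) {
      stopf("`frame_interval_s` must be a positive number")
    }
    frame_times_s <- (seq_len(n_frames) - 1) * frame_interval_s
  }
  frame_times_s <- as.numeric(frame_times_s)
  if (length(frame_times_s) != n_frames) {
    stopf("frame_times_s has length %d but traces have %d frames",
          length(frame_times_s), n_frames)
  }
  check_uniform_spacing(frame_times_s)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stopf("non-finite trace value at frame %d, cell '%s'",
          bad[1L], cell_ids[bad[2L]])
  }
  colnames(values) <- cell_ids
  rownames(values) <- NULL
  flags <- utils::modifyList(
    list(smoothed = FALSE, normalised = FALSE,
         smooth_window = NA_integer_, f0_frames = NA_integer_),
    flags
  )
  structure(
    list(cell_ids = cell_ids, frame_times_s = frame_times_s,
         values = values, flags = flags),
    class = "trace_matrix"
  )
}

check_uniform_spacing <- function(times) {
  if (length(times) >= 3L) {
    d <- diff(times)
    if (any(d <= 0)) stopf("frame times must be strictly increasing")
    if ((max(d) - min(d)) > 1e-9 * max(abs(d))) {
      stopf("frame times are not uniformly spaced (max interval %.9g, min %.9g)",
            max(d), min(d))
    }
  }
  invisible(times)
}

#' @export
print.trace_matrix <- function(x, ...) {
  dt <- if (length(x$frame_times_s) > 1L) diff(x$frame_times_s[1:2]) else NA
  cat(sprintf("<trace_matrix> %d cells x %d frames (dt = %g s)\n",
              length(x$cell_ids), nrow(x$values), dt))
  cat(sprintf("  smoothed: %s%s | normalised: %s%s\n",
              x$flags$smoothed,
              if (isTRUE(x$flags$smoothed))
                sprintf(" (window %d)", x$flags$smooth_window) else "",
              x$flags$normalised,
              if (isTRUE(x$flags$normalised))
                sprintf(" (F0 over first %d frames)", x$flags$f0_frames) else ""))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

n_frames <- function(t) nrow(t$values)
n_cells <- function(t) ncol(t$values)

#' Read and write trace files
#'
#' Traces travel as comma-delimited text with header
#' `time_s,<cell id>,<cell id>,...`, one row per frame. `write_traces()`
#' followed by `read_traces()` is the identity on canonical files.
#'
#' @param path path to a trace file.
#' @return `read_traces()` returns a [trace_matrix()]; `write_traces()`
#'   returns `path` invisibly.
#' @examples
#' tm <- trace_matrix(matrix(1:6 / 2, 3, 2, dimnames = list(NULL, c("a", "b"))))
#' f <- tempfile(fileext = ".csv")
#' write_traces(tm, f)
#' read_traces(f)
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stopf("trace file not found: %s", path)
  nf <- utils::count.fields(path, sep = ",", quote = "")
  if (length(nf) < 2L) stopf("trace file %s has no data rows", path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stopf("ragged trace file %s: row %d has %d fields, expected %d",
          path, bad - 1L, nf[bad], nf[1L])
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (header[1L] != "time_s") {
    stopf("trace file %s: first column must be 'time_s', got '%s'",
          path, header[1L])
  }
  if (length(header) < 2L) stopf("trace file %s contains no cell columns", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  vals <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df)), USE.NAMES = TRUE)
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, names(df)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("trace file %s: non-numeric value at data row %d, column '%s'",
          path, bad[1L], colnames(vals)[bad[2L]])
  }
  trace_matrix(vals[, -1L, drop = FALSE],
               frame_times_s = vals[, 1L],
               cell_ids = header[-1L])
}

#' @param t a [trace_matrix()].
#' @rdname read_traces
#' @export
write_traces <- function(t, path) {
  stopifnot(inherits(t, "trace_matrix"))
  df <- data.frame(time_s = t$frame_times_s, t$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cell coordinate files
#'
#' ROI centroid coordinates travel as comma-delimited text with header
#' `cell_id,x,y`.
#'
#' @param path path to a coordinates file.
#' @param coords data frame with columns `cell_id`, `x`, `y`.
#' @return `read_coords()` returns a data frame with columns
#'   `cell_id` (character), `x`, `y` (numeric).
#' @export
read_coords <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("cell_id", "x", "y")
  if (!identical(names(df)[1:3], need)) {
    stopf("coordinates file %s: header must be 'cell_id,x,y'", path)
  }
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id)) stopf("duplicate cell ids in %s", path)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stopf("non-finite coordinate in %s", path)
  }
  df[need]
}

#' @rdname read_coords
#' @export
write_coords <- function(coords, path) {
  stopifnot(all(c("cell_id", "x", "y") %in% names(coords)))
  utils::write.csv(coords[c("cell_id", "x", "y")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
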