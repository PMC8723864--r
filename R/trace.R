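#' Sampled state trajectory
#'
#' A `pbc_trace` wraps a uniformly sampled matrix of state vectors (rows =
#' time points) together with its sampling interval and run provenance.
#'
#' @param states numeric matrix, one column per labelled state component.
#' @param dt_sample sampling interval (ms).
#' @param t0 time of the first row (ms).
#' @param meta named list of provenance (parameters, network, integration
#'   settings); stored as an attribute.
#' @return An object of class `pbc_trace`.
#' @export
new_trace <- function(states, dt_sample, t0 = 0, meta = list()) {
  if (!is.matrix(states) || nrow(states) < 2)
    stop("trace needs a matrix with at least 2 samples")
  if (is.null(colnames(states))) stop("trace columns must be labelled")
  structure(list(states = states, t0 = t0, dt_sample = dt_sample,
                 meta = meta),
            class = "pbc_trace")
}

#' @export
print.pbc_trace <- function(x, ...) {
  cat(sprintf("<pbc_trace> %d samples x %d vars [%s], t = %g..%g ms, dt = %g ms\n",
              nrow(x$states), ncol(x$states),
              paste(colnames(x$states), collapse = ", "),
              x$t0, x$t0 + (nrow(x$states) - 1) * x$dt_sample, x$dt_sample))
  invisible(x)
}

#' Sample times of a trace
#' @param trace a `pbc_trace`.
#' @return Numeric vector of times (ms).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_len(nrow(trace$states)) - 1) * trace$dt_sample
}

#' Extract one state variable from a trace
#' @param trace a `pbc_trace`.
#' @param var column label, e.g. `"V"` or `"V1"`.
#' @export
trace_var <- function(trace, var) {
  if (!var %in% colnames(trace$states))
    stop("no state variable '", var, "' in trace")
  trace$states[, var]
}

#' @export
as.data.frame.pbc_trace <- function(x, ...) {
  data.frame(t = trace_times(x), x$states)
}

#' Drop the initial transient of a trace
#'
#' @param trace a `pbc_trace`.
#' @param frac fraction of the run discarded from the start (default 0.5,
#'   the convention used by every metric in this package).
#' @return The truncated `pbc_trace`.
#' @export
discard_transient <- function(trace, frac = 0.5) {
  stopifnot(frac >= 0, frac < 1)
  n <- nrow(trace$states)
  from <- floor(n * frac) + 1
  if (n - from + 1 < 2) stop("transient discard leaves < 2 samples")
  new_trace(trace$states[from:n, , drop = FALSE], trace$dt_sample,
            t0 = trace$t0 + (from - 1) * trace$dt_sample, meta = trace$meta)
}

#' Write / read a trace as CSV
#'
#' Plain-text round-trip: values are written with full double precision
#' (17 significant digits), so `read_trace_csv(write_trace_csv(x))`
#' reproduces the sampled values exactly.  Metadata is not serialized.
#'
#' @param trace a `pbc_trace`.
#' @param path file path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `pbc_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  txt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  txt <- rbind(colnames(df), txt)
  writeLines(apply(txt, 1, paste, collapse = ","), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = "numeric")
  if (!"t" %in% names(df) || nrow(df) < 2) stop("not a trace CSV")
  dt <- df$t[2] - df$t[1]
  m <- as.matrix(df[setdiff(names(df), "t")])
  new_trace(m, dt_sample = dt, t0 = df$t[1])
}
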