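#' Binary event series
#'
#' Construct an `event_series`: an aligned vector of binary (0/1) event
#' indicators sampled at constant intervals. A value of 1 marks a sample at
#' which the event occurred, 0 one at which it did not. This is the input
#' type for all coincidence counting and causal testing in the package.
#'
#' @param values integer or logical vector; every element must be 0 or 1
#'   (`NA` is not allowed: event logic is undefined for gaps).
#' @param label channel name (single string), used in printed output and as
#'   the column header on disk.
#' @param dt sampling interval in arbitrary time units; metadata only, used
#'   to convert lags (always counted in samples) to time for display.
#' @return an object of class `event_series`: an integer 0/1 vector with
#'   `label` and `dt` attributes.
#' @examples
#' x <- event_series(c(0, 1, 0, 0, 1, 0, 1), label = "X")
#' x
#' @seealso [read_event_series()], [simulate_network()]
#' @export
event_series <- function(values, label = "x", dt = 1) {
  if (is.logical(values)) values <- as.integer(values)
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a non-empty numeric/logical vector", call. = FALSE)
  if (anyNA(values))
    stop("missing values are not allowed in an event series", call. = FALSE)
  v <- as.integer(values)
  if (any(v != values) || any(v != 0L & v != 1L))
    stop("event series values must all be 0 or 1", call. = FALSE)
  if (!is.character(label) || length(label) != 1L)
    stop("'label' must be a single string", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  structure(v, label = label, dt = dt, class = "event_series")
}

#' Coerce to an event series
#'
#' @param x vector, `event_series`, or single-column data frame.
#' @param ... passed to [event_series()].
#' @return an `event_series`.
#' @export
as_event_series <- function(x, ...) {
  if (inherits(x, "event_series")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) != 1L)
      stop("cannot coerce a multi-column data frame to one event series",
           call. = FALSE)
    return(event_series(x[[1L]], label = names(x)[1L], ...))
  }
  event_series(x, ...)
}

#' @export
print.event_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("Event series '%s': %d samples, %d events (rate %.4f)\n",
              attr(x, "label"), n, sum(x), mean(x)))
  invisible(x)
}

#' Binarize a numeric vector by threshold
#'
#' Convenience for turning a continuous channel into events: samples at or
#' above `threshold` become 1, others 0.
#'
#' @param x numeric vector.
#' @param threshold cutoff; `x >= threshold` maps to 1.
#' @param ... passed to [event_series()].
#' @return an `event_series`.
#' @export
binarize <- function(x, threshold, ...) {
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  event_series(as.integer(x >= threshold), ...)
}

# internal: check two aligned series, return common length
check_aligned <- function(x, y) {
  if (length(x) != length(y))
    stop(sprintf("series lengths differ (%d vs %d); inputs must be aligned",
                 length(x), length(y)), call. = FALSE)
  length(x)
}

series_label <- function(x, default) {
  lab <- attr(x, "label")
  if (is.null(lab)) default else lab
}
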