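#' A normalized fluorescence recovery curve
#'
#' Container for a single line-FRAP observable: normalized fluorescence
#' `F(t)/F_pre` sampled at post-bleach times.  Time zero is the first
#' post-bleach sample.  Values are intensities divided by the pre-bleach mean
#' `F_pre` (after background subtraction), so the pre-bleach level corresponds
#' to 1 and the first value must lie below 1 (a bleach happened).
#'
#' @param times Seconds since bleach; strictly increasing, first element 0.
#' @param values Normalized fluorescence, same length as `times`, finite.
#' @param F_pre Pre-bleach mean intensity (arbitrary units, `> 0`), if known.
#' @param meta Named list of acquisition metadata (e.g. `frame_interval_s`,
#'   `condition`, `source`).
#' @param validate Set `FALSE` to skip the bleach-happened check (e.g. for
#'   constant control curves).
#' @return An object of class `"frap_curve"`.
#' @export
recovery_curve <- function(times, values, F_pre = NA_real_, meta = list(),
                           validate = TRUE) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 1L)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("'times' and 'values' must be finite", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (abs(times[1]) > sqrt(.Machine$double.eps))
    stop("first time point must be 0 (the first post-bleach sample)", call. = FALSE)
  if (validate && values[1] >= 1)
    stop("values[1] must be < 1: no bleach is visible in this curve", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 F_pre = F_pre, meta = meta),
            class = "frap_curve")
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("Line-FRAP recovery curve: %d samples over %.4g s\n",
              length(x$times), max(x$times)))
  cat(sprintf("  initial depth %.4f, final value %.4f",
              x$values[1], x$values[length(x$values)]))
  if (is.finite(x$F_pre)) cat(sprintf(", F_pre = %.4g", x$F_pre))
  cat("\n")
  if (!is.null(x$meta$condition))
    cat(sprintf("  condition: %s\n", x$meta$condition))
  invisible(x)
}

#' @export
plot.frap_curve <- function(x, ..., xlab = "time since bleach (s)",
                            ylab = "F / F_pre") {
  graphics::plot(x$times, x$values, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
as.data.frame.frap_curve <- function(x, ...) {
  data.frame(time_s = x$times, F_norm = x$values)
}

#' Read and write recovery-curve CSV files
#'
#' The on-disk dialect is a two-column CSV with header `time_s,F_norm`, one
#' file per curve.
#'
#' @param path File path.
#' @param meta Metadata list attached to the curve on read.
#' @return `read_recovery_csv()` returns a [recovery_curve()];
#'   `write_recovery_csv()` returns `path` invisibly.
#' @export
read_recovery_csv <- function(path, meta = list()) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "F_norm") %in% names(d)))
    stop(sprintf("'%s' lacks the required columns time_s,F_norm", path), call. = FALSE)
  meta$source <- path
  recovery_curve(d$time_s, d$F_norm, meta = meta, validate = FALSE)
}

#' @rdname read_recovery_csv
#' @param curve A [recovery_curve()].
#' @export
write_recovery_csv <- function(curve, path) {
  stopifnot(inherits(curve, "frap_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
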