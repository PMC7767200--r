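#' Optical parameters of a line-bleach experiment
#'
#' Bundles the three constants of the closed-form line-FRAP recovery model:
#' the dimensionless peak bleach dose `K0`, the e^-2 radius of the bleaching
#' line profile `r0e`, and the e^-2 radius of the imaging (detection) profile
#' `r0c`.  All lengths are in micrometres.
#'
#' `K0 = 0` corresponds to no bleaching, for which the model predicts a
#' constant normalized fluorescence of 1.  `r0c = 0` is the idealized limit of
#' a perfectly sharp detection profile; in that limit the model value at
#' `t = 0` equals `exp(-K0)`.
#'
#' @param K0 Dimensionless bleaching parameter, `>= 0`.
#' @param r0e Bleach line e^-2 resolution in micrometres, `> 0`.
#' @param r0c Imaging e^-2 resolution in micrometres, `>= 0`.
#' @return An object of class `"beam_parameters"`.
#' @examples
#' beam <- beam_parameters(K0 = 0.5, r0e = 1, r0c = 0.25)
#' frap_recovery(c(0, 0.1, 1), D = 1, beam = beam)
#' @export
beam_parameters <- function(K0, r0e, r0c = 0) {
  stopifnot(is.numeric(K0), length(K0) == 1L, is.finite(K0),
            is.numeric(r0e), length(r0e) == 1L, is.finite(r0e),
            is.numeric(r0c), length(r0c) == 1L, is.finite(r0c))
  if (K0 < 0) stop("'K0' must be >= 0", call. = FALSE)
  if (r0e <= 0) stop("'r0e' must be > 0", call. = FALSE)
  if (r0c < 0) stop("'r0c' must be >= 0", call. = FALSE)
  structure(list(K0 = K0, r0e = r0e, r0c = r0c), class = "beam_parameters")
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat("Line-FRAP beam parameters\n")
  cat(sprintf("  K0  (bleach dose)        : %g\n", x$K0))
  cat(sprintf("  r0e (bleach resolution)  : %g um\n", x$r0e))
  cat(sprintf("  r0c (imaging resolution) : %g um\n", x$r0c))
  invisible(x)
}

#' Truncation control for the recovery series
#'
#' The closed-form recovery model is an alternating series with factorial
#' decay.  Summation stops once the magnitude of the next term falls below
#' `rel_tol` times the current partial sum, or fails with a truncation error
#' after `n_max` terms.
#'
#' @param rel_tol Relative truncation tolerance, in `(0, 1)`.
#' @param n_max Maximum summation index, integer `>= 1`.
#' @return An object of class `"series_settings"`.
#' @export
series_settings <- function(rel_tol = 1e-10, n_max = 200L) {
  stopifnot(is.numeric(rel_tol), length(rel_tol) == 1L,
            is.numeric(n_max), length(n_max) == 1L)
  if (!(rel_tol > 0 && rel_tol < 1)) stop("'rel_tol' must be in (0, 1)", call. = FALSE)
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop("'n_max' must be an integer >= 1", call. = FALSE)
  structure(list(rel_tol = rel_tol, n_max = n_max), class = "series_settings")
}

is_beam <- function(x) inherits(x, "beam_parameters")
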