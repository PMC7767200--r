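#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("Line-FRAP fit (%s backend, %d point%s)%s\n",
              x$backend, x$n_points, if (x$n_points > 1) "s" else "",
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  comps <- x$components
  comps$label <- classify_quietly(comps$D)
  print(format(comps, digits = 4), row.names = FALSE)
  cat(sprintf("  mobile fraction k = %.3f, F_post0 = %.3f, K0 = %.3g\n",
              x$k_hat, x$F_post0_hat, x$K0_hat))
  cat(sprintf("  residual RMS = %.4g%s\n", x$residual_rms,
              if (isTRUE(x$boundary)) "  [parameter at bound]" else ""))
  invisible(x)
}

classify_quietly <- function(D, threshold_D = 10) {
  suppressWarnings(classify_components(D, threshold_D))
}

#' @export
summary.frap_fit <- function(object, threshold_D = 10, ...) {
  comps <- object$components
  comps$label <- classify_quietly(comps$D, threshold_D)
  structure(list(fit = object, components = comps,
                 threshold_D = threshold_D), class = "summary.frap_fit")
}

#' @export
print.summary.frap_fit <- function(x, ...) {
  print(x$fit)
  mem <- x$components$D[x$components$label == "membrane"]
  if (length(mem)) {
    cat(sprintf("  membrane diffusion coefficient: %.4g um^2/s\n",
                stats::weighted.mean(mem, x$components$weight[x$components$label == "membrane"])))
  } else {
    cat("  no membrane component (all classified free_dye)\n")
  }
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  nc <- nrow(object$components)
  out <- c(object$components$D, object$components$weight,
           object$k_hat, object$F_post0_hat, object$K0_hat)
  names(out) <- c(paste0("D", seq_len(nc)), paste0("weight", seq_len(nc)),
                  "k", "F_post0", "K0")
  out
}

fitted_model_of <- function(object) {
  frap_model(object$components[, c("D", "weight")],
             beam_parameters(object$K0_hat, object$beam$r0e, object$beam$r0c),
             k = object$k_hat,
             F_post0 = min(max(object$F_post0_hat, 1e-9), 1))
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$curve$times
        else if (is.list(newdata) && !is.null(newdata$times)) newdata$times
        else if (is.data.frame(newdata) && !is.null(newdata$time_s)) newdata$time_s
        else as.numeric(newdata)
  if (object$backend == "double_exponential") {
    ef <- object$exp_fit
    return(ef$plateau - ef$amplitudes[1] * exp(-ef$rates[1] * tt) -
             ef$amplitudes[2] * exp(-ef$rates[2] * tt))
  }
  frap_recovery_multi(tt, fitted_model_of(object),
                      settings = object$settings)
}

#' @export
fitted.frap_fit <- function(object, ...) predict(object)

#' @export
residuals.frap_fit <- function(object, ...) {
  object$curve$values - predict(object)
}

#' @export
plot.frap_fit <- function(x, n_grid = 200L, ...) {
  cv <- x$curve
  graphics::plot(cv$times, cv$values, xlab = "time since bleach (s)",
                 ylab = "F / F_pre", ...)
  tt <- seq(min(cv$times), max(cv$times), length.out = n_grid)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Simulate noisy recovery curves from a fitted model
#'
#' Draws `nsim` synthetic curves from the fitted recovery model with i.i.d.
#' Gaussian noise at the fitted residual RMS, on the time grid of the
#' original curve.  Useful for quick parametric-bootstrap checks.
#'
#' @param object A [frap_fit()].
#' @param nsim Number of curves.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [recovery_curve()] objects.
#' @export
simulate.frap_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  tt <- object$curve$times
  lapply(seq_len(nsim), function(i) {
    recovery_curve(tt, mu + stats::rnorm(length(mu), 0, object$residual_rms),
                   meta = list(simulated_from = "frap_fit", replicate = i),
                   validate = FALSE)
  })
}
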