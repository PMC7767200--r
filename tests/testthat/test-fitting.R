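# Curve fitting: self-consistency, the empirical double-exponential
# backend, rate conversion and component classification.

test_that("noiseless single-component fit recovers the generating parameters", {
  beam <- default_beam()
  tt <- seq(0, 20, length.out = 50)
  y <- frap_recovery(tt, 1, beam)
  fit <- frap_fit(recovery_curve(tt, y), beam)
  expect_true(fit$converged)
  expect_equal(fit$components$D, 1, tolerance = 1e-4)
  expect_equal(fit$k_hat, 1, tolerance = 1e-4)
  expect_equal(fit$F_post0_hat, y[1], tolerance = 1e-4)
  expect_lt(fit$residual_rms, 1e-6)
  # methods on the fitted object
  expect_named(coef(fit), c("D1", "weight1", "k", "F_post0", "K0"))
  expect_equal(unname(coef(fit)["K0"]), beam$K0)
  expect_lt(max(abs(residuals(fit))), 1e-5)
  expect_equal(predict(fit, c(0, 5)), frap_recovery(c(0, 5), 1, beam),
               tolerance = 1e-4)
})

test_that("noiseless two-component fit separates fast and slow", {
  beam <- default_beam()
  tt <- seq(0, 1.59, by = 0.01)
  m <- frap_model(data.frame(D = c(30, 1), weight = c(0.4, 0.6)), beam, k = 1)
  y <- frap_recovery_multi(tt, m)
  fit <- frap_fit(recovery_curve(tt, y), beam, fit_options(n_components = 2L))
  expect_equal(fit$components$D, c(30, 1), tolerance = 1e-3)
  expect_equal(fit$components$weight, c(0.4, 0.6), tolerance = 1e-3)
  expect_true(all(diff(fit$components$D) < 0))  # sorted descending
})

test_that("a fixed component coefficient is honoured", {
  beam <- default_beam()
  tt <- seq(0, 1.59, by = 0.01)
  m <- frap_model(data.frame(D = c(30, 1), weight = c(0.4, 0.6)), beam, k = 1)
  y <- frap_recovery_multi(tt, m)
  fit <- frap_fit(recovery_curve(tt, y), beam,
                  fit_options(n_components = 2L, fix_D = c(30, NA)))
  expect_identical(fit$components$D[1], 30)
  expect_true(fit$components$fixed[1])
  expect_equal(fit$components$D[2], 1, tolerance = 1e-3)
})

test_that("too few samples is an explicit error", {
  beam <- default_beam()
  tt <- seq(0, 2, length.out = 5)
  cv <- recovery_curve(tt, frap_recovery(tt, 1, beam))
  expect_error(frap_fit(cv, beam), "at least 8")
  tt2 <- seq(0, 2, length.out = 10)
  cv2 <- recovery_curve(tt2, frap_recovery(tt2, 1, beam))
  expect_error(frap_fit(cv2, beam, fit_options(n_components = 2L)), "at least 15")
})

test_that("a diffusion coefficient on its bound sets the boundary flag", {
  beam <- default_beam()
  tt <- seq(0, 20, length.out = 50)
  y <- frap_recovery(tt, 5, beam)
  fit <- frap_fit(recovery_curve(tt, y), beam,
                  fit_options(D_bounds = c(1e-3, 1), init_grid = c(0.1, 0.9)))
  expect_true(fit$boundary)
  expect_true(any(fit$components$at_bound))
})

test_that("double-exponential fit nests the single-exponential case", {
  tt <- seq(0, 30, length.out = 60)
  y <- 0.95 - 0.5 * exp(-0.3 * tt)
  # a second exponential adds nothing here, so the fit flags single-component
  expect_warning(fit <- fit_double_exponential(recovery_curve(tt, y)),
                 class = "frap_degeneracy_warning")
  dom <- which.max(fit$amplitudes)
  expect_equal(fit$rates[dom], 0.3, tolerance = 0.01)
  expect_equal(fit$plateau, 0.95, tolerance = 0.01)
  expect_true(fit$degenerate)
})

test_that("double-exponential fit recovers two separated rates under noise", {
  # sampling dense enough to resolve the fast rate, long enough for the slow;
  # at 5% noise the fast-rate standard error is ~10-15%, so assert on the
  # median over replicate noise draws
  tt <- c(seq(0, 3, by = 0.05), seq(3.5, 40, by = 0.5))
  y <- 0.9 - 0.2 * exp(-2 * tt) - 0.3 * exp(-0.1 * tt)
  fits <- lapply(1:5, function(s) {
    set.seed(40 + s)
    yn <- y + rnorm(length(y), 0, 0.05 * 0.5)  # 5% of the recovering span
    fit_double_exponential(recovery_curve(tt, yn))
  })
  expect_equal(median(vapply(fits, function(f) f$rates[1], numeric(1))), 2,
               tolerance = 0.15)
  expect_equal(median(vapply(fits, function(f) f$rates[2], numeric(1))), 0.1,
               tolerance = 0.15)
  expect_false(any(vapply(fits, `[[`, logical(1), "degenerate")))
})

test_that("degenerate curves are flagged, not crashed", {
  tt <- seq(0, 10, length.out = 30)
  # constant curve: no recovery at all
  cv <- recovery_curve(tt, rep(0.6, 30), validate = FALSE)
  expect_error(fit_double_exponential(cv), class = "frap_degeneracy_error")
  # two nearly equal rates: collapse warning
  y <- 0.9 - 0.25 * exp(-0.3 * tt) - 0.25 * exp(-0.32 * tt)
  set.seed(7)
  yn <- y + rnorm(length(y), 0, 0.002)
  expect_warning(fit_double_exponential(recovery_curve(tt, yn)),
                 class = "frap_degeneracy_warning")
})

test_that("rates convert to diffusion coefficients by the line-FRAP timescale", {
  beam <- beam_parameters(1, r0e = 1)
  expect_equal(rates_to_diffusion(8, beam), 1)
  expect_equal(rates_to_diffusion(c(8, 16), beam_parameters(1, 2)), c(4, 8))
  expect_error(rates_to_diffusion(0, beam), "> 0")
  expect_error(rates_to_diffusion(-1, beam), "> 0")
})

test_that("double-exponential backend round-trips D under matched acquisition", {
  # Cross-backend fixture, established by fitting noiseless forward-model
  # curves (K0 = 0.2, acquisition window 8Dt/r0e^2 in [0, 80], 80 samples):
  # the dominant-amplitude rate scales exactly with the generating D and
  # recovers it with a calibration factor of 1.904; the literal slow rate
  # chases the 1/sqrt(t) tail and underestimates D about 20-fold, which is
  # why the conversion exposes a calibration constant.
  beam <- beam_parameters(0.2, 1, 0.25)
  ratios <- vapply(c(0.5, 1, 5), function(D) {
    tt <- seq(0, 10 / D, length.out = 80)
    y <- frap_recovery(tt, D, beam)
    fit <- suppressWarnings(fit_double_exponential(recovery_curve(tt, y)))
    dom <- which.max(fit$amplitudes)
    rates_to_diffusion(fit$rates[dom], beam, calibration = 1.904) / D
  }, numeric(1))
  expect_equal(ratios, rep(1, 3), tolerance = 0.02)
  # the conversion factor is invariant across D (relative spread < 1%)
  expect_lt(diff(range(ratios)) / mean(ratios), 0.01)
})

test_that("components classify as membrane or free dye by threshold", {
  expect_identical(classify_components(c(34, 1.2)), c("free_dye", "membrane"))
  expect_identical(classify_components(2), "membrane")
  expect_warning(lab <- classify_components(c(15, 12)),
                 class = "frap_empty_membrane_warning")
  expect_identical(lab, c("free_dye", "free_dye"))
  # configurable threshold
  expect_identical(classify_components(c(34, 1.2), threshold_D = 50),
                   c("membrane", "membrane"))
  # refuses non-converged fits
  fake <- structure(list(converged = FALSE,
                         components = data.frame(D = 1, weight = 1)),
                    class = "frap_fit")
  expect_error(classify_components(fake), "non-converged")
})

test_that("simulate() generates curves consistent with the fitted model", {
  beam <- default_beam()
  tt <- seq(0, 20, length.out = 50)
  y <- frap_recovery(tt, 1, beam)
  fit <- frap_fit(recovery_curve(tt, y + rnorm(50, 0, 0.01)), beam)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "frap_curve")
  expect_equal(mean(sims[[1]]$values - predict(fit)), 0,
               tolerance = 4 * fit$residual_rms / sqrt(50))
})
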