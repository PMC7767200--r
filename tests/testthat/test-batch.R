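# Batch analysis: aggregation, exclusion policy, trend assessment,
# reports, configuration, and the command-line dispatcher.

beam_b <- beam_parameters(0.5, 1, 0.25)

make_curve_set <- function(D_values, seed = 1, fast_weight = 0.2,
                           noise = 0.01) {
  tt <- seq(0, 1.59, by = 0.01)
  lapply(seq_along(D_values), function(i) {
    m <- frap_model(data.frame(D = c(30, D_values[i]),
                               weight = c(fast_weight, 1 - fast_weight)),
                    beam_b, k = 1)
    set.seed(seed + i)
    recovery_curve(tt, frap_recovery_multi(tt, m) +
                     rnorm(length(tt), 0, noise), validate = FALSE)
  })
}

batch_manifest <- function(D_by_temp, n_each = 3, seed = 1) {
  rows <- do.call(rbind, lapply(seq_along(D_by_temp), function(i)
    data.frame(condition = paste0("T", names(D_by_temp)[i]),
               temperature_C = as.numeric(names(D_by_temp)[i]),
               D = D_by_temp[[i]])))
  m <- data.frame(condition = rows$condition,
                  temperature_C = rows$temperature_C)
  m$curve <- make_curve_set(rows$D, seed = seed)
  m
}

opts_b <- fit_options(n_components = 2L, fix_D = c(30, NA))

test_that("batches aggregate membrane components only, per condition", {
  man <- batch_manifest(list(`22` = c(0.5, 0.52, 0.48),
                             `30` = c(0.8, 0.78, 0.82),
                             `38` = c(1.1, 1.05, 1.15)))
  b <- run_batch(man, beam_b, opts_b, require_free_dye = TRUE)
  expect_equal(nrow(b$summaries), 3)
  expect_true(all(b$summaries$n == 3))
  # the injected 30 um^2/s component never contaminates the mean
  expect_true(all(b$summaries$mean_D < 2))
  expect_equal(b$summaries$mean_D, c(0.5, 0.8, 1.1), tolerance = 0.1)
  # n counts successfully fitted, non-excluded scans
  expect_equal(b$summaries$n,
               as.integer(table(b$per_curve$condition[!b$per_curve$excluded])[
                 b$summaries$condition]), ignore_attr = TRUE)
})

test_that("a batch of one reports n = 1 with no SD", {
  man <- batch_manifest(list(`22` = 1))
  b <- run_batch(man, beam_b, opts_b)
  expect_equal(b$summaries$n, 1L)
  expect_true(is.na(b$summaries$sd_D))
  expect_false(is.na(b$summaries$mean_D))
})

test_that("per-curve failures are recorded, never fatal", {
  man <- data.frame(condition = c("a", "a"), temperature_C = c(22, 22),
                    file = c("/nonexistent/x.csv", "/nonexistent/y.csv"))
  b <- suppressWarnings(run_batch(man, beam_b, opts_b))
  expect_true(all(b$per_curve$excluded))
  expect_match(b$per_curve$reason, "load_error", all = TRUE)
  expect_equal(b$summaries$n, 0L)
  expect_equal(b$summaries$excluded, 2L)
})

test_that("trend verdicts: engineered increase, shuffled labels, identical conditions", {
  man <- batch_manifest(list(`22` = c(0.5, 0.52, 0.48, 0.51),
                             `30` = c(0.8, 0.78, 0.82, 0.79),
                             `38` = c(1.1, 1.05, 1.15, 1.12)))
  b <- run_batch(man, beam_b, opts_b)
  tr <- trend_test(b)
  expect_identical(tr$verdict, "increasing")
  expect_gt(tr$statistic, 0.9)
  expect_true(tr$monotone_means)

  # permutation sanity: shuffle temperature labels on the same fits
  b_shuf <- b
  set.seed(99)
  perm <- sample(nrow(b$per_curve))
  b_shuf$per_curve$temperature_C <- b$per_curve$temperature_C[perm]
  b_shuf$per_curve$condition <- b$per_curve$condition[perm]
  s <- b_shuf$summaries
  for (j in seq_len(nrow(s))) {
    rows <- b_shuf$per_curve$condition == s$condition[j] &
      !b_shuf$per_curve$excluded
    s$mean_D[j] <- mean(b_shuf$per_curve$D_membrane[rows])
  }
  b_shuf$summaries <- s
  expect_identical(trend_test(b_shuf)$verdict, "none")

  # all conditions identical: statistic 0
  b_id <- b
  b_id$per_curve$D_membrane <- 1
  b_id$summaries$mean_D <- 1
  tr_id <- trend_test(b_id)
  expect_identical(tr_id$statistic, 0)
  expect_identical(tr_id$verdict, "none")

  # fewer than three conditions: not applicable
  man2 <- batch_manifest(list(`22` = c(0.5, 0.6), `38` = c(1, 1.1)))
  expect_identical(trend_test(run_batch(man2, beam_b, opts_b))$verdict,
                   "not_applicable")
})

test_that("reports round-trip and order conditions by composition then temperature", {
  man <- batch_manifest(list(`30` = c(0.8, 0.82), `22` = c(0.5, 0.52)))
  man$composition <- rep("2:2:1", nrow(man))
  b <- run_batch(man, beam_b, opts_b)
  expect_equal(b$summaries$temperature_C, c(22, 30))  # ascending
  dir <- file.path(tempdir(), "rep")
  paths <- write_report(b, dir, trend = trend_test(b))
  rt <- read_report(dir)
  expect_equal(rt$summaries$mean_D, b$summaries$mean_D)       # exact
  expect_equal(rt$summaries$sd_D, b$summaries$sd_D)
  expect_equal(rt$summaries$n, b$summaries$n)
  expect_identical(rt$summaries$condition, b$summaries$condition)
  expect_identical(rt$provenance$package, "lineFRAP")
  # determinism: a rerun writes identical bytes
  dir2 <- file.path(tempdir(), "rep2")
  b2 <- run_batch(man, beam_b, opts_b)
  write_report(b2, dir2, trend = trend_test(b2))
  expect_identical(readLines(paths$summary_csv),
                   readLines(file.path(dir2, "report_summary.csv")))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("plain-text configuration files parse with units intact", {
  cfgf <- tempfile(fileext = ".cfg")
  writeLines(c("# beam calibration", "K0 = 0.5", "r0e = 1.0  # um",
               "r0c = 0.25", "threshold_D = 10", "label = test"), cfgf)
  cfg <- read_frap_config(cfgf)
  expect_equal(cfg$K0, 0.5)
  expect_equal(cfg$r0e, 1)
  expect_identical(cfg$label, "test")
  bm <- lineFRAP:::beam_from_config(cfg)
  expect_s3_class(bm, "beam_parameters")
  writeLines("no equals sign here", cfgf)
  expect_error(read_frap_config(cfgf), "malformed")
  unlink(cfgf)
})

test_that("the CLI dispatcher fits curves and reports batch status codes", {
  dir <- file.path(tempdir(), "cli")
  dir.create(dir, showWarnings = FALSE)
  # write a curve and a beam config
  tt <- seq(0, 10, length.out = 40)
  cvf <- file.path(dir, "curve.csv")
  write_recovery_csv(recovery_curve(tt, frap_recovery(tt, 1, beam_b)), cvf)
  cfgf <- file.path(dir, "beam.cfg")
  writeLines(c("K0 = 0.5", "r0e = 1", "r0c = 0.25", "n_components = 1"), cfgf)

  status <- frap_cli(c("fit", "--curve", cvf, "--config", cfgf,
                       "--out-dir", dir, "--log-level", "quiet"))
  expect_identical(status, 0L)
  fitj <- jsonlite::read_json(file.path(dir, "curve_fit.json"))
  expect_equal(fitj$components$D[[1]], 1, tolerance = 1e-3)
  expect_true(fitj$converged)

  # batch over a manifest with one unreadable file -> partial failure (1)
  manf <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(file = c(cvf, file.path(dir, "missing.csv")),
                              condition = c("c1", "c1"),
                              temperature_C = c(22, 22)),
                   manf, row.names = FALSE)
  status2 <- suppressWarnings(
    frap_cli(c("batch", "--manifest", manf, "--config", cfgf,
               "--out-dir", dir, "--log-level", "quiet")))
  expect_identical(status2, 1L)
  expect_true(file.exists(file.path(dir, "report_summary.csv")))

  # unknown subcommand -> fatal (2)
  expect_identical(suppressMessages(frap_cli("frobnicate")), 2L)
  unlink(dir, recursive = TRUE)
})
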