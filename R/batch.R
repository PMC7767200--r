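#' Batch-fit recovery curves grouped by experimental condition
#'
#' Runs the full per-curve workflow (load or extract, fit, classify) over a
#' manifest, then aggregates the membrane-component diffusion coefficient
#' per condition into mean, standard deviation, and the number of
#' contributing line scans.  Free-dye components never enter the
#' aggregation, mirroring the standard practice of neglecting the fast
#' buffer-fluorophore component.  Per-curve failures are recorded with
#' reasons and never abort the batch.
#'
#' A curve is excluded from the condition summary when loading or fitting
#' fails, the fit does not converge, a diffusion coefficient rests on its
#' bound, or no component is classified as membrane.  When a curve has two
#' membrane components, it contributes their weight-averaged `D`.
#'
#' @param manifest Data frame (or CSV path) with columns `condition`,
#'   `temperature_C`, and either `file` (per-curve CSV or TIFF stack) or a
#'   list column `curve` of [recovery_curve()] objects.  An optional
#'   `composition` column refines the condition ordering.
#' @param beam A [beam_parameters()] calibration object.
#' @param options A [fit_options()] object (two components by default, so a
#'   free-dye component can be separated).
#' @param threshold_D Free-dye classification threshold, um^2/s.
#' @param roi,background_roi ROIs used when a manifest row points to a TIFF
#'   stack.
#' @param require_free_dye If `TRUE`, a two-component fit in which no
#'   component exceeds the free-dye threshold is excluded as ambiguous
#'   (reason `free_dye_not_separated`).  Appropriate when the sample is
#'   known to contain a free-dye contribution, as every fixture scenario
#'   here does.
#' @return An object of class `"frap_batch"`: `per_curve` (one row per
#'   manifest entry), `summaries` (one row per condition, ordered by
#'   composition then temperature), and the fitted objects.
#' @export
run_batch <- function(manifest, beam,
                      options = fit_options(n_components = 2L),
                      threshold_D = 10, roi = NULL, background_roi = NULL,
                      require_free_dye = FALSE) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(is.data.frame(manifest),
            all(c("condition", "temperature_C") %in% names(manifest)))
  if (!"composition" %in% names(manifest)) manifest$composition <- ""
  n <- nrow(manifest)
  fits <- vector("list", n)
  D_mem <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    cv <- tryCatch({
      if (!is.null(manifest$curve)) manifest$curve[[i]]
      else {
        f <- manifest$file[i]
        if (grepl("\\.csv$", f, ignore.case = TRUE)) read_recovery_csv(f)
        else {
          st <- read_stack(f)
          extract_recovery_curve(st, roi %||% stop("a ROI is required for stack input"),
                                 background_roi = background_roi)
        }
      }
    }, error = function(e) e)
    if (inherits(cv, "error")) {
      reason[i] <- paste0("load_error: ", conditionMessage(cv))
      next
    }
    fit <- tryCatch(frap_fit(cv, beam, options), error = function(e) e)
    if (inherits(fit, "error")) {
      reason[i] <- paste0("fit_error: ", conditionMessage(fit))
      next
    }
    fits[[i]] <- fit
    if (!isTRUE(fit$converged)) {
      reason[i] <- "not_converged"
      next
    }
    lab <- suppressWarnings(classify_components(fit, threshold_D))
    mem <- lab == "membrane"
    if (!any(mem)) {
      reason[i] <- "no_membrane_component"
      next
    }
    at_bound <- fit$components$at_bound %||% rep(FALSE, length(mem))
    if (any(mem & at_bound)) {
      reason[i] <- "boundary"
      next
    }
    if (require_free_dye && !any(!mem)) {
      reason[i] <- "free_dye_not_separated"
      next
    }
    D_mem[i] <- stats::weighted.mean(fit$components$D[mem],
                                     fit$components$weight[mem])
  }

  per_curve <- data.frame(condition = manifest$condition,
                          composition = manifest$composition,
                          temperature_C = manifest$temperature_C,
                          D_membrane = D_mem,
                          excluded = !is.na(reason),
                          reason = reason,
                          stringsAsFactors = FALSE)

  key <- unique(per_curve[, c("condition", "composition", "temperature_C")])
  key <- key[order(key$composition, key$temperature_C), , drop = FALSE]
  summaries <- do.call(rbind, lapply(seq_len(nrow(key)), function(j) {
    rows <- per_curve$condition == key$condition[j]
    d <- per_curve$D_membrane[rows & !per_curve$excluded]
    data.frame(condition = key$condition[j],
               composition = key$composition[j],
               temperature_C = key$temperature_C[j],
               n = length(d),
               mean_D = if (length(d)) mean(d) else NA_real_,
               sd_D = if (length(d) >= 2L) stats::sd(d) else NA_real_,
               excluded = sum(rows & per_curve$excluded),
               stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL
  structure(list(per_curve = per_curve, summaries = summaries, fits = fits,
                 beam = beam, options = options, threshold_D = threshold_D),
            class = "frap_batch")
}

#' @export
print.frap_batch <- function(x, ...) {
  cat(sprintf("Line-FRAP batch: %d curves, %d conditions\n",
              nrow(x$per_curve), nrow(x$summaries)))
  print(format(x$summaries, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Descriptive temperature-trend assessment
#'
#' Reports the Spearman rank correlation between temperature and the
#' per-curve membrane diffusion coefficient (curves pooled across
#' conditions), together with a flag for strictly increasing per-condition
#' means.  The verdict is `"increasing"` only when the correlation is
#' positive, at least `rho_min`, and all ordered condition means increase;
#' otherwise `"none"`.  This is deliberately descriptive -- no p-value is
#' reported.
#'
#' @param batch A [run_batch()] result.
#' @param rho_min Minimum rank correlation for an `"increasing"` verdict.
#' @return An object of class `"frap_trend"`: ordered condition labels and
#'   means, the rank-correlation `statistic`, the `monotone_means` flag and
#'   the `verdict` (`"increasing"`, `"none"`, or `"not_applicable"` for
#'   fewer than 3 conditions).
#' @export
trend_test <- function(batch, rho_min = 0.5) {
  stopifnot(inherits(batch, "frap_batch"))
  s <- batch$summaries[batch$summaries$n >= 1L, , drop = FALSE]
  s <- s[order(s$temperature_C), , drop = FALSE]
  if (nrow(s) < 3L) {
    return(structure(list(labels = s$condition, means = s$mean_D,
                          temperatures = s$temperature_C,
                          statistic = NA_real_, monotone_means = NA,
                          verdict = "not_applicable", n_curves = sum(s$n)),
                     class = "frap_trend"))
  }
  pc <- batch$per_curve[!batch$per_curve$excluded, , drop = FALSE]
  stat <- suppressWarnings(
    stats::cor(pc$temperature_C, pc$D_membrane, method = "spearman"))
  if (!is.finite(stat)) stat <- 0
  monotone <- all(diff(s$mean_D) > 0)
  verdict <- if (stat > 0 && stat >= rho_min && monotone) "increasing" else "none"
  structure(list(labels = s$condition, means = s$mean_D,
                 temperatures = s$temperature_C, statistic = stat,
                 monotone_means = monotone, verdict = verdict,
                 n_curves = nrow(pc)),
            class = "frap_trend")
}

#' @export
print.frap_trend <- function(x, ...) {
  cat("Temperature-trend assessment\n")
  if (length(x$labels))
    for (i in seq_along(x$labels))
      cat(sprintf("  %-20s mean D = %s um^2/s\n", x$labels[i],
                  format(x$means[i], digits = 4)))
  cat(sprintf("  rank correlation = %s, monotone means = %s\n",
              format(x$statistic, digits = 3), x$monotone_means))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write and reload a batch report
#'
#' `write_report()` produces a condition-summary CSV (one row per
#' condition: label, n, mean_D, sd_D, excluded) and a JSON file with the
#' per-curve detail and provenance (package version, options, seeds).
#' `read_report()` reloads both; summaries round-trip exactly.
#'
#' @param batch A [run_batch()] result.
#' @param dir Output directory.
#' @param name Report basename.
#' @param trend Optional [trend_test()] result to embed.
#' @return `write_report()` returns the written paths invisibly;
#'   `read_report()` returns a list with `summaries`, `per_curve` and
#'   `provenance`.
#' @export
write_report <- function(batch, dir, name = "report", trend = NULL) {
  stopifnot(inherits(batch, "frap_batch"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- batch$summaries
  csv <- file.path(dir, paste0(name, "_summary.csv"))
  lines <- c("condition,composition,temperature_C,n,mean_D,sd_D,excluded",
             vapply(seq_len(nrow(s)), function(j) paste(
               s$condition[j], s$composition[j], fmt_num(s$temperature_C[j]),
               s$n[j], fmt_num(s$mean_D[j]), fmt_num(s$sd_D[j]),
               s$excluded[j], sep = ","), character(1)))
  writeLines(lines, csv)

  opts <- batch$options
  provenance <- list(package = "lineFRAP",
                     version = as.character(utils::packageVersion("lineFRAP")),
                     n_components = opts$n_components,
                     fix_beam = opts$fix_beam,
                     D_bounds = opts$D_bounds,
                     seed = opts$seed,
                     threshold_D = batch$threshold_D,
                     beam = unclass(batch$beam))
  js <- file.path(dir, paste0(name, "_detail.json"))
  jsonlite::write_json(list(per_curve = batch$per_curve,
                            summaries = s,
                            trend = if (!is.null(trend)) unclass(trend),
                            provenance = provenance),
                       js, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(list(summary_csv = csv, detail_json = js))
}

#' @rdname write_report
#' @export
read_report <- function(dir, name = "report") {
  csv <- file.path(dir, paste0(name, "_summary.csv"))
  js <- file.path(dir, paste0(name, "_detail.json"))
  summaries <- utils::read.csv(csv, stringsAsFactors = FALSE)
  summaries$condition <- as.character(summaries$condition)
  summaries$composition[is.na(summaries$composition)] <- ""
  detail <- jsonlite::read_json(js, simplifyVector = TRUE)
  pc <- detail$per_curve
  if (!is.null(pc$composition)) pc$composition[is.na(pc$composition)] <- ""
  list(summaries = summaries, per_curve = as.data.frame(pc),
       provenance = detail$provenance, trend = detail$trend)
}
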