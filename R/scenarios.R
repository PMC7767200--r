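#' Inject a fast free-dye component into a recovery curve
#'
#' Mixes a fraction `weight` of single-component closed-form recovery at
#' `D_fast` into an existing curve:
#' `F'(t) = (1 - weight) * F(t) + weight * F_fast(t)`.
#' This is a fixture-construction device for validating the component
#' classification and aggregation stages: it emulates the fast signal of
#' free fluorophores in the buffer above the membrane, which a
#' two-component fit must separate and discard.  It is applied before
#' detection noise so the noise acts on the total signal.
#'
#' @param curve A [recovery_curve()].
#' @param beam A [beam_parameters()] object.
#' @param D_fast Diffusion coefficient of the injected component, um^2/s.
#' @param weight Signal fraction of the injected component, in `[0, 1)`.
#' @return A [recovery_curve()] with the mixed signal.
#' @export
inject_fast_component <- function(curve, beam, D_fast = 30, weight = 0.2) {
  stopifnot(inherits(curve, "frap_curve"), is_beam(beam),
            weight >= 0, weight < 1, D_fast > 0)
  fast <- frap_recovery(curve$times, D_fast, beam)
  recovery_curve(curve$times, (1 - weight) * curve$values + weight * fast,
                 F_pre = curve$F_pre,
                 meta = c(curve$meta,
                          list(injected_D_fast = D_fast,
                               injected_weight = weight)),
                 validate = FALSE)
}

scenario_curve <- function(frac, seed, beam, membrane_count = 40000L,
                           n_frames = 156L, bleach_after_frame = 6L,
                           frame_interval = 0.02, box = 32,
                           domain_radius = 0.2, dt = 0.01,
                           fast_D = 30, fast_weight = 0.2,
                           photons_per_point = 20000) {
  dm <- if (frac > 0) domain_map(box, frac, radius = domain_radius,
                                 seed = seed) else NULL
  cfg <- sim_config(box = box,
                    species = data.frame(D = 1, count = membrane_count,
                                         label = "membrane"),
                    n_frames = n_frames, frame_interval = frame_interval,
                    beam = beam, bleach_after_frame = bleach_after_frame,
                    dt = dt, domain_map = dm, seed = seed)
  cv <- stream_recovery_curve(cfg, collapse_x = TRUE, normalize = "same_frame")
  cv <- inject_fast_component(cv, beam, D_fast = fast_D, weight = fast_weight)
  set.seed(seed + 7L)
  noisy <- stats::rpois(length(cv$values),
                        pmax(cv$values, 0) * photons_per_point) /
    photons_per_point
  recovery_curve(cv$times, noisy, F_pre = cv$F_pre,
                 meta = c(cv$meta, list(domain_area_fraction = frac)),
                 validate = FALSE)
}

#' Synthetic condition-series scenarios
#'
#' `scenario_temperature_series()` builds the homogeneous
#' cholesterol-containing membrane scenario: one obstacle area fraction per
#' nominal temperature (domain coverage shrinking as temperature rises), so
#' the effective membrane diffusion coefficient increases monotonically
#' with the temperature label.  `scenario_gel_membrane()` builds the
#' heterogeneous gel-forming membrane scenario: within every temperature
#' label, half the line scans sit in a dense obstacle field and half in a
#' sparse one, producing high within-condition scatter and no systematic
#' temperature trend.
#'
#' Each curve is an independent Brownian simulation of labelled membrane
#' lipid (D = 1 um^2/s, 4e4 particles, 32 um box, deep bleach K0 = 1 with a
#' 2 um bleach line so the measurement averages over many domains) with its
#' own obstacle layout (0.2 um discs, randomized lattice phase), a 20% fast
#' free-dye component injected at D = 30 um^2/s, and Poisson detection
#' noise at a 2e4-photon budget per sample.  Batch fits should fix the fast
#' coefficient at its known value (`fit_options(n_components = 2,
#' fix_D = c(30, NA))`), the analogue of calibrating the free-dye
#' coefficient on a dye-only control.
#'
#' @param seed Base seed; each curve derives its own.
#' @param n_per_condition Line scans per temperature.
#' @param temperatures_C Nominal temperature labels.
#' @param area_fractions Per-temperature obstacle area fraction
#'   (temperature series), or the two fractions mixed within every
#'   condition (gel scenario).
#' @param beam A [beam_parameters()] object.
#' @return A manifest data frame (`condition`, `composition`,
#'   `temperature_C`, and a `curve` list column) ready for [run_batch()].
#' @export
scenario_temperature_series <- function(seed = 1L, n_per_condition = 12L,
                                        temperatures_C = c(22, 30, 38),
                                        area_fractions = c(0.35, 0.20, 0.05),
                                        beam = beam_parameters(1, 2, 0.25)) {
  stopifnot(length(area_fractions) == length(temperatures_C))
  rows <- list()
  k <- 0L
  for (i in seq_along(temperatures_C)) {
    for (j in seq_len(n_per_condition)) {
      k <- k + 1L
      rows[[k]] <- list(
        condition = sprintf("chol %g C", temperatures_C[i]),
        composition = "2:2:1 DOPC:DPPC:Chol",
        temperature_C = temperatures_C[i],
        curve = scenario_curve(area_fractions[i], seed + k * 101L, beam))
    }
  }
  manifest_from_rows(rows)
}

#' @rdname scenario_temperature_series
#' @export
scenario_gel_membrane <- function(seed = 1L, n_per_condition = 12L,
                                  temperatures_C = c(22, 30, 38),
                                  area_fractions = c(0.5, 0.1),
                                  beam = beam_parameters(1, 2, 0.25)) {
  stopifnot(length(area_fractions) == 2L)
  rows <- list()
  k <- 0L
  for (i in seq_along(temperatures_C)) {
    for (j in seq_len(n_per_condition)) {
      k <- k + 1L
      frac <- area_fractions[1L + (j %% 2L)]
      rows[[k]] <- list(
        condition = sprintf("gel %g C", temperatures_C[i]),
        composition = "1:1 DOPC:DPPC",
        temperature_C = temperatures_C[i],
        curve = scenario_curve(frac, seed + 7919L + k * 101L, beam))
    }
  }
  manifest_from_rows(rows)
}

manifest_from_rows <- function(rows) {
  out <- data.frame(
    condition = vapply(rows, `[[`, character(1), "condition"),
    composition = vapply(rows, `[[`, character(1), "composition"),
    temperature_C = vapply(rows, `[[`, numeric(1), "temperature_C"),
    stringsAsFactors = FALSE)
  out$curve <- lapply(rows, `[[`, "curve")
  out
}
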