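#' Read a plain-text key = value configuration file
#'
#' The configuration dialect is one `key = value` pair per line; `#` starts
#' a comment; values parse as numbers when possible and are kept as strings
#' otherwise.  Documented keys (units in parentheses): `K0` (dimensionless),
#' `r0e` (um), `r0c` (um), `threshold_D` (um^2/s), `n_components`,
#' `D_min`/`D_max` (um^2/s), and the scenario keys used by the command-line
#' interface (`box` um, `n_frames`, `frame_interval` s, `membrane_D` um^2/s,
#' `membrane_count`, `free_dye_D` um^2/s, `free_dye_count`,
#' `immobile_count`, `domain_area_fraction`, `bleach_after_frame`,
#' `pixel_size` um, `photons_per_particle`).
#'
#' @param path Configuration file path.
#' @return Named list of values.
#' @export
read_frap_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("malformed config line (expected key = value): '%s'", ln),
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

beam_from_config <- function(cfg) {
  for (k in c("K0", "r0e"))
    if (is.null(cfg[[k]]))
      stop(sprintf("config is missing beam parameter '%s'", k), call. = FALSE)
  beam_parameters(cfg$K0, cfg$r0e, cfg$r0c %||% 0)
}

options_from_config <- function(cfg, seed = 1L) {
  fit_options(n_components = cfg$n_components %||% 2L,
              D_bounds = c(cfg$D_min %||% 1e-3, cfg$D_max %||% 1e3),
              seed = seed)
}

sim_config_from_config <- function(cfg, seed = 1L) {
  species <- data.frame(
    D = c(cfg$membrane_D %||% 1, cfg$free_dye_D %||% 30, 0),
    count = c(cfg$membrane_count %||% 40000, cfg$free_dye_count %||% 0,
              cfg$immobile_count %||% 0),
    label = c("membrane", "free_dye", "immobile"))
  box <- cfg$box %||% 16
  frac <- cfg$domain_area_fraction %||% 0
  dm <- if (frac > 0) domain_map(box, frac, seed = seed) else NULL
  sim_config(box = box, species = species,
             n_frames = cfg$n_frames %||% 50L,
             frame_interval = cfg$frame_interval %||% 0.1,
             beam = beam_from_config(cfg),
             bleach_after_frame = cfg$bleach_after_frame %||% 10L,
             dt = cfg$dt %||% 0.02,
             domain_map = dm,
             camera = list(pixel_size = cfg$pixel_size %||% 0.1,
                           photons_per_particle = cfg$photons_per_particle %||% 50,
                           read_noise = cfg$read_noise %||% 0,
                           noise = cfg$noise %||% "poisson"),
             seed = seed)
}
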