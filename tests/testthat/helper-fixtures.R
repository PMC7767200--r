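# Shared fixtures and the independent series oracle.

default_beam <- function(K0 = 0.5, r0e = 1, r0c = 0.25) {
  beam_parameters(K0, r0e, r0c)
}

# Independent oracle for the closed-form recovery series: direct 50-term
# summation in factorial form (no recursive update, no truncation logic).
series_oracle <- function(t, D, beam, n_terms = 50L) {
  cc <- beam$r0c^2 + 8 * D * t
  vapply(seq_along(t), function(i) {
    n <- 0:n_terms
    sum((-beam$K0)^n / factorial(n) * beam$r0e / sqrt(beam$r0e^2 + n * cc[i]))
  }, numeric(1))
}

# Small free-diffusion scenario for simulator tests.
quick_config <- function(..., seed = 1L) {
  sim_config(box = 10,
             species = data.frame(D = 1, count = 20000L, label = "membrane"),
             n_frames = 20L, frame_interval = 0.1,
             beam = default_beam(),
             bleach_after_frame = 5L,
             camera = list(pixel_size = 0.1, photons_per_particle = 100,
                           noise = "none"),
             seed = seed, ...)
}

# Noise-free simulated curve via the streaming engine (internal but stable).
sim_curve <- function(config, ...) {
  lineFRAP:::stream_recovery_curve(config, ...)
}
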