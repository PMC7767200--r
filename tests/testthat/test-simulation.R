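# Brownian membrane simulator: diffusion law, bleach model, obstacles,
# determinism, and the brute-force recovery oracle.

test_that("free-diffusion MSD follows 4Dt", {
  cfg <- sim_config(box = 60,
                    species = data.frame(D = 1, count = 10000L,
                                         label = "membrane"),
                    n_frames = 11L, frame_interval = 0.1,
                    beam = default_beam(), bleach_after_frame = 5L, seed = 3L)
  m <- msd_curve(simulate_trajectories(cfg))
  i <- which.min(abs(m$t - 1))
  expect_equal(m$msd[i], 4 * m$t[i], tolerance = 0.03)
})

test_that("immobile particles never move and mobile mixtures stay in the box", {
  cfg <- sim_config(box = 10,
                    species = data.frame(D = c(1, 1), count = c(500L, 500L),
                                         label = c("membrane", "immobile")),
                    n_frames = 10L, frame_interval = 0.1,
                    beam = default_beam(), bleach_after_frame = 3L, seed = 4L)
  traj <- simulate_trajectories(cfg)
  imm <- traj$label == "immobile"
  expect_identical(traj$positions[imm, , 1], traj$positions[imm, , 10])
  expect_true(all(traj$positions >= 0 & traj$positions <= 10))
  expect_false(identical(traj$positions[!imm, , 1], traj$positions[!imm, , 10]))
})

test_that("line bleach follows the Gaussian-dose survival law", {
  beam <- beam_parameters(1, 1, 0.25)
  # K0 = 0: nothing bleached
  b0 <- apply_line_bleach(cbind(runif(100), runif(100)),
                          beam_parameters(0, 1), line_y = 0.5, seed = 1)
  expect_false(any(b0$bleached))
  # on the line, K0 = 1: p = 1 - exp(-1)
  b1 <- apply_line_bleach(cbind(0.5, 5), beam, line_y = 5, mode = "expected")
  expect_equal(b1$prob, 1 - exp(-1))
  expect_equal(b1$survival, exp(-1))
  # far from the line: survival ~ 1
  b2 <- apply_line_bleach(cbind(0.5, 20), beam, line_y = 5, mode = "expected")
  expect_equal(b2$prob, 0, tolerance = 1e-12)
  # bernoulli mode is deterministic under seed
  pos <- cbind(runif(500, 0, 10), runif(500, 0, 10))
  expect_identical(apply_line_bleach(pos, beam, 5, seed = 9)$bleached,
                   apply_line_bleach(pos, beam, 5, seed = 9)$bleached)
})

test_that("trajectories are a pure function of the seed", {
  cfg <- quick_config(seed = 11L)
  t1 <- simulate_trajectories(cfg)
  t2 <- simulate_trajectories(cfg)
  expect_identical(t1$positions, t2$positions)
  t3 <- simulate_trajectories(quick_config(seed = 12L))
  expect_false(identical(t1$positions, t3$positions))
})

test_that("domain maps hit the requested area fraction with disjoint discs", {
  for (frac in c(0.1, 0.35, 0.5)) {
    dm <- domain_map(16, frac, radius = 0.4, seed = 2)
    expect_lt(abs(dm$area_fraction - frac) / frac, 0.02)
    d <- dm$discs
    if (nrow(d) > 1) {
      dd <- as.matrix(dist(d[, c("x", "y")]))
      diag(dd) <- Inf
      expect_gte(min(dd), 2 * d$r[1] - 1e-9)
    }
  }
  expect_error(domain_map(16, 0.9), "area_fraction")
})

test_that("obstructed effective diffusion decreases with domain coverage", {
  d_eff <- vapply(c(0, 0.2, 0.35), function(frac) {
    dm <- if (frac > 0) domain_map(16, frac, radius = 0.3, seed = 5) else NULL
    cfg <- sim_config(box = 16,
                      species = data.frame(D = 1, count = 8000L,
                                           label = "membrane"),
                      n_frames = 30L, frame_interval = 0.04,
                      beam = default_beam(), bleach_after_frame = 5L,
                      dt = 0.01, domain_map = dm, seed = 6L)
    m <- msd_curve(simulate_trajectories(cfg))
    unname(coef(stats::lm(msd ~ t, m[10:30, ]))[2] / 4)
  }, numeric(1))
  expect_true(all(diff(d_eff) < 0))
  expect_lt(d_eff[3], 0.85 * d_eff[1])
})

test_that("membrane particles never sit inside obstacle discs", {
  dm <- domain_map(16, 0.35, radius = 0.4, seed = 7)
  cfg <- sim_config(box = 16,
                    species = data.frame(D = 1, count = 5000L,
                                         label = "membrane"),
                    n_frames = 15L, frame_interval = 0.04,
                    beam = default_beam(), bleach_after_frame = 5L,
                    dt = 0.01, domain_map = dm, seed = 8L)
  traj <- simulate_trajectories(cfg)
  p_end <- traj$positions[, , 15]
  expect_false(any(lineFRAP:::inside_disc(dm, p_end[, 1], p_end[, 2])))
})

test_that("the step-size precondition is enforced with obstacles", {
  dm <- domain_map(16, 0.2, radius = 0.4, seed = 1)
  expect_error(
    sim_config(box = 16,
               species = data.frame(D = 10, count = 100L, label = "membrane"),
               n_frames = 5L, frame_interval = 0.1, beam = default_beam(),
               bleach_after_frame = 2L, dt = 0.05, domain_map = dm),
    "configuration error")
})

test_that("brute-force recovery is constant 1 without bleaching", {
  cfg <- quick_config(seed = 21L)
  traj <- simulate_trajectories(cfg)
  bl <- apply_line_bleach(traj$positions[, , 6], beam_parameters(0, 1, 0.25),
                          cfg$line_y, mode = "expected")
  cv <- brute_force_recovery(traj, bl, normalize = "same_frame")
  expect_equal(cv$values, rep(1, length(cv$values)), tolerance = 1e-12)
})

test_that("simulator matches the closed form (reduced-size oracle check)", {
  beam <- default_beam(K0 = 0.5)
  cfg <- sim_config(box = 10,
                    species = data.frame(D = 1, count = 50000L,
                                         label = "membrane"),
                    n_frames = 30L, frame_interval = 0.1, beam = beam,
                    bleach_after_frame = 8L, seed = 31L)
  traj <- simulate_trajectories(cfg)
  bl <- apply_line_bleach(traj$positions[, , 9], beam, cfg$line_y,
                          mode = "expected")
  cv <- brute_force_recovery(traj, bl, collapse_x = TRUE,
                             normalize = "same_frame")
  model <- frap_recovery(cv$times, 1, beam)
  expect_lt(max(abs(cv$values - model)), 0.02)
  # bernoulli sampling agrees at a looser budget
  blb <- apply_line_bleach(traj$positions[, , 9], beam, cfg$line_y,
                           mode = "bernoulli", seed = 32L)
  cvb <- brute_force_recovery(traj, blb, collapse_x = TRUE,
                              normalize = "same_frame")
  expect_lt(max(abs(cvb$values - model)), 0.05)
})

test_that("an immobile fraction caps the recovery at the mobile-fraction asymptote", {
  beam <- default_beam(K0 = 1)
  cfg <- sim_config(box = 10,
                    species = data.frame(D = c(1, 0),
                                         count = c(42000L, 18000L),
                                         label = c("membrane", "immobile")),
                    n_frames = 48L, frame_interval = 0.25, beam = beam,
                    bleach_after_frame = 8L, seed = 41L)
  traj <- simulate_trajectories(cfg)
  bl <- apply_line_bleach(traj$positions[, , 9], beam, cfg$line_y,
                          mode = "expected")
  cv <- brute_force_recovery(traj, bl, collapse_x = TRUE,
                             normalize = "same_frame")
  k <- 0.7
  model <- frap_model(data.frame(D = 1, weight = 1), beam, k = k)
  expect_lt(max(abs(cv$values - frap_recovery_multi(cv$times, model))), 0.02)
})

test_that("rendered photons are conserved and scale with the photon budget", {
  # point-deposit rendering (r0c = 0) conserves total photons exactly
  cfg <- sim_config(box = 10,
                    species = data.frame(D = 1, count = 2000L,
                                         label = "membrane"),
                    n_frames = 5L, frame_interval = 0.1,
                    beam = beam_parameters(0.5, 1, 0),
                    bleach_after_frame = 2L,
                    camera = list(pixel_size = 0.1, photons_per_particle = 50,
                                  noise = "none"),
                    seed = 51L)
  traj <- simulate_trajectories(cfg)
  bl <- apply_line_bleach(traj$positions[, , 3], cfg$beam, cfg$line_y,
                          mode = "expected")
  st <- render_frames(traj, bl)
  totals <- vapply(st$frames[1:2], sum, numeric(1))  # pre-bleach frames
  expect_equal(totals, rep(2000 * 50, 2))
  # Poisson noise halves when the photon budget quadruples
  rel_noise <- function(photons) {
    cfg$camera$photons_per_particle <- photons
    cfg$camera$noise <- "poisson"
    traj2 <- simulate_trajectories(cfg)
    stn <- render_frames(traj2, bl, seed = 52L)
    cfg$camera$noise <- "none"
    traj3 <- simulate_trajectories(cfg)
    st0 <- render_frames(traj3, bl)
    lam <- st0$frames[[1]]
    keep <- lam > 1
    stats::sd((stn$frames[[1]][keep] - lam[keep]) / lam[keep] * sqrt(lam[keep]))
  }
  expect_equal(rel_noise(200) / rel_noise(50), 1, tolerance = 0.15)
})

test_that("generate_dataset is byte-identical under a fixed seed", {
  cfg <- sim_config(box = 10,
                    species = data.frame(D = 1, count = 3000L,
                                         label = "membrane"),
                    n_frames = 6L, frame_interval = 0.1,
                    beam = default_beam(),
                    bleach_after_frame = 3L,
                    camera = list(pixel_size = 0.1, photons_per_particle = 80,
                                  noise = "poisson"),
                    seed = 61L)
  d1 <- file.path(tempdir(), "gen1"); d2 <- file.path(tempdir(), "gen2")
  r1 <- generate_dataset(cfg, d1)
  r2 <- generate_dataset(cfg, d2)
  expect_identical(unname(tools::md5sum(r1$paths$tiff)),
                   unname(tools::md5sum(r2$paths$tiff)))
  expect_identical(readLines(r1$paths$truth_csv), readLines(r2$paths$truth_csv))
  # manifest carries the ground truth needed to regenerate
  man <- jsonlite::read_json(r1$paths$manifest)
  expect_equal(man$config$seed, 61)
  expect_equal(man$bleach_frame, 4)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("injected fast components mix the closed-form fast signal", {
  beam <- default_beam()
  tt <- seq(0, 2, length.out = 30)
  base <- recovery_curve(tt, frap_recovery(tt, 1, beam))
  mixed <- inject_fast_component(base, beam, D_fast = 30, weight = 0.25)
  expect_equal(mixed$values,
               0.75 * base$values + 0.25 * frap_recovery(tt, 30, beam),
               tolerance = 1e-12)
})
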