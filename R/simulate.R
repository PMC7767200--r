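#' Gel-domain obstacle map
#'
#' Lays out non-overlapping impermeable discs emulating gel or
#' liquid-ordered lipid domains that exclude the fluid-phase probe.  Discs
#' are placed on a jittered square lattice (domains in spin-coated bilayers
#' appear homogeneously distributed), with the disc radius adjusted so the
#' realized area fraction matches the request within 2%.
#'
#' @param box Side length of the square membrane patch, um.
#' @param area_fraction Requested obstacle area fraction in `[0, 0.7]`.
#' @param radius Nominal disc radius, um.
#' @param seed Seed for the placement jitter.
#' @return An object of class `"domain_map"`: `discs` (data frame `x`, `y`,
#'   `r`), `area_fraction` (realized), `box`, and a conservative lookup grid
#'   used for fast collision tests.
#' @export
domain_map <- function(box, area_fraction, radius = 0.6, seed = 1L) {
  stopifnot(box > 0, area_fraction >= 0, area_fraction <= 0.7, radius > 0)
  if (area_fraction == 0) {
    dm <- list(discs = data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
               area_fraction = 0, box = box)
    class(dm) <- "domain_map"
    return(dm)
  }
  # lattice spacing for the requested fraction; non-overlap needs s >= 2 r
  s <- radius * sqrt(pi / area_fraction)
  if (s < 2 * radius)
    stop("requested area_fraction too high for non-overlapping discs", call. = FALSE)
  set.seed(seed)
  # random global lattice phase, so domain layouts are not aligned with the
  # (fixed) bleach line from one realization to the next
  phase <- stats::runif(2, 0, s)
  centers1d <- seq(-s, box + s, by = s)
  grid <- expand.grid(x = centers1d + phase[1], y = centers1d + phase[2])
  grid <- grid[grid$x >= radius & grid$x <= box - radius &
               grid$y >= radius & grid$y <= box - radius, , drop = FALSE]
  n <- nrow(grid)
  if (n < 1L)
    stop("box too small for the requested domain layout", call. = FALSE)
  # adjust radius so realized n * pi r^2 / box^2 matches the request
  r_adj <- box * sqrt(area_fraction / (n * pi))
  jit_max <- max((s - 2 * r_adj) / 2 - 1e-6, 0)
  grid$x <- grid$x + stats::runif(n, -jit_max, jit_max)
  grid$y <- grid$y + stats::runif(n, -jit_max, jit_max)
  grid$x <- pmin(pmax(grid$x, r_adj), box - r_adj)
  grid$y <- pmin(pmax(grid$y, r_adj), box - r_adj)
  realized <- n * pi * r_adj^2 / box^2
  if (abs(realized - area_fraction) / area_fraction > 0.02)
    stop(sprintf("realized area fraction %.3f deviates more than 2%% from request %.3f",
                 realized, area_fraction), call. = FALSE)
  dm <- list(discs = data.frame(x = grid$x, y = grid$y, r = r_adj),
             area_fraction = realized, box = box)
  dm$lookup <- build_disc_lookup(dm)
  class(dm) <- "domain_map"
  dm
}

# Conservative cell -> candidate-disc lookup.  Every cell that could
# contain a point inside disc i (cell centre within r + half the cell
# diagonal) records i as a candidate; the two nearest candidates (by cell
# centre) are kept.  For disjoint discs at this resolution a cell cannot
# intersect more than two disc interiors, so testing both candidates is
# exact.
build_disc_lookup <- function(dm) {
  res <- min(0.08, max(min(dm$discs$r) / 3, dm$box / 3200))
  ncell <- ceiling(dm$box / res)
  ids1 <- matrix(0L, ncell, ncell)
  ids2 <- matrix(0L, ncell, ncell)
  d2min1 <- matrix(Inf, ncell, ncell)
  d2min2 <- matrix(Inf, ncell, ncell)
  cx <- (seq_len(ncell) - 0.5) * res
  halo <- 0.71 * res
  for (i in seq_len(nrow(dm$discs))) {
    xi <- dm$discs$x[i]; yi <- dm$discs$y[i]; ri <- dm$discs$r[i]
    jx <- which(abs(cx - xi) <= ri + halo + res)
    jy <- which(abs(cx - yi) <= ri + halo + res)
    if (!length(jx) || !length(jy)) next
    d2 <- outer((cx[jx] - xi)^2, (cx[jy] - yi)^2, `+`)
    sub <- d2 <= (ri + halo)^2
    b1 <- ids1[jx, jy, drop = FALSE]
    b2 <- ids2[jx, jy, drop = FALSE]
    bd1 <- d2min1[jx, jy, drop = FALSE]
    bd2 <- d2min2[jx, jy, drop = FALSE]
    closer <- sub & d2 < bd1
    b2[closer] <- b1[closer]          # demote the previous nearest
    bd2[closer] <- bd1[closer]
    b1[closer] <- i
    bd1[closer] <- d2[closer]
    second <- sub & !closer & d2 < bd2
    b2[second] <- i
    bd2[second] <- d2[second]
    ids1[jx, jy] <- b1
    ids2[jx, jy] <- b2
    d2min1[jx, jy] <- bd1
    d2min2[jx, jy] <- bd2
  }
  list(ids = ids1, ids2 = ids2, res = res, ncell = ncell)
}

disc_cell_index <- function(dm, x, y) {
  lk <- dm$lookup
  ix <- pmin(pmax(floor(x / lk$res), 0), lk$ncell - 1L) + 1L
  iy <- pmin(pmax(floor(y / lk$res), 0), lk$ncell - 1L) + 1L
  cbind(ix, iy)
}

# TRUE where (x, y) lies strictly inside an obstacle disc
inside_disc <- function(dm, x, y) {
  cells <- disc_cell_index(dm, x, y)
  out <- logical(length(x))
  for (layer in list(dm$lookup$ids, dm$lookup$ids2)) {
    id <- layer[cells]
    hit <- which(!out & id > 0L)
    if (length(hit)) {
      d <- dm$discs[id[hit], ]
      out[hit] <- (x[hit] - d$x)^2 + (y[hit] - d$y)^2 < d$r^2
    }
  }
  out
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("Gel-domain map: %d discs (r = %.3g um) in a %g um box, area fraction %.3f\n",
              nrow(x$discs), if (nrow(x$discs)) x$discs$r[1] else NA,
              x$box, x$area_fraction))
  invisible(x)
}

#' Configuration of a synthetic line-FRAP experiment
#'
#' Defines the full ground-truthed scenario: a square membrane patch with
#' one or more diffusing species, an instantaneous Gaussian line bleach
#' across the patch centre, and camera rendering through a Gaussian imaging
#' profile with Poisson detection noise.
#'
#' Species labels: `"membrane"` (diffuses in the plane, obstructed by gel
#' domains), `"free_dye"` (fast fluorophores in the buffer; modelled as an
#' unobstructed planar species), `"immobile"` (static; gives rise to an
#' immobile fraction).
#'
#' Obstacle interactions are integrated with sub-steps of length at most
#' `dt`, which must satisfy `dt <= r0e^2 / (40 * max D)` over the obstructed
#' species.  In obstacle-free scenarios Brownian increments are sampled
#' exactly at the frame interval.
#'
#' @param box Side length of the membrane patch, um; must be `>= 10 * r0e`.
#' @param species Data frame with columns `D` (um^2/s), `count`, `label`.
#' @param n_frames Total number of frames (pre + post bleach), `>= 3`.
#' @param frame_interval Seconds between frames.
#' @param beam A [beam_parameters()] object.
#' @param bleach_after_frame Number of pre-bleach frames; the bleach occurs
#'   instantaneously before the following frame, which defines `t = 0`.
#' @param dt Sub-step for obstacle integration, s.
#' @param domain_map A [domain_map()] or `NULL`.
#' @param camera List with `pixel_size` (um), `photons_per_particle`,
#'   `read_noise` (counts), `noise` (`"poisson"` or `"none"`).
#' @param seed Integer seed; every stochastic stage derives from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(box = 16,
                       species = data.frame(D = 1, count = 50000L,
                                            label = "membrane"),
                       n_frames = 50L, frame_interval = 0.1,
                       beam = beam_parameters(0.5, 1, 0.25),
                       bleach_after_frame = 10L,
                       dt = 0.02, domain_map = NULL,
                       camera = list(pixel_size = 0.1,
                                     photons_per_particle = 50,
                                     read_noise = 0, noise = "poisson"),
                       seed = 1L) {
  stopifnot(is.data.frame(species),
            all(c("D", "count", "label") %in% names(species)),
            all(species$D >= 0), all(species$count >= 0),
            all(species$label %in% c("membrane", "free_dye", "immobile")),
            is_beam(beam), n_frames >= 3L, bleach_after_frame >= 1L,
            bleach_after_frame < n_frames, frame_interval > 0, dt > 0)
  if (box < 10 * beam$r0e)
    stop("'box' must be at least 10 * r0e to bound edge effects", call. = FALSE)
  if (!is.null(domain_map)) {
    stopifnot(inherits(domain_map, "domain_map"))
    if (abs(domain_map$box - box) > 1e-9)
      stop("'domain_map' box size does not match 'box'", call. = FALSE)
    obstructed <- species$label != "free_dye" & species$D > 0
    if (any(obstructed)) {
      d_max <- max(species$D[obstructed])
      if (dt > beam$r0e^2 / (40 * d_max))
        stop(sprintf(
          "configuration error: dt = %g exceeds r0e^2/(40 max D) = %g for obstructed species",
          dt, beam$r0e^2 / (40 * d_max)), call. = FALSE)
    }
  }
  camera <- utils::modifyList(list(pixel_size = 0.1, photons_per_particle = 50,
                                   read_noise = 0, noise = "poisson"), camera)
  n_px <- round(box / camera$pixel_size)
  if (abs(n_px * camera$pixel_size - box) > 1e-9)
    stop("'box' must be an integer number of pixels", call. = FALSE)
  # bleach line runs along x through the centre of the central pixel row
  line_y <- (n_px %/% 2 - 0.5) * camera$pixel_size
  structure(list(box = box, species = species, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, beam = beam,
                 bleach_after_frame = as.integer(bleach_after_frame),
                 dt = dt, domain_map = domain_map, camera = camera,
                 n_px = as.integer(n_px), line_y = line_y,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic line-FRAP scenario: %g um box, %d frames @ %g s, seed %d\n",
              x$box, x$n_frames, x$frame_interval, x$seed))
  print(x$species, row.names = FALSE)
  cat(sprintf("  K0 = %g, r0e = %g um, r0c = %g um, bleach after frame %d\n",
              x$beam$K0, x$beam$r0e, x$beam$r0c, x$bleach_after_frame))
  if (!is.null(x$domain_map))
    cat(sprintf("  obstacles: area fraction %.3f\n", x$domain_map$area_fraction))
  invisible(x)
}

# reflect coordinates into [0, L] (triangle wave, no branching)
fold_box <- function(x, L) {
  L - abs(x %% (2 * L) - L)
}

#' Simulate particle trajectories
#'
#' Each mobile particle performs 2D Brownian steps with per-axis variance
#' `2 D dt`, reflected at the box walls.  Membrane species reflect off
#' impermeable obstacle discs (a proposed position inside a disc is mirrored
#' across the disc boundary; in the rare case the mirrored point is still
#' blocked the move is rejected).  Free-dye particles ignore obstacles;
#' immobile particles never move.  Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `"frap_traj"`: `positions` (array
#'   `n_particles x 2 x n_frames`, um), `label` (per particle), `D`
#'   (per particle), and the `config`.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eng <- NULL
  out <- NULL
  cb <- function(f, pos, state) {
    if (f == 1L)
      out <<- array(NA_real_, dim = c(nrow(pos), 2L, config$n_frames))
    out[, , f] <<- pos
    NULL
  }
  eng <- sim_engine(config, cb)
  structure(list(positions = out, label = eng$label, D = eng$D,
                 config = config),
            class = "frap_traj")
}

# Core Brownian engine.  Runs the full frame loop and invokes
# frame_callback(frame, positions, state) after every frame; memory stays
# O(n_particles) unless the callback stores more.  All randomness derives
# from config$seed.
sim_engine <- function(config, frame_callback) {
  sp <- config$species
  sp <- sp[sp$count > 0, , drop = FALSE]
  N <- sum(sp$count)
  label <- rep(sp$label, sp$count)
  Dvec <- rep(sp$D, sp$count)
  spid <- rep(seq_len(nrow(sp)), sp$count)
  L <- config$box
  dm <- config$domain_map
  set.seed(config$seed)

  # initial positions: uniform; membrane-bound species start outside discs
  pos <- cbind(stats::runif(N, 0, L), stats::runif(N, 0, L))
  if (!is.null(dm) && nrow(dm$discs)) {
    needs <- label != "free_dye"
    for (iter in 1:200) {
      bad <- which(needs & inside_disc(dm, pos[, 1], pos[, 2]))
      if (!length(bad)) break
      pos[bad, ] <- cbind(stats::runif(length(bad), 0, L),
                          stats::runif(length(bad), 0, L))
    }
  }
  has_obs <- !is.null(dm) && nrow(dm$discs) > 0
  n_sub <- max(1L, ceiling(config$frame_interval / config$dt))
  h <- config$frame_interval / n_sub

  step_free <- function(p, sd1) {
    p <- p + matrix(stats::rnorm(length(p), 0, 1), ncol = 2) * sd1
    p[, 1] <- fold_box(p[, 1], L)
    p[, 2] <- fold_box(p[, 2], L)
    p
  }
  step_obstructed <- function(p, sd1) {
    .obstructed_steps_cpp(p, n_sub, sd1, dm$discs$x, dm$discs$y, dm$discs$r,
                          dm$lookup$ids, dm$lookup$ids2,
                          dm$lookup$res, dm$lookup$ncell, L)
  }

  sp_idx <- split(seq_len(N), spid)
  state <- frame_callback(1L, pos, NULL)
  for (f in 2:config$n_frames) {
    for (si in seq_len(nrow(sp))) {
      idx <- sp_idx[[si]]
      if (!length(idx)) next
      if (!(sp$D[si] > 0) || sp$label[si] == "immobile") next
      if (has_obs && sp$label[si] != "free_dye") {
        pos[idx, ] <- step_obstructed(pos[idx, , drop = FALSE],
                                      sqrt(2 * sp$D[si] * h))
      } else {
        pos[idx, ] <- step_free(pos[idx, , drop = FALSE],
                                sqrt(2 * sp$D[si] * config$frame_interval))
      }
    }
    state <- frame_callback(f, pos, state)
  }
  list(label = label, D = Dvec, state = state)
}

# Streamed simulation of a single ROI recovery curve: runs the engine once,
# applies the bleach at the first post-bleach frame, and accumulates the
# PSF-weighted ROI signal per frame without storing trajectories.
stream_recovery_curve <- function(config, bleach_mode = "expected",
                                  roi = NULL, collapse_x = TRUE,
                                  normalize = "same_frame") {
  if (is.null(roi)) roi <- default_line_roi(config)
  b <- roi_bounds(config, roi)
  sigma <- config$beam$r0c / 2
  pad <- if (sigma > 0) 6 * sigma else 0
  npre <- config$bleach_after_frame
  L <- config$box

  # one pass per frame: both the surviving-particle and all-particle signal
  signals_of <- function(pos, surv) {
    x <- pos[, 1]; y <- pos[, 2]
    near <- which(y >= b$y_lo - pad & y <= b$y_hi + pad &
                  (collapse_x | (x >= b$x_lo - pad & x <= b$x_hi + pad)))
    if (!length(near)) return(c(0, 0))
    w <- if (sigma > 0) {
      wy <- stats::pnorm((b$y_hi - y[near]) / sigma) -
        stats::pnorm((b$y_lo - y[near]) / sigma)
      wx <- if (collapse_x) (b$x_hi - b$x_lo) / L
            else stats::pnorm((b$x_hi - x[near]) / sigma) -
              stats::pnorm((b$x_lo - x[near]) / sigma)
      wx * wy
    } else if (collapse_x) {
      rep((b$x_hi - b$x_lo) / L, length(near))
    } else {
      rep(1, length(near))
    }
    if (is.null(surv)) c(sum(w), sum(w)) else c(sum(surv[near] * w), sum(w))
  }

  cb <- function(f, pos, state) {
    if (is.null(state))
      state <- list(surv = NULL, sig = numeric(config$n_frames),
                    all = numeric(config$n_frames))
    if (f == npre + 1L)
      state$surv <- apply_line_bleach(pos, config$beam, config$line_y,
                                      mode = bleach_mode)$survival
    s2 <- signals_of(pos, if (f <= npre) NULL else state$surv)
    state$sig[f] <- s2[1]
    state$all[f] <- s2[2]
    state
  }
  st <- sim_engine(config, cb)$state
  F_pre <- mean(st$all[seq_len(npre)])
  if (F_pre <= 0) stop("no pre-bleach signal in the ROI", call. = FALSE)
  post <- (npre + 1L):config$n_frames
  values <- if (normalize == "same_frame") st$sig[post] / st$all[post]
            else st$sig[post] / F_pre
  recovery_curve((seq_along(post) - 1L) * config$frame_interval, values,
                 F_pre = F_pre,
                 meta = list(frame_interval_s = config$frame_interval,
                             source = "stream_recovery_curve",
                             normalize = normalize, seed = config$seed),
                 validate = FALSE)
}

#' Mean squared displacement of simulated particles
#'
#' @param traj A [simulate_trajectories()] result.
#' @param label Species label to include.
#' @return Data frame with `t` (s, lag from the first frame) and `msd`
#'   (um^2).
#' @export
msd_curve <- function(traj, label = "membrane") {
  stopifnot(inherits(traj, "frap_traj"))
  idx <- which(traj$label == label)
  if (!length(idx)) stop("no particles with label '", label, "'", call. = FALSE)
  p0 <- traj$positions[idx, , 1L]
  nf <- dim(traj$positions)[3]
  msd <- vapply(seq_len(nf), function(f) {
    d <- traj$positions[idx, , f] - p0
    mean(d[, 1]^2 + d[, 2]^2)
  }, numeric(1))
  data.frame(t = (seq_len(nf) - 1L) * traj$config$frame_interval, msd = msd)
}

#' Apply an instantaneous Gaussian line bleach
#'
#' A particle at perpendicular distance `y` from the bleach line is
#' irreversibly bleached with probability
#' \deqn{p(y) = 1 - \exp\left(-K_0 e^{-2 y^2 / r_{0e}^2}\right),}
#' the survival law of a Gaussian beam line profile with e^-2 radius `r0e`
#' and peak dose `K0` (the simulator's operational definition of `K0`).
#'
#' @param positions Particle positions: an `n x 2` matrix, or a numeric
#'   vector of y coordinates.
#' @param beam A [beam_parameters()] object.
#' @param line_y The y coordinate of the bleach line, um.
#' @param mode `"bernoulli"` samples a hard bleached/survived flag per
#'   particle; `"expected"` returns the exact per-particle survival
#'   probability as a continuous brightness weight (a variance-reduced
#'   estimator of the ensemble mean recovery).
#' @param seed Optional seed for the Bernoulli draw.
#' @return An object of class `"bleach_result"`: `prob` (bleach
#'   probability), `survival` (brightness weight in `[0, 1]`), and
#'   `bleached` (logical, `NULL` in expected mode).
#' @export
apply_line_bleach <- function(positions, beam, line_y,
                              mode = c("bernoulli", "expected"),
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_beam(beam))
  y <- if (is.matrix(positions)) positions[, 2] else as.numeric(positions)
  prob <- 1 - exp(-beam$K0 * exp(-2 * (y - line_y)^2 / beam$r0e^2))
  if (mode == "expected") {
    res <- list(prob = prob, survival = 1 - prob, bleached = NULL,
                mode = mode)
  } else {
    if (!is.null(seed)) set.seed(seed)
    bl <- stats::runif(length(prob)) < prob
    res <- list(prob = prob, survival = as.numeric(!bl), bleached = bl,
                mode = mode)
  }
  class(res) <- "bleach_result"
  res
}

# pixel-integrated Gaussian mass of each particle inside an x/y interval
roi_bounds <- function(config, roi) {
  ps <- config$camera$pixel_size
  list(x_lo = (min(roi$cols) - 1) * ps, x_hi = max(roi$cols) * ps,
       y_lo = (roi$row - 1) * ps, y_hi = roi$row * ps)
}

#' Brute-force recovery curve from particle positions
#'
#' The independent simulation oracle for the closed-form model: per frame,
#' the PSF-weighted fluorescence of surviving particles inside the ROI is
#' summed directly from positions and normalized to its pre-bleach mean.
#' No closed-form model enters the computation.
#'
#' Because the bleach geometry is invariant along the line direction (x),
#' the x-dependence of the ROI weight can be integrated analytically over
#' the uniform stationary distribution (`collapse_x = TRUE`), a
#' Rao-Blackwellized estimator of the same ensemble mean with much lower
#' sampling variance.  This is exact for obstacle-free scenarios; with
#' obstacles the x-y independence it relies on is broken, so the default is
#' the plain per-particle estimator.
#'
#' @param traj A [simulate_trajectories()] result.
#' @param bleach An [apply_line_bleach()] result (evaluated at the first
#'   post-bleach frame).
#' @param roi A [line_roi()]; default is the 100 x 1 pixel line ROI centred
#'   on the bleach line.
#' Two normalizations are available.  `"pre"` divides post-bleach signal by
#' the mean pre-bleach ROI signal, exactly as [extract_recovery_curve()]
#' does on images.  `"same_frame"` divides each post-bleach frame's
#' surviving signal by the all-particle (bleached + unbleached) signal of
#' the same frame; both share the same particle positions, so ROI density
#' fluctuations cancel and the sampling variance of the estimated ensemble
#' mean drops by more than an order of magnitude.  Both estimate the same
#' quantity, since the expected all-particle signal equals the pre-bleach
#' level at every frame.
#'
#' @param collapse_x Integrate the ROI x-weight analytically (see above).
#' @param normalize `"pre"` or `"same_frame"` (see above).
#' @return A noise-free [recovery_curve()].
#' @export
brute_force_recovery <- function(traj, bleach, roi = NULL,
                                 collapse_x = FALSE,
                                 normalize = c("pre", "same_frame")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(traj, "frap_traj"), inherits(bleach, "bleach_result"))
  cfg <- traj$config
  if (is.null(roi)) roi <- default_line_roi(cfg)
  b <- roi_bounds(cfg, roi)
  sigma <- cfg$beam$r0c / 2
  pad <- if (sigma > 0) 6 * sigma else 0
  nf <- cfg$n_frames
  npre <- cfg$bleach_after_frame

  frame_signal <- function(f, surv) {
    x <- traj$positions[, 1, f]
    y <- traj$positions[, 2, f]
    near <- which(y >= b$y_lo - pad & y <= b$y_hi + pad & surv > 0 &
                  (collapse_x | (x >= b$x_lo - pad & x <= b$x_hi + pad)))
    if (!length(near)) return(0)
    if (sigma > 0) {
      wy <- stats::pnorm((b$y_hi - y[near]) / sigma) -
        stats::pnorm((b$y_lo - y[near]) / sigma)
      wx <- if (collapse_x) (b$x_hi - b$x_lo) / cfg$box
            else stats::pnorm((b$x_hi - x[near]) / sigma) -
              stats::pnorm((b$x_lo - x[near]) / sigma)
      sum(surv[near] * wx * wy)
    } else if (collapse_x) {
      sum(surv[near]) * (b$x_hi - b$x_lo) / cfg$box
    } else {
      sum(surv[near])
    }
  }
  alive <- rep(1, length(traj$label))
  pre <- vapply(seq_len(npre), frame_signal, numeric(1), surv = alive)
  post <- vapply((npre + 1L):nf, frame_signal, numeric(1),
                 surv = bleach$survival)
  F_pre <- mean(pre)
  if (F_pre <= 0) stop("no pre-bleach signal in the ROI", call. = FALSE)
  values <- if (normalize == "same_frame") {
    all_post <- vapply((npre + 1L):nf, frame_signal, numeric(1), surv = alive)
    post / all_post
  } else {
    post / F_pre
  }
  recovery_curve((seq_along(post) - 1L) * cfg$frame_interval, values,
                 F_pre = F_pre,
                 meta = list(frame_interval_s = cfg$frame_interval,
                             source = "brute_force_recovery",
                             normalize = normalize,
                             seed = cfg$seed),
                 validate = FALSE)
}

default_line_roi <- function(config, length_px = 100L) {
  row <- config$n_px %/% 2L
  half <- length_px %/% 2L
  c0 <- max(1L, config$n_px %/% 2L - half + 1L)
  line_roi(row = row, col_start = c0,
           col_end = min(config$n_px, c0 + length_px - 1L))
}

#' Render simulated particles into an image stack
#'
#' Surviving particles are deposited as pixel-integrated Gaussian spots of
#' e^-2 radius `r0c` scaled to `photons_per_particle`, followed (in
#' `"poisson"` mode) by per-pixel Poisson sampling, additive Gaussian read
#' noise, and 16-bit clipping.  In `"none"` mode the expected-photon image
#' is returned unquantized.  Deterministic given the configuration seed.
#'
#' @param traj A [simulate_trajectories()] result.
#' @param bleach An [apply_line_bleach()] result.
#' @param seed Seed for the detection noise (default derives from the
#'   configuration seed).
#' @return A [frap_stack()] object.  If more than 1% of pixels saturate, a
#'   warning is issued and recorded in the stack metadata.
#' @export
render_frames <- function(traj, bleach, seed = NULL) {
  stopifnot(inherits(traj, "frap_traj"), inherits(bleach, "bleach_result"))
  cfg <- traj$config
  cam <- cfg$camera
  np <- cfg$n_px
  ps <- cam$pixel_size
  sigma <- cfg$beam$r0c / 2
  sig_px <- sigma / ps
  hw <- if (sigma > 0) ceiling(5.5 * sig_px) + 1L else 0L
  nf <- cfg$n_frames
  npre <- cfg$bleach_after_frame
  if (is.null(seed)) seed <- cfg$seed + 2L
  set.seed(seed)

  deposit <- function(f, surv) {
    x <- traj$positions[, 1, f]
    y <- traj$positions[, 2, f]
    keep <- which(surv > 0)
    if (!length(keep)) return(matrix(0, np, np))
    x <- x[keep]; y <- y[keep]; w <- surv[keep] * cam$photons_per_particle
    if (sigma > 0) {
      .deposit_spots_cpp(x, y, w, np, ps, sigma, hw)
    } else {
      point_deposit(x, y, w, np, ps)
    }
  }

  alive <- rep(1, length(traj$label))
  frames <- vector("list", nf)
  n_sat <- 0L
  for (f in seq_len(nf)) {
    lam <- deposit(f, if (f <= npre) alive else bleach$survival)
    if (identical(cam$noise, "poisson")) {
      counts <- stats::rpois(length(lam), lam)
      if (cam$read_noise > 0)
        counts <- counts + round(stats::rnorm(length(counts), 0, cam$read_noise))
      counts <- pmin(pmax(counts, 0), 65535)
      n_sat <- n_sat + sum(counts == 65535)
      lam <- matrix(as.numeric(counts), np, np)
    }
    frames[[f]] <- lam
  }
  sat_frac <- n_sat / (as.numeric(np)^2 * nf)
  if (sat_frac > 0.01)
    warning(sprintf("%.1f%% of pixels saturated at the 16-bit ceiling",
                    100 * sat_frac))
  frap_stack(frames, frame_interval = cfg$frame_interval, pixel_size = ps,
             bleach_frame = npre + 1L,
             meta = list(seed = seed, saturation_fraction = sat_frac,
                         noise = cam$noise))
}

#' Render a bleached stack together with its unbleached control
#'
#' Produces the bleached image stack and, from the same particle
#' positions, an unbleached control stack (all survival weights 1) in a
#' single pass.  The control is the paired-field reference used by
#' [extract_recovery_curve()]'s `control_stack` argument in synthetic
#' validation: dividing by it cancels the ROI density fluctuations the two
#' stacks share.  Noise-free rendering only.
#'
#' @inheritParams render_frames
#' @return A list with elements `stack` (bleached) and `control`.
#' @export
render_frames_paired <- function(traj, bleach) {
  stopifnot(inherits(traj, "frap_traj"), inherits(bleach, "bleach_result"))
  cfg <- traj$config
  cam <- cfg$camera
  if (!identical(cam$noise, "none"))
    stop("paired rendering is defined for noise = 'none' only", call. = FALSE)
  np <- cfg$n_px
  ps <- cam$pixel_size
  sigma <- cfg$beam$r0c / 2
  hw <- if (sigma > 0) ceiling(5.5 * sigma / ps) + 1L else 0L
  nf <- cfg$n_frames
  npre <- cfg$bleach_after_frame
  alive <- rep(cam$photons_per_particle, length(traj$label))
  wbl <- bleach$survival * cam$photons_per_particle

  frames <- vector("list", nf)
  ctrl <- vector("list", nf)
  for (f in seq_len(nf)) {
    x <- traj$positions[, 1, f]
    y <- traj$positions[, 2, f]
    if (f <= npre) {
      img <- if (sigma > 0) .deposit_spots_cpp(x, y, alive, np, ps, sigma, hw)
             else point_deposit(x, y, alive, np, ps)
      frames[[f]] <- img
      ctrl[[f]] <- img
    } else if (sigma > 0) {
      pair <- .deposit_spots2_cpp(x, y, wbl, alive, np, ps, sigma, hw)
      frames[[f]] <- pair[[1]]
      ctrl[[f]] <- pair[[2]]
    } else {
      frames[[f]] <- point_deposit(x, y, wbl, np, ps)
      ctrl[[f]] <- point_deposit(x, y, alive, np, ps)
    }
  }
  list(stack = frap_stack(frames, frame_interval = cfg$frame_interval,
                          pixel_size = ps, bleach_frame = npre + 1L,
                          meta = list(noise = "none", paired = TRUE)),
       control = frap_stack(ctrl, frame_interval = cfg$frame_interval,
                            pixel_size = ps, bleach_frame = npre + 1L,
                            meta = list(noise = "none", control = TRUE)))
}

point_deposit <- function(x, y, w, np, ps) {
  img <- matrix(0, np, np)
  px <- floor(x / ps); py <- floor(y / ps)
  ok <- px >= 0L & px < np & py >= 0L & py < np & w > 0
  acc <- rowsum(w[ok], py[ok] + 1L + px[ok] * np)
  img[as.integer(rownames(acc))] <- acc
  img
}

#' Generate a complete ground-truthed line-FRAP dataset
#'
#' One call runs the Brownian simulation, applies the line bleach, renders
#' the image stack, computes the noise-free brute-force recovery curve, and
#' writes everything to disk: a multi-frame 16-bit TIFF, a JSON sidecar with
#' acquisition metadata, a JSON ground-truth manifest (full configuration,
#' seeds, per-species truth, bleach summary), and the noise-free curve as
#' CSV.  Regeneration with the same configuration and seed is bit-exact.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the output files.
#' @param bleach_mode `"bernoulli"` or `"expected"` (see
#'   [apply_line_bleach()]).
#' @return Invisibly, a list with the in-memory objects (`traj`, `bleach`,
#'   `stack`, `truth_curve`) and the written `paths`.
#' @export
generate_dataset <- function(config, dir, name = "linefrap",
                             bleach_mode = "bernoulli") {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  traj <- simulate_trajectories(config)
  bleach <- apply_line_bleach(traj$positions[, , config$bleach_after_frame + 1L],
                              config$beam, config$line_y,
                              mode = bleach_mode, seed = config$seed + 1L)
  stack <- render_frames(traj, bleach, seed = config$seed + 2L)
  truth <- brute_force_recovery(traj, bleach)

  tif <- file.path(dir, paste0(name, ".tif"))
  write_stack(stack, tif)
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  write_recovery_csv(truth, csv)
  manifest <- list(
    config = list(box = config$box,
                  species = config$species,
                  n_frames = config$n_frames,
                  frame_interval_s = config$frame_interval,
                  beam = list(K0 = config$beam$K0, r0e = config$beam$r0e,
                              r0c = config$beam$r0c),
                  bleach_after_frame = config$bleach_after_frame,
                  dt = config$dt,
                  domain_area_fraction = if (is.null(config$domain_map)) 0
                                         else config$domain_map$area_fraction,
                  camera = config$camera, seed = config$seed),
    bleach = list(mode = bleach_mode,
                  n_bleached = if (is.null(bleach$bleached)) NA
                               else sum(bleach$bleached),
                  mean_survival = mean(bleach$survival)),
    bleach_frame = config$bleach_after_frame + 1L,
    truth_curve = csv, tiff = tif,
    saturation_fraction = stack$meta$saturation_fraction)
  man <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(frame_interval_s = config$frame_interval,
                            pixel_size_um = config$camera$pixel_size,
                            bleach_frame = config$bleach_after_frame + 1L),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(traj = traj, bleach = bleach, stack = stack,
                 truth_curve = truth,
                 paths = list(tiff = tif, sidecar = sidecar,
                              manifest = man, truth_csv = csv)))
}

#' Simulate replicate noisy recovery curves
#'
#' Convenience wrapper for parameter-recovery experiments: runs independent
#' Brownian simulations (seeds `config$seed + 0:(n-1)`), computes each
#' brute-force recovery curve, and adds Poisson detection noise at a photon
#' budget of `photons_per_point` per sample (relative noise about
#' `1/sqrt(photons_per_point)` at full intensity).
#'
#' @param n Number of replicate curves.
#' @param config A [sim_config()] (its seed is the base seed).
#' @param photons_per_point Photon budget per curve sample.
#' @param bleach_mode Passed to [apply_line_bleach()].
#' @param roi Optional [line_roi()].
#' @param collapse_x Passed to [brute_force_recovery()]; on by default
#'   (these convenience scenarios are obstacle-free).
#' @return A list of [recovery_curve()] objects; each carries its seed in
#'   `meta`.
#' @export
simulate_recovery_curves <- function(n, config, photons_per_point = 2500,
                                     bleach_mode = "expected", roi = NULL,
                                     collapse_x = is.null(config$domain_map),
                                     normalize = if (is.null(config$domain_map))
                                       "same_frame" else "pre") {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 11L
    cv <- stream_recovery_curve(cfg, bleach_mode = bleach_mode, roi = roi,
                                collapse_x = collapse_x,
                                normalize = normalize)
    set.seed(cfg$seed + 2L)
    noisy <- stats::rpois(length(cv$values),
                          pmax(cv$values, 0) * photons_per_point) /
      photons_per_point
    recovery_curve(cv$times, noisy, F_pre = cv$F_pre,
                   meta = c(cv$meta, list(replicate = i, noisy = TRUE)),
                   validate = FALSE)
  })
}
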