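#' Confocal time-lapse image stack
#'
#' @param frames List of `H x W` numeric matrices (rows = y, cols = x), one
#'   per frame, in acquisition order; at least 3 frames (pre-bleach, bleach,
#'   post-bleach).  Intensities follow the 16-bit unsigned convention and
#'   are treated as linear.
#' @param frame_interval Seconds between frames, `> 0`.
#' @param pixel_size Micrometres per pixel, `> 0`.
#' @param bleach_frame 1-based index of the first post-bleach frame, or `NA`
#'   if unknown (see [detect_bleach_frame()]).
#' @param meta Optional metadata list.
#' @return An object of class `"frap_stack"`.
#' @export
frap_stack <- function(frames, frame_interval, pixel_size,
                       bleach_frame = NA_integer_, meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 3L,
            all(vapply(frames, is.matrix, logical(1))))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions", call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be > 0", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be > 0", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size,
                 bleach_frame = as.integer(bleach_frame), meta = meta),
            class = "frap_stack")
}

#' @export
print.frap_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Line-FRAP image stack: %d frames of %d x %d px (%g um/px) @ %g s\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  if (!is.na(x$bleach_frame))
    cat(sprintf("  first post-bleach frame: %d\n", x$bleach_frame))
  invisible(x)
}

#' Line region of interest
#'
#' A one-pixel-high line ROI along x, matching the acquisition convention of
#' line FRAP (default length 100 pixels).  Indices are 1-based and column
#' ranges inclusive, following R convention.  `row` may be a vector of rows
#' for rectangular background, fading or whole-field normalization regions;
#' the measurement ROI itself is conventionally a single row.
#'
#' @param row Pixel row (y index) of the line, or a vector of rows.
#' @param col_start,col_end First and last column (x indices), inclusive.
#' @return An object of class `"line_roi"`.
#' @export
line_roi <- function(row, col_start, col_end) {
  row <- as.integer(row); col_start <- as.integer(col_start)
  col_end <- as.integer(col_end)
  stopifnot(all(row >= 1L), col_start >= 1L, col_end >= col_start)
  structure(list(row = row, cols = col_start:col_end), class = "line_roi")
}

roi_check <- function(roi, frame) {
  d <- dim(frame)
  if (max(roi$row) > d[1] || max(roi$cols) > d[2])
    stop("ROI exceeds the frame bounds", call. = FALSE)
  invisible(TRUE)
}

roi_mean <- function(frame, roi) mean(frame[roi$row, roi$cols])

#' Write an image stack as multi-frame 16-bit TIFF
#'
#' Intensities are rounded and clipped to `[0, 65535]`; integer-valued
#' stacks round-trip bit-exactly through [read_stack()].
#'
#' @param stack A [frap_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frap_stack"))
  imgs <- lapply(stack$frames, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-frame grayscale TIFF stack
#'
#' Acquisition metadata (frame interval, pixel size, optionally the bleach
#' frame) is not reliably stored in TIFF tags, so it must come from a JSON
#' sidecar file (`frame_interval_s`, `pixel_size_um`, optional
#' `bleach_frame`) or from the explicit arguments; missing metadata is an
#' error, never a silent default.
#'
#' @param path TIFF file path.
#' @param sidecar Path to the JSON sidecar; defaults to `path` with a
#'   `.json` extension if such a file exists.
#' @param frame_interval,pixel_size,bleach_frame Explicit metadata,
#'   overriding the sidecar.
#' @return A [frap_stack()].
#' @export
read_stack <- function(path, sidecar = NULL, frame_interval = NULL,
                       pixel_size = NULL, bleach_frame = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e)
                       stop(sprintf("'%s' is not a readable TIFF: %s",
                                    path, conditionMessage(e)), call. = FALSE))
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) != 2L, logical(1))))
    stop("multi-channel (e.g. RGB) TIFF input is not supported; supply a single-channel grayscale stack",
         call. = FALSE)
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  if (is.null(sidecar)) {
    guess <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (file.exists(guess) && guess != path) sidecar <- guess
  }
  sc <- if (!is.null(sidecar)) jsonlite::read_json(sidecar) else list()
  frame_interval <- frame_interval %||% sc$frame_interval_s
  pixel_size <- pixel_size %||% sc$pixel_size_um
  bleach_frame <- bleach_frame %||% sc$bleach_frame %||% NA_integer_
  if (is.null(frame_interval) || is.null(pixel_size))
    stop(sprintf(
      "missing acquisition metadata for '%s': supply frame_interval and pixel_size via arguments or a JSON sidecar",
      path), call. = FALSE)
  frap_stack(frames, frame_interval = as.numeric(frame_interval),
             pixel_size = as.numeric(pixel_size),
             bleach_frame = as.integer(bleach_frame),
             meta = list(source = path, sidecar = sidecar))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the first post-bleach frame
#'
#' Finds the largest single-frame drop in mean ROI intensity (ties broken
#' by the earliest frame).  If that drop does not exceed three times the
#' pre-bleach frame-to-frame standard deviation, detection fails with an
#' error of class `"frap_detection_error"` and the caller should supply the
#' bleach frame explicitly.
#'
#' @param stack A [frap_stack()].
#' @param roi A [line_roi()].
#' @return Integer index of the first post-bleach frame.
#' @export
detect_bleach_frame <- function(stack, roi) {
  stopifnot(inherits(stack, "frap_stack"), inherits(roi, "line_roi"))
  roi_check(roi, stack$frames[[1]])
  m <- vapply(stack$frames, roi_mean, numeric(1), roi = roi)
  drops <- -diff(m)                       # drops[i]: frame i -> i + 1
  cand <- which.max(drops)                # earliest maximal drop
  pre_d <- if (cand >= 4L) drops[seq_len(cand - 1L)] else drops[-cand]
  noise <- if (length(pre_d) >= 2L) stats::sd(pre_d) else 0
  if (!is.finite(drops[cand]) || drops[cand] <= 3 * noise ||
      drops[cand] <= 0) {
    cond <- structure(class = c("frap_detection_error", "error", "condition"),
                      list(message = sprintf(
                        "no bleach detected: largest ROI drop %.4g does not exceed 3 x pre-bleach noise %.4g",
                        drops[cand], noise), call = sys.call()))
    stop(cond)
  }
  cand + 1L
}

#' Extract a normalized recovery curve from an image stack
#'
#' The pre-bleach reference `F_pre` is the mean ROI intensity over all
#' pre-bleach frames after background subtraction; post-bleach values are
#' divided by `F_pre`.  If a `fading_roi` is given, every frame is
#' additionally divided by the fading ROI intensity relative to its own
#' pre-bleach mean, correcting gradual photofading during imaging.  Times
#' are `(frame - bleach_frame) * frame_interval`, starting at 0 at the
#' first post-bleach frame.
#'
#' @param stack A [frap_stack()].
#' @param roi Measurement [line_roi()].
#' @param background_roi Optional far-field [line_roi()]; its per-frame mean
#'   is subtracted as a constant background.
#' @param fading_roi Optional [line_roi()] used for relative-intensity
#'   normalization: a far-field region corrects gradual photofading, and a
#'   whole-field region additionally corrects depletion of the finite
#'   fluorescent pool (the bleached molecules missing from the total
#'   signal), the standard whole-field normalization of FRAP analysis.
#' @param bleach_frame First post-bleach frame; defaults to the stack's
#'   value, else [detect_bleach_frame()].
#' @param control_stack Optional paired unbleached stack rendered from the
#'   same particle field (a synthetic-validation device): each frame's ROI
#'   signal is divided by the control's, cancelling shared density
#'   fluctuations before the pre-bleach normalization.
#' @return A [recovery_curve()] with provenance in `meta`.
#' @export
extract_recovery_curve <- function(stack, roi, background_roi = NULL,
                                   fading_roi = NULL, bleach_frame = NULL,
                                   control_stack = NULL) {
  stopifnot(inherits(stack, "frap_stack"), inherits(roi, "line_roi"))
  roi_check(roi, stack$frames[[1]])
  if (!is.null(background_roi)) roi_check(background_roi, stack$frames[[1]])
  if (!is.null(fading_roi)) roi_check(fading_roi, stack$frames[[1]])
  bf <- bleach_frame %||%
    (if (!is.na(stack$bleach_frame)) stack$bleach_frame
     else detect_bleach_frame(stack, roi))
  nf <- length(stack$frames)
  if (bf < 2L || bf > nf) stop("invalid bleach frame index", call. = FALSE)

  bg <- if (is.null(background_roi)) rep(0, nf)
        else vapply(stack$frames, roi_mean, numeric(1), roi = background_roi)
  sig <- vapply(stack$frames, roi_mean, numeric(1), roi = roi) - bg
  if (!is.null(control_stack)) {
    stopifnot(inherits(control_stack, "frap_stack"),
              length(control_stack$frames) == nf)
    ctrl <- vapply(control_stack$frames, roi_mean, numeric(1), roi = roi)
    if (any(ctrl <= 0)) stop("control stack ROI signal is not positive", call. = FALSE)
    sig <- sig / ctrl
  }
  pre_idx <- seq_len(bf - 1L)
  F_pre <- mean(sig[pre_idx])
  if (!is.finite(F_pre) || F_pre <= 0)
    stop("pre-bleach ROI intensity is not positive after background subtraction",
         call. = FALSE)
  fade <- rep(1, nf)
  if (!is.null(fading_roi)) {
    fd <- vapply(stack$frames, roi_mean, numeric(1), roi = fading_roi) - bg
    fd_pre <- mean(fd[pre_idx])
    if (!is.finite(fd_pre) || fd_pre <= 0)
      stop("fading ROI intensity is not positive in the pre-bleach frames",
           call. = FALSE)
    fade <- fd / fd_pre
  }
  post <- bf:nf
  values <- sig[post] / (F_pre * fade[post])
  recovery_curve((post - bf) * stack$frame_interval, values, F_pre = F_pre,
                 meta = list(frame_interval_s = stack$frame_interval,
                             bleach_frame = bf,
                             roi = unclass(roi),
                             background = !is.null(background_roi),
                             fading_corrected = !is.null(fading_roi),
                             source = stack$meta$source))
}

#' Estimate the bleach line resolution from the first post-bleach frame
#'
#' Averages the intensity profile perpendicular to the bleach line over the
#' ROI columns, normalizes it by the pre-bleach profile (removing static
#' structure such as domains), and fits a Gaussian dip
#' `b * (1 - A * exp(-2 (y - y0)^2 / w^2))`.  The imaging profile broadens
#' the dip, so if `r0c` is supplied the returned estimate is deconvolved in
#' quadrature: `r0e = sqrt(w^2 - r0c^2)`.
#'
#' @param stack A [frap_stack()].
#' @param roi A [line_roi()] marking the bleach line columns.
#' @param bleach_frame First post-bleach frame; defaults to the stack's.
#' @param r0c Imaging e^-2 radius in um used for the quadrature correction
#'   (0 = no correction).
#' @return An object of class `"r0e_estimate"`: `r0e` (um), `width_raw`
#'   (um, before correction), `depth` (fitted dip contrast `A`), `quality`
#'   (R^2 of the profile fit).  If the dip contrast is below three times
#'   the profile residual noise, estimation fails with an error of class
#'   `"frap_estimation_error"`.
#' @export
estimate_bleach_resolution <- function(stack, roi, bleach_frame = NULL,
                                       r0c = 0) {
  stopifnot(inherits(stack, "frap_stack"), inherits(roi, "line_roi"))
  roi_check(roi, stack$frames[[1]])
  bf <- bleach_frame %||% stack$bleach_frame
  if (is.na(bf) || bf < 2L || bf > length(stack$frames))
    stop("a valid bleach frame index is required", call. = FALSE)
  ps <- stack$pixel_size
  post_prof <- rowMeans(stack$frames[[bf]][, roi$cols, drop = FALSE])
  pre_prof <- rowMeans(Reduce(`+`, stack$frames[seq_len(bf - 1L)])[, roi$cols,
                                                                   drop = FALSE]) /
    (bf - 1L)
  ok <- pre_prof > 0.2 * stats::median(pre_prof)
  y <- (which(ok) - 0.5) * ps
  ratio <- post_prof[ok] / pre_prof[ok]

  b0 <- stats::median(ratio)
  y0_0 <- y[which.min(ratio)]
  dip <- pmax(b0 - ratio, 0)
  w0 <- if (sum(dip) > 0) {
    2 * sqrt(sum(dip * (y - y0_0)^2) / sum(dip) / 2 + (ps / 2)^2)
  } else 2 * ps
  A0 <- min(max(-log(max(min(ratio), 1e-6) / b0), 1e-3), 10)
  # survival profile of a Gaussian bleach line: b * exp(-A exp(-2(y-y0)^2/w^2));
  # reduces to the Gaussian dip b (1 - A exp(...)) for small dose A
  p0 <- c(b = b0, A = A0, y0 = y0_0, w = w0)
  resid_fun <- function(p) p[1] * exp(-p[2] * exp(-2 * (y - p[3])^2 / p[4]^2)) - ratio
  fit <- minpack.lm::nls.lm(par = p0,
                            lower = c(1e-6, 0, min(y), ps / 4),
                            upper = c(10, 20, max(y), diff(range(y))),
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200L))
  p <- fit$par
  r <- resid_fun(p)
  quality <- 1 - sum(r^2) / max(sum((ratio - mean(ratio))^2), 1e-300)
  contrast <- p[1] * (1 - exp(-p[2]))
  if (!is.finite(contrast) || contrast < 3 * stats::sd(r)) {
    cond <- structure(class = c("frap_estimation_error", "error", "condition"),
                      list(message = sprintf(
                        "bleach dip contrast %.4g is below 3 x profile noise %.4g: cannot estimate r0e",
                        contrast, stats::sd(r)), call = sys.call()))
    stop(cond)
  }
  w <- unname(p[4])
  r0e <- if (r0c > 0 && w > r0c) sqrt(w^2 - r0c^2) else w
  structure(list(r0e = r0e, width_raw = w, depth = unname(1 - exp(-p[2])),
                 K0_hat = unname(p[2]), quality = quality, y0 = unname(p[3]),
                 converged = fit$info %in% 1:4),
            class = "r0e_estimate")
}

#' @export
print.r0e_estimate <- function(x, ...) {
  cat(sprintf("Bleach resolution estimate: r0e = %.4g um (raw width %.4g um)\n",
              x$r0e, x$width_raw))
  cat(sprintf("  dip depth %.3f, fit R^2 = %.4f\n", x$depth, x$quality))
  invisible(x)
}
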