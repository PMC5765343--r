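#' Acquisition configuration for a high-speed recording
#'
#' Describes the camera geometry and timing of a recording. Defaults match
#' the acquisition used throughout the package's validation suite: 228 x 320
#' pixel frames at 300 frames/s for 1000 frames, with 28 pixels spanning
#' 10 micrometres.
#'
#' @param height_px,width_px Frame dimensions in pixels (positive integers).
#' @param fps Acquisition rate in frames per second.
#' @param n_frames Number of frames per recording.
#' @param px_per_10um Spatial calibration: pixels per 10 micrometres.
#' @return An object of class `acquisition_config`.
#' @examples
#' cfg <- acquisition_config()
#' cfg$height_px * cfg$width_px  # pixels analysed per frame
#' @export
acquisition_config <- function(height_px = 228L, width_px = 320L, fps = 300,
                               n_frames = 1000L, px_per_10um = 28) {
  height_px <- as.integer(height_px)
  width_px <- as.integer(width_px)
  n_frames <- as.integer(n_frames)
  if (any(is.na(c(height_px, width_px, n_frames))) ||
      height_px < 1L || width_px < 1L || n_frames < 1L)
    stop("height_px, width_px and n_frames must be positive integers")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (!is.numeric(px_per_10um) || px_per_10um <= 0)
    stop("px_per_10um must be positive")
  structure(list(height_px = height_px, width_px = width_px, fps = fps,
                 n_frames = n_frames, px_per_10um = px_per_10um),
            class = "acquisition_config")
}

#' Parametric model of a beating flagellum
#'
#' A travelling sinusoidal wave on a straight centreline, rendered as a
#' bright curve with a Gaussian cross-section and a bright head disc on a
#' dark background. The lateral displacement of the midline at axial
#' position `s` (micrometres from the head) and time `t` is
#' `A(s) * sin(2*pi*f*t - 2*pi*s/lambda + phase)`, where `A(s)` is the
#' (optionally linearly tapered) amplitude. Every estimator target is
#' therefore analytic: the true beat frequency is `f` and the mean lateral
#' speed of any midline point is `4*A*f`.
#'
#' Coordinates are 1-based (row, col) with the origin at the top-left pixel
#' and rows increasing downward; `orientation_deg` is the centreline angle
#' measured from the +column axis toward +row.
#'
#' @param length_um Arc length of the flagellum (micrometres).
#' @param amplitude_um Peak lateral excursion A (micrometres).
#' @param beat_frequency_hz Beat frequency f (Hz); must be below the Nyquist
#'   limit `fps / 2` of the acquisition it is rendered with.
#' @param wavelength_um Spatial wavelength of the travelling wave.
#' @param head_position_px `(row, col)` anchor of the head (may be fractional).
#' @param orientation_deg Centreline angle in degrees.
#' @param head_radius_px Rendered head radius in pixels.
#' @param psf_sigma_px Gaussian blur (point-spread) width in pixels.
#' @param flagellum_intensity Peak brightness, 0-255.
#' @param background_level Background gray level, 0-255.
#' @param noise_sd Additive Gaussian noise SD in gray levels (0 = noise free).
#' @param phase Temporal phase offset (radians) at the head at t = 0.
#' @param taper Length-2 multiplier on the amplitude at the head and tail
#'   ends; `c(1, 1)` (default) is an untapered wave.
#' @param seed Integer RNG seed; with `noise_sd > 0`, frame `k` depends only
#'   on `(model, seed, k)`, so stacks are bit-reproducible.
#' @return An object of class `flagellum_model`.
#' @seealso [generate_video()], [render_frame()]
#' @export
flagellum_model <- function(length_um = 60, amplitude_um = 5,
                            beat_frequency_hz = 10, wavelength_um = 40,
                            head_position_px = c(114, 40),
                            orientation_deg = 0, head_radius_px = 3,
                            psf_sigma_px = 1.2, flagellum_intensity = 200,
                            background_level = 20, noise_sd = 2,
                            phase = 0, taper = c(1, 1), seed = 1L) {
  if (length_um <= 0) stop("length_um must be positive")
  if (amplitude_um < 0) stop("amplitude_um must be non-negative")
  if (beat_frequency_hz <= 0) stop("beat_frequency_hz must be positive")
  if (wavelength_um <= 0) stop("wavelength_um must be positive")
  if (length(head_position_px) != 2L) stop("head_position_px must be (row, col)")
  if (head_radius_px < 0 || psf_sigma_px <= 0)
    stop("head_radius_px must be >= 0 and psf_sigma_px > 0")
  if (flagellum_intensity < 0 || flagellum_intensity > 255 ||
      background_level < 0 || background_level > 255)
    stop("intensities must lie in [0, 255]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(taper) != 2L || any(taper < 0)) stop("taper must be two non-negative values")
  structure(list(length_um = length_um, amplitude_um = amplitude_um,
                 beat_frequency_hz = beat_frequency_hz,
                 wavelength_um = wavelength_um,
                 head_position_px = as.numeric(head_position_px),
                 orientation_deg = orientation_deg,
                 head_radius_px = head_radius_px,
                 psf_sigma_px = psf_sigma_px,
                 flagellum_intensity = flagellum_intensity,
                 background_level = background_level,
                 noise_sd = noise_sd, phase = phase,
                 taper = as.numeric(taper), seed = as.integer(seed)),
            class = "flagellum_model")
}

#' @export
print.flagellum_model <- function(x, ...) {
  cat("Beating-flagellum model\n")
  cat(sprintf("  length %g um, amplitude %g um, f = %g Hz, wavelength %g um\n",
              x$length_um, x$amplitude_um, x$beat_frequency_hz, x$wavelength_um))
  cat(sprintf("  head at (row %g, col %g), orientation %g deg, noise sd %g\n",
              x$head_position_px[1], x$head_position_px[2],
              x$orientation_deg, x$noise_sd))
  invisible(x)
}

# round-half-up quantization to integer gray levels
.quantize8 <- function(x) {
  storage.mode(x) <- "double"
  x[x < 0] <- 0
  x[x > 255] <- 255
  m <- floor(x + 0.5)
  storage.mode(m) <- "integer"
  m
}

# evaluate with a temporary RNG state derived from (seed, frame_index),
# restoring the caller's stream afterwards
.with_frame_seed <- function(seed, frame_index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.double(seed) * 100003 + as.double(frame_index)) %% 2147483647)
  force(expr)
}

.check_nyquist <- function(model, config) {
  if (model$beat_frequency_hz >= config$fps / 2)
    stop("beat_frequency_hz (", model$beat_frequency_hz,
         " Hz) must be below the Nyquist limit fps/2 = ", config$fps / 2, " Hz")
}

# local amplitude (px) at axial position s (px from the head)
.amp_px <- function(model, s_px, px_per_um) {
  L <- model$length_um * px_per_um
  a0 <- model$amplitude_um * px_per_um
  frac <- pmin(pmax(s_px, 0), L) / L
  a0 * (model$taper[1] + (model$taper[2] - model$taper[1]) * frac)
}

# static per-recording rendering geometry: the bounding band of pixels the
# wave can ever reach (padded by the PSF support), with cached axial (u) and
# lateral (v) pixel coordinates relative to the head anchor
.render_ctx <- function(model, config) {
  px_per_um <- config$px_per_10um / 10
  L <- model$length_um * px_per_um
  sig <- model$psf_sigma_px
  th <- model$orientation_deg * pi / 180
  ux <- cos(th); uy <- sin(th)          # axis unit vector (col, row)
  hr <- model$head_position_px[1]; hc <- model$head_position_px[2]
  s_chk <- seq(0, L, by = 0.5)
  amp_chk <- .amp_px(model, s_chk, px_per_um)
  pad <- 4 * sig + model$head_radius_px + 1
  # envelope of the midline over all phases: offset +- amp(s)
  col_env <- c(hc + ux * s_chk - uy * amp_chk, hc + ux * s_chk + uy * amp_chk)
  row_env <- c(hr + uy * s_chk + ux * amp_chk, hr + uy * s_chk - ux * amp_chk)
  r0 <- max(1L, floor(min(row_env) - pad)); r1 <- min(config$height_px, ceiling(max(row_env) + pad))
  c0 <- max(1L, floor(min(col_env) - pad)); c1 <- min(config$width_px, ceiling(max(col_env) + pad))
  if (r0 > r1 || c0 > c1)
    stop("flagellum lies entirely outside the frame (columns ",
         sprintf("%.1f..%.1f", min(col_env), max(col_env)), ", rows ",
         sprintf("%.1f..%.1f", min(row_env), max(row_env)), ")")
  rows <- r0:r1; cols <- c0:c1
  R <- matrix(rows, length(rows), length(cols))
  C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  list(px_per_um = px_per_um, L = L, sig = sig, ux = ux, uy = uy,
       hr = hr, hc = hc, rows = rows, cols = cols,
       u = (C - hc) * ux + (R - hr) * uy,
       v = (R - hr) * ux - (C - hc) * uy,
       amp = .amp_px(model, (C - hc) * ux + (R - hr) * uy, px_per_um))
}

.render_frame_ctx <- function(model, config, ctx, frame_index) {
  lam <- model$wavelength_um * ctx$px_per_um
  tt <- (frame_index - 1) / config$fps
  f <- model$beat_frequency_hz
  sig <- ctx$sig

  ph <- 2 * pi * f * tt - 2 * pi * ctx$u / lam + model$phase
  sph <- sin(ph)
  y <- ctx$amp * sph
  # slope of the midline in the (u, v) frame, for perpendicular distance
  a0 <- model$amplitude_um * ctx$px_per_um
  dyds <- (a0 * (model$taper[2] - model$taper[1]) / ctx$L) * sph -
    ctx$amp * cos(ph) * (2 * pi / lam)
  d <- (ctx$v - y) / sqrt(1 + dyds^2)
  flag <- model$flagellum_intensity * exp(-d^2 / (2 * sig^2))
  flag[abs(d) > 4 * sig | ctx$u < 0 | ctx$u > ctx$L] <- 0

  h <- config$height_px; w <- config$width_px
  img <- matrix(model$background_level, h, w)
  img[ctx$rows, ctx$cols] <- pmax(model$background_level, flag)

  # head follows the midline at s = 0, rendered on a small patch
  y0 <- .amp_px(model, 0, ctx$px_per_um) * sin(2 * pi * f * tt + model$phase)
  hd_c <- ctx$hc - ctx$uy * y0
  hd_r <- ctx$hr + ctx$ux * y0
  hpad <- model$head_radius_px + 4 * sig
  hrows <- max(1L, floor(hd_r - hpad)):min(h, ceiling(hd_r + hpad))
  hcols <- max(1L, floor(hd_c - hpad)):min(w, ceiling(hd_c + hpad))
  if (length(hrows) > 0 && length(hcols) > 0 &&
      hd_r + hpad >= 1 && hd_r - hpad <= h && hd_c + hpad >= 1 && hd_c - hpad <= w) {
    dh <- sqrt(outer((hrows - hd_r)^2, (hcols - hd_c)^2, `+`))
    head_img <- model$flagellum_intensity *
      stats::pnorm((model$head_radius_px - dh) / sig)
    head_img[dh > hpad] <- 0
    img[hrows, hcols] <- pmax(img[hrows, hcols], head_img)
  }

  if (model$noise_sd > 0)
    img <- img + .with_frame_seed(model$seed, frame_index,
                                  matrix(stats::rnorm(h * w, 0, model$noise_sd), h, w))
  .quantize8(img)
}

#' Render a single frame of a simulated flagellum recording
#'
#' Draws the travelling-wave midline as a bright curve with a Gaussian
#' cross-section of width `psf_sigma_px` (perpendicular distance, hard cutoff
#' at 4 sigma), the head as a Gaussian-blurred filled disc, on a uniform
#' background; optional i.i.d. Gaussian noise is added before clipping to
#' \[0, 255\] and round-half-up quantization. Frame `k` depicts time
#' `t = (k - 1) / fps` with no exposure integration; with noise, frame `k`
#' depends only on `(model, seed, k)`.
#'
#' @param model A [flagellum_model()].
#' @param config An [acquisition_config()].
#' @param frame_index Frame number in `1:n_frames`.
#' @return An integer matrix `height_px x width_px` of gray levels 0-255.
#' @export
render_frame <- function(model, config, frame_index) {
  stopifnot(inherits(model, "flagellum_model"),
            inherits(config, "acquisition_config"))
  .check_nyquist(model, config)
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 1L || frame_index > config$n_frames)
    stop("frame_index must lie in 1..n_frames")
  .render_frame_ctx(model, config, .render_ctx(model, config), frame_index)
}

#' Generate a simulated high-speed recording with ground truth
#'
#' Renders `n_frames` frames of the beating-flagellum model and returns the
#' stack together with a `ground_truth` object carrying the analytic midline
#' displacement. Identical `(model, config)` (including the model's `seed`)
#' yield bit-identical stacks.
#'
#' @inheritParams render_frame
#' @return A list with components `stack` (a [frame_stack()]) and
#'   `ground_truth` (class `ground_truth`).
#' @examples
#' cfg <- acquisition_config(n_frames = 30)
#' sim <- generate_video(flagellum_model(noise_sd = 0), cfg)
#' dim(sim$stack$frames)
#' @export
generate_video <- function(model, config = acquisition_config()) {
  stopifnot(inherits(model, "flagellum_model"),
            inherits(config, "acquisition_config"))
  .check_nyquist(model, config)
  ctx <- .render_ctx(model, config)
  frames <- array(0L, dim = c(config$height_px, config$width_px, config$n_frames))
  for (k in seq_len(config$n_frames))
    frames[, , k] <- .render_frame_ctx(model, config, ctx, k)
  list(stack = frame_stack(frames, fps = config$fps,
                           px_per_10um = config$px_per_10um),
       ground_truth = structure(list(model = model, config = config),
                                class = "ground_truth"))
}

#' Analytic lateral displacement of the simulated midline
#'
#' @param gt A `ground_truth` object from [generate_video()].
#' @param arc_fraction Position along the flagellum as a fraction of its
#'   length, in \[0, 1\] (0 = head).
#' @param t Time in seconds, within the recording
#'   (`0 <= t <= (n_frames - 1)/fps`).
#' @param units `"um"` (default) or `"px"`.
#' @return Lateral displacement of the midline, vectorised over `t`.
#' @export
ground_truth_displacement <- function(gt, arc_fraction, t, units = c("um", "px")) {
  stopifnot(inherits(gt, "ground_truth"))
  units <- match.arg(units)
  if (any(arc_fraction < 0 | arc_fraction > 1))
    stop("arc_fraction must lie in [0, 1]")
  dur <- (gt$config$n_frames - 1) / gt$config$fps
  if (any(t < 0 | t > dur))
    stop("t must lie within the recording duration [0, ", signif(dur, 6), "] s")
  m <- gt$model
  a_um <- m$amplitude_um *
    (m$taper[1] + (m$taper[2] - m$taper[1]) * arc_fraction)
  s_um <- arc_fraction * m$length_um
  d_um <- a_um * sin(2 * pi * m$beat_frequency_hz * t -
                       2 * pi * s_um / m$wavelength_um + m$phase)
  if (units == "um") d_um else d_um * gt$config$px_per_10um / 10
}

#' Default measurement points along a simulated flagellum
#'
#' Places points at a set of axial fractions of the flagellum, laterally
#' offset to the local peak excursion of the wave (where the passing
#' flagellum produces one intensity burst per beat cycle, so the
#' zero-crossing count of the centred intensity series equals two crossings
#' per cycle).
#'
#' @param model A [flagellum_model()].
#' @param config An [acquisition_config()].
#' @param arc_fractions Axial fractions along the flagellum; five by default.
#' @param window_radius Averaging window half-width for [extract_series()].
#' @param lateral_offset_px Lateral offset from the centreline; default
#'   (`NULL`) uses the local amplitude in pixels.
#' @return A data frame with columns `row`, `col`, `window_radius`
#'   (integer pixel coordinates).
#' @export
default_measurement_points <- function(model, config = acquisition_config(),
                                       arc_fractions = c(0.15, 0.3, 0.5, 0.7, 0.85),
                                       window_radius = 1L,
                                       lateral_offset_px = NULL) {
  stopifnot(inherits(model, "flagellum_model"),
            inherits(config, "acquisition_config"))
  px_per_um <- config$px_per_10um / 10
  s_px <- arc_fractions * model$length_um * px_per_um
  off <- if (is.null(lateral_offset_px)) .amp_px(model, s_px, px_per_um)
         else rep_len(lateral_offset_px, length(s_px))
  th <- model$orientation_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  row <- round(model$head_position_px[1] + uy * s_px + ux * off)
  col <- round(model$head_position_px[2] + ux * s_px - uy * off)
  data.frame(row = as.integer(row), col = as.integer(col),
             window_radius = as.integer(rep_len(window_radius, length(s_px))))
}
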