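#' Measurement point on the image
#'
#' A pixel location with an averaging window of half-width `window_radius`;
#' intensity at the point is the mean of the `(2r + 1)^2` window.
#'
#' @param row,col 1-based pixel coordinates.
#' @param window_radius Window half-width in pixels (0 = single pixel).
#' @return An object of class `measurement_point`.
#' @export
measurement_point <- function(row, col, window_radius = 1L) {
  row <- as.integer(row); col <- as.integer(col)
  window_radius <- as.integer(window_radius)
  if (any(is.na(c(row, col, window_radius))) || window_radius < 0L)
    stop("row, col must be integers and window_radius >= 0")
  structure(list(row = row, col = col, window_radius = window_radius),
            class = "measurement_point")
}

.as_point <- function(p) {
  if (inherits(p, "measurement_point")) return(p)
  measurement_point(p[["row"]], p[["col"]],
                    if (!is.null(p[["window_radius"]])) p[["window_radius"]] else 1L)
}

.points_list <- function(points) {
  if (is.data.frame(points)) lapply(seq_len(nrow(points)), function(i) .as_point(points[i, ]))
  else if (inherits(points, "measurement_point")) list(points)
  else lapply(points, .as_point)
}

#' Per-frame intensity time series at a measurement point
#'
#' @param stack A [frame_stack()].
#' @param point A [measurement_point()] (or a list/data-frame row with
#'   `row`, `col`, `window_radius`).
#' @return An object of class `intensity_series`: real-valued window means,
#'   one per frame (no re-quantization), with the stack's `fps`.
#' @export
extract_series <- function(stack, point) {
  stopifnot(inherits(stack, "frame_stack"))
  point <- .as_point(point)
  d <- dim(stack$frames)
  r <- point$window_radius
  rows <- (point$row - r):(point$row + r)
  cols <- (point$col - r):(point$col + r)
  if (min(rows) < 1L || max(rows) > d[1] || min(cols) < 1L || max(cols) > d[2])
    stop("measurement window at (", point$row, ", ", point$col,
         ") with radius ", r, " extends beyond the ", d[1], " x ", d[2], " frame")
  vals <- apply(stack$frames[rows, cols, , drop = FALSE], 3, mean)
  structure(list(values = as.numeric(vals), fps = stack$fps),
            class = "intensity_series")
}

#' Zero-crossing beat frequency of an intensity series
#'
#' The series is optionally smoothed with a centred moving average, centred
#' by subtracting its mean (or median), and sign changes between consecutive
#' samples are counted; a zero-valued centred sample inherits the previous
#' sign so plateaus are not double-counted. A sinusoid crosses its mean
#' twice per cycle, so the crossing count estimates the beat frequency.
#'
#' With `method = "refined"` (default) crossing times are located by linear
#' interpolation between the bracketing samples and
#' `frequency = (crossings - 1) / (2 * (t_last - t_first))`; this is exact
#' for a pure sinusoid and insensitive to the partial cycles clipped at the
#' window boundaries. `method = "count"` is the plain crossing rate
#' `crossings / (2 * duration)` with `duration = length / fps` over the
#' samples actually scanned (the moving average shortens the series by
#' `smoothing_window - 1`); the two agree within `1/(2 * duration)`.
#'
#' @param series An [extract_series()] result (or a list with `values`, `fps`).
#' @param smoothing_window Odd moving-average width in frames; 1 disables
#'   smoothing. Default 3 suppresses quantization chatter.
#' @param centering `"mean"` (default) or `"median"`.
#' @param method `"refined"` (default) or `"count"`, see above.
#' @return Beat frequency in Hz (0 for a constant series).
#' @export
beat_frequency <- function(series, smoothing_window = 3L,
                           centering = c("mean", "median"),
                           method = c("refined", "count")) {
  centering <- match.arg(centering)
  method <- match.arg(method)
  v <- as.numeric(series$values)
  fps <- series$fps
  if (length(v) < 2L) stop("series must contain at least 2 samples")
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd and >= 1")
  if (smoothing_window > 1L) {
    v <- as.numeric(stats::filter(v, rep(1 / smoothing_window, smoothing_window),
                                  sides = 2))
    v <- v[!is.na(v)]
  }
  v <- v - if (centering == "mean") mean(v) else stats::median(v)
  s <- sign(v)
  # zeros inherit the previous sign; leading zeros the first non-zero sign
  nz <- which(s != 0)
  if (length(nz) == 0L) return(0)
  if (nz[1] > 1L) s[seq_len(nz[1] - 1L)] <- s[nz[1]]
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  cross_at <- which(s[-1L] != s[-length(s)])   # between sample i and i + 1
  crossings <- length(cross_at)
  duration <- length(v) / fps
  if (method == "count" || crossings < 2L)
    return(crossings / (2 * duration))
  # sub-sample crossing times by linear interpolation
  tc <- (cross_at - 1 + v[cross_at] / (v[cross_at] - v[cross_at + 1L])) / fps
  (crossings - 1) / (2 * (tc[crossings] - tc[1L]))
}

#' Kymograph: intensity profiles along a fixed probe line over time
#'
#' For each frame, samples the intensity along a line segment of
#' `probe_length_px` samples (1 px spacing) centred on the point, at angle
#' `probe_angle_deg` (degrees from the +column axis toward +row; use 90 for
#' a vertical probe perpendicular to a horizontal flagellum). Off-grid
#' positions are bilinearly interpolated.
#'
#' @param stack A [frame_stack()].
#' @param point A [measurement_point()]; the probe centre.
#' @param probe_length_px Number of samples along the probe (>= 1).
#' @param probe_angle_deg Probe direction in degrees.
#' @return A `kymograph` object: a `probe_length_px x n_frames` matrix with
#'   attributes `fps`, `px_per_10um`.
#' @export
kymograph <- function(stack, point, probe_length_px, probe_angle_deg = 90) {
  stopifnot(inherits(stack, "frame_stack"))
  point <- .as_point(point)
  probe_length_px <- as.integer(probe_length_px)
  if (probe_length_px < 1L) stop("probe_length_px must be >= 1")
  d <- dim(stack$frames)
  a <- probe_angle_deg * pi / 180
  off <- seq_len(probe_length_px) - (probe_length_px + 1) / 2
  pr <- point$row + off * sin(a)
  pc <- point$col + off * cos(a)
  if (min(pr) < 1 || max(pr) > d[1] || min(pc) < 1 || max(pc) > d[2])
    stop("probe (rows ", sprintf("%.1f..%.1f", min(pr), max(pr)),
         ", cols ", sprintf("%.1f..%.1f", min(pc), max(pc)),
         ") exits the ", d[1], " x ", d[2], " frame")
  r0 <- floor(pr); c0 <- floor(pc)
  # clamp upper neighbours for on-boundary samples
  r1 <- pmin(r0 + 1L, d[1]); c1 <- pmin(c0 + 1L, d[2])
  wr <- pr - r0; wc <- pc - c0
  km <- matrix(0, probe_length_px, d[3])
  fr <- stack$frames
  for (i in seq_len(probe_length_px)) {
    km[i, ] <- (1 - wr[i]) * (1 - wc[i]) * fr[r0[i], c0[i], ] +
      (1 - wr[i]) * wc[i] * fr[r0[i], c1[i], ] +
      wr[i] * (1 - wc[i]) * fr[r1[i], c0[i], ] +
      wr[i] * wc[i] * fr[r1[i], c1[i], ]
  }
  structure(km, class = c("kymograph", "matrix"),
            fps = stack$fps, px_per_10um = stack$px_per_10um)
}

# sub-pixel peak of one profile: parabolic interpolation around the argmax,
# on log(intensity - baseline) where valid (exact for a Gaussian profile),
# otherwise on the raw intensities
.subpixel_peak <- function(p, baseline) {
  i0 <- which.max(p)
  if (i0 == 1L || i0 == length(p)) return(i0)
  tri <- p[(i0 - 1L):(i0 + 1L)] - baseline
  if (all(tri > 0)) tri <- log(tri) else tri <- p[(i0 - 1L):(i0 + 1L)]
  den <- tri[1] - 2 * tri[2] + tri[3]
  if (den >= 0) return(i0)
  i0 + 0.5 * (tri[1] - tri[3]) / den
}

#' Tail beat speed from a kymograph
#'
#' Tracks the flagellum crossing point as the sub-pixel peak of each frame's
#' probe profile (parabolic interpolation around the argmax) and reports the
#' mean absolute frame-to-frame displacement, calibrated to micrometres per
#' second. Frames whose profile never rises above `background + 3 * sd` are
#' considered untracked and dropped; displacement is taken only between
#' consecutive tracked frames.
#'
#' @param kymo A [kymograph()] (or plain position x time matrix).
#' @param fps Frames per second; defaults to the kymograph attribute.
#' @param px_per_10um Calibration; defaults to the kymograph attribute.
#' @return Beat speed in micrometres per second.
#' @export
beat_speed <- function(kymo, fps = attr(kymo, "fps"),
                       px_per_10um = attr(kymo, "px_per_10um")) {
  km <- unclass(kymo)
  if (!is.matrix(km) || ncol(km) < 2L)
    stop("kymograph must cover at least 2 frames")
  if (is.null(fps) || is.null(px_per_10um))
    stop("fps and px_per_10um are required")
  bg <- stats::median(km)
  sd_bg <- stats::mad(km)
  thr <- bg + 3 * sd_bg
  tracked <- apply(km, 2, max) > thr
  if (mean(tracked) < 0.5)
    stop("untrackable input: ", sum(!tracked), " of ", ncol(km),
         " frames show no peak above background + 3 sd")
  pos <- rep(NA_real_, ncol(km))
  for (j in which(tracked)) pos[j] <- .subpixel_peak(km[, j], bg)
  steps <- abs(diff(pos))
  steps <- steps[!is.na(steps)]       # only consecutive tracked pairs
  if (length(steps) == 0L) return(0)
  mean(steps) * fps * 10 / px_per_10um
}

#' Whole-field intensity index of sperm motion
#'
#' The mean absolute lag-`d` pixel brightness difference over all pixels and
#' all valid frame pairs, normalised by the brightness depth `g` and
#' expressed as a percentage:
#' \deqn{\mathrm{index} = \frac{1}{m(n-d)} \sum_{i=d+1}^{n} \sum_{j=1}^{m}
#'   \frac{|p_{ji} - p_{j,i-d}|}{g} \times 100}
#' where `n` is the frame count, `m` the pixels per frame and `p_ji` the
#' brightness of pixel `j` in frame `i`. A static scene scores 0; a
#' full-field 0/255 flicker at `d = 1` scores `100 * 255/256 = 99.609375`,
#' the attainable maximum for 8-bit input.
#'
#' @param stack A [frame_stack()].
#' @param d Frame-index lag, `1 <= d <= n - 1`. Default 1 (finest temporal
#'   resolution).
#' @param g Brightness depth; 256 for 8-bit video.
#' @return The index as a percentage in `[0, 100 * (g - 1)/g]`.
#' @export
intensity_index <- function(stack, d = 1L, g = 256) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- as.integer(d)
  n <- n_frames(stack)
  if (is.na(d) || d < 1L) stop("lag d must be a positive integer")
  if (d >= n) stop("lag d = ", d, " requires more than ", n, " frames")
  fr <- stack$frames
  total <- 0
  for (i in (d + 1L):n)
    total <- total + sum(abs(fr[, , i] - fr[, , i - d]))
  m <- pixels_per_frame(stack)
  total / (m * (n - d)) / g * 100
}

#' Motion-parameter report over a set of measurement points
#'
#' Computes the zero-crossing beat frequency and the kymograph beat speed at
#' each measurement point, the whole-stack intensity index, and the
#' across-point mean with its standard error (sample SD / sqrt(N), the
#' "mean +- SE" convention).
#'
#' @param stack A [frame_stack()].
#' @param points A data frame with columns `row`, `col`, `window_radius`
#'   (e.g. from [default_measurement_points()]) or a list of
#'   [measurement_point()]s.
#' @param d Intensity-index lag (frames).
#' @param smoothing_window Passed to [beat_frequency()].
#' @param probe_length_px,probe_angle_deg Passed to [kymograph()].
#' @return A `motion_report`: a data frame with one row per point plus one
#'   `mean` summary row (columns `point_id`, `beat_frequency_hz`,
#'   `beat_speed_um_s`), with attributes `se` (named numeric) and
#'   `intensity_index`.
#' @export
motion_report <- function(stack, points, d = 1L, smoothing_window = 3L,
                          probe_length_px = 65L, probe_angle_deg = 90) {
  pts <- .points_list(points)
  if (length(pts) < 1L) stop("at least one measurement point is required")
  freq <- speed <- numeric(length(pts))
  for (i in seq_along(pts)) {
    freq[i] <- beat_frequency(extract_series(stack, pts[[i]]),
                              smoothing_window = smoothing_window)
    speed[i] <- beat_speed(kymograph(stack, pts[[i]], probe_length_px,
                                     probe_angle_deg))
  }
  k <- length(pts)
  se <- function(x) if (k > 1) stats::sd(x) / sqrt(k) else NA_real_
  out <- data.frame(point_id = c(paste0("p", seq_len(k)), "mean"),
                    beat_frequency_hz = c(freq, mean(freq)),
                    beat_speed_um_s = c(speed, mean(speed)))
  structure(out,
            se = c(beat_frequency_hz = se(freq), beat_speed_um_s = se(speed)),
            intensity_index = intensity_index(stack, d = d),
            class = c("motion_report", "data.frame"))
}

#' @export
print.motion_report <- function(x, digits = 4, ...) {
  cat("Sperm motion parameters\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  se <- attr(x, "se")
  cat(sprintf("SE of mean: beat frequency %.4g Hz, beat speed %.4g um/s\n",
              se[["beat_frequency_hz"]], se[["beat_speed_um_s"]]))
  cat(sprintf("Intensity index: %.4g %%\n", attr(x, "intensity_index")))
  invisible(x)
}

#' Write a motion report as CSV
#'
#' Point rows first, then footer rows `mean`, `se` and `intensity_index`
#' (the latter in the `beat_frequency_hz` column slot labelled `value`).
#'
#' @param report A [motion_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_motion_report <- function(report, path) {
  stopifnot(inherits(report, "motion_report"))
  se <- attr(report, "se")
  footer <- data.frame(point_id = c("se", "intensity_index"),
                       beat_frequency_hz = c(se[["beat_frequency_hz"]],
                                             attr(report, "intensity_index")),
                       beat_speed_um_s = c(se[["beat_speed_um_s"]], NA))
  utils::write.csv(rbind(as.data.frame(report), footer), path,
                   row.names = FALSE)
  invisible(path)
}
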