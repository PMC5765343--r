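#' Frame stack container
#'
#' An ordered stack of 8-bit grayscale frames with its acquisition metadata.
#' Pixel values are integer gray levels in `[0, g - 1]` with brightness
#' depth `g = 256`.
#'
#' @param frames A `height x width x n_frames` integer array (a single
#'   matrix is promoted to a 1-frame stack), values 0-255.
#' @param fps Acquisition rate, frames per second.
#' @param px_per_10um Spatial calibration, pixels per 10 micrometres.
#' @return An object of class `frame_stack` with fields `frames`, `fps`,
#'   `px_per_10um`.
#' @export
frame_stack <- function(frames, fps = 300, px_per_10um = 28) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a height x width x n_frames array")
  if (any(is.na(frames))) stop("frames contain NA")
  if (min(frames) < 0 || max(frames) > 255)
    stop("pixel values must lie in [0, 255]")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (!is.numeric(px_per_10um) || px_per_10um <= 0)
    stop("px_per_10um must be positive")
  storage.mode(frames) <- "integer"
  structure(list(frames = frames, fps = fps, px_per_10um = px_per_10um),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Frame stack: %d frames of %d x %d px (%d px/frame)\n",
              d[3], d[1], d[2], d[1] * d[2]))
  cat(sprintf("  %g frames/s, %g px per 10 um, gray levels %d..%d\n",
              x$fps, x$px_per_10um, min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Pixels analysed per frame
#' @param stack A [frame_stack()].
#' @return Integer `height * width`.
#' @export
pixels_per_frame <- function(stack) as.integer(prod(dim(stack$frames)[1:2]))

.read_one_tiff <- function(path, rescale_16bit) {
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)  # one row per page
  bps_all <- info$bits.per.sample
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L)
      stop("frame ", i, " in ", path, " is not single-channel grayscale")
    bps <- bps_all[min(i, length(bps_all))]
    if (!is.null(bps) && bps > 8) {
      if (!rescale_16bit)
        stop("frame ", i, " in ", path, " is ", bps,
             "-bit; pass rescale_16bit = TRUE to rescale to 8 bits")
      pg <- floor(pg / 2^(bps - 8))
    }
    storage.mode(pg) <- "integer"
    pg
  })
}

.read_one_png <- function(path) {
  pg <- png::readPNG(path)
  if (length(dim(pg)) == 3L) {
    if (dim(pg)[3] == 2L) pg <- pg[, , 1L]  # gray + alpha
    else stop("PNG frame ", basename(path), " is not single-channel grayscale")
  }
  m <- floor(pg * 255 + 0.5)
  storage.mode(m) <- "integer"
  m
}

#' Read a frame stack from disk
#'
#' Accepts either a multi-page grayscale TIFF or a directory of
#' lexicographically ordered single-frame image files (TIFF or PNG).
#' Calibration is never inferred from image headers: pass it explicitly or
#' via a sidecar config read with [read_calibration()].
#'
#' @param path Path to a TIFF file or a frame directory.
#' @param fps Acquisition rate (frames/s).
#' @param px_per_10um Spatial calibration.
#' @param rescale_16bit If `TRUE`, 16-bit TIFF input is rescaled to 8 bits;
#'   otherwise such input is rejected.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, fps = 300, px_per_10um = 28, rescale_16bit = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no frame files found in ", path)
    pages <- unlist(lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) list(.read_one_png(f))
      else .read_one_tiff(f, rescale_16bit)
    }), recursive = FALSE)
  } else if (file.exists(path)) {
    pages <- .read_one_tiff(path, rescale_16bit)
  } else stop("no such file or directory: ", path)
  if (length(pages) == 0L) stop("empty stack: ", path)
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), d1))
      stop("frame ", i, " has shape ", paste(dim(pages[[i]]), collapse = " x "),
           ", expected ", paste(d1, collapse = " x "))
  frames <- array(unlist(pages), dim = c(d1, length(pages)))
  frame_stack(frames, fps = fps, px_per_10um = px_per_10um)
}

#' Write a frame stack as a multi-page 8-bit grayscale TIFF
#'
#' Lossless (deflate-compressed) 8-bit output; a written stack reloads
#' bit-identically.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @param compression `"deflate"` (default) or `"none"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, compression = c("deflate", "none")) {
  stopifnot(inherits(stack, "frame_stack"))
  compression <- match.arg(compression)
  pages <- lapply(seq_len(n_frames(stack)),
                  function(k) stack$frames[, , k] / 255)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                        compression = compression, reduce = TRUE)
  if (!isTRUE(ok > 0)) stop("failed to write TIFF to ", path)
  invisible(path)
}

#' Read / write a plain-text calibration sidecar
#'
#' Calibration (keys `fps`, `px_per_10um`, `bit_depth`) lives in a YAML
#' sidecar next to the pixel data rather than in TIFF tags.
#'
#' @param path Config file path.
#' @return For `read_calibration`, a list with `fps`, `px_per_10um` and
#'   `bit_depth`.
#' @export
read_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(fps = cfg$fps %||% 300,
              px_per_10um = cfg$px_per_10um %||% 28,
              bit_depth = cfg$bit_depth %||% 8)
  if (out$fps <= 0 || out$px_per_10um <= 0) stop("invalid calibration in ", path)
  out
}

#' @rdname read_calibration
#' @param fps,px_per_10um,bit_depth Values to store.
#' @export
write_calibration <- function(path, fps = 300, px_per_10um = 28, bit_depth = 8) {
  yaml::write_yaml(list(fps = fps, px_per_10um = px_per_10um,
                        bit_depth = bit_depth), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert pixel distances to micrometres
#'
#' `um = px * 10 / px_per_10um` (10/28 micrometres per pixel at the default
#' calibration).
#'
#' @param px Distance in pixels.
#' @param px_per_10um Pixels per 10 micrometres.
#' @return Distance in micrometres.
#' @export
px_to_um <- function(px, px_per_10um = 28) px * 10 / px_per_10um
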