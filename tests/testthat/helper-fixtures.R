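# compact acquisition + model for fast unit tests (the acceptance suite uses
# the full default geometry)
small_config <- function(n_frames = 60L, fps = 300) {
  acquisition_config(height_px = 64L, width_px = 96L, fps = fps,
                     n_frames = n_frames, px_per_10um = 28)
}

small_model <- function(beat_frequency_hz = 10, amplitude_um = 3,
                        noise_sd = 0, ...) {
  flagellum_model(length_um = 25, amplitude_um = amplitude_um,
                  beat_frequency_hz = beat_frequency_hz, wavelength_um = 18,
                  head_position_px = c(32, 10), noise_sd = noise_sd, ...)
}

# uniform-random 8-bit stack
random_stack <- function(h = 8, w = 8, n = 20, fps = 300) {
  frame_stack(array(sample(0:255, h * w * n, replace = TRUE), c(h, w, n)),
              fps = fps)
}

# literal transcription of the intensity-index formula (triple loop),
# independent of the vectorised implementation
intensity_index_loop <- function(stack, d = 1, g = 256) {
  fr <- stack$frames
  n <- dim(fr)[3]
  hh <- dim(fr)[1]; ww <- dim(fr)[2]
  acc <- 0
  for (i in (d + 1):n)
    for (r in 1:hh)
      for (c in 1:ww)
        acc <- acc + abs(fr[r, c, i] - fr[r, c, i - d]) / g
  acc / ((hh * ww) * (n - d)) * 100
}

# tie-free integer samples realising a given first-group U statistic
samples_with_u <- function(W, n1, n2) {
  N <- n1 + n2
  p <- seq_len(n1)
  excess <- W
  for (i in n1:1) {
    up <- min(excess, N - (n1 - i) - p[i])
    p[i] <- p[i] + up
    excess <- excess - up
  }
  stopifnot(excess == 0)
  list(x = p, y = setdiff(seq_len(N), p))
}

# exact U pmf by complete enumeration of all label assignments
u_pmf_enumerated <- function(n1, n2) {
  N <- n1 + n2
  idx <- utils::combn(N, n1)
  u <- colSums(matrix(seq_len(N)[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  tab <- table(factor(u, levels = 0:(n1 * n2)))
  as.numeric(tab) / ncol(idx)
}
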