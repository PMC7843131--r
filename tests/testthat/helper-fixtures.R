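# Small deterministic fixtures shared across test files.

# smooth band-limited random field in 0..255
smooth_field <- function(n = 240, sigma = 4, seed = 3) {
  set.seed(seed)
  img <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n), sigma = sigma)
  (img - min(img)) / diff(range(img)) * 255
}

# constant-value stack for mux round trips: frame j of sample i carries
# the literal value i * 1000 + j in every pixel
coded_stacks <- function(ids, n_frames, dim_px = c(4, 4), fps = 10) {
  stacks <- lapply(seq_along(ids), function(i) {
    arr <- array(0, dim = c(dim_px, n_frames))
    for (j in seq_len(n_frames)) arr[, , j] <- i * 1000 + j
    frame_stack(arr, fps = fps, sample_id = ids[i])
  })
  names(stacks) <- ids
  stacks
}

# closed-form intensity of a periodic opaque-bar target convolved with a
# Gaussian PSF: independent oracle for the psfcal forward model
oracle_grid_contrast <- function(fwhm, line_width = 20, period = 40) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  k <- -80:80
  intensity <- function(x) {
    1 - sum(stats::pnorm((x - (k * period - line_width / 2)) / s) -
            stats::pnorm((x - (k * period + line_width / 2)) / s))
  }
  intensity(period / 2) / intensity(0)
}
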