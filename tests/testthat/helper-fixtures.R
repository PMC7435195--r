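# Shared fixtures, all generated in code.

# Pixel-coordinate grids (0-based, x along columns).
grid_x <- function(n) matrix(0:(n - 1), n, n, byrow = TRUE)
grid_y <- function(n) matrix(0:(n - 1), n, n)

# Pure cosine carrier along x.
carrier <- function(n, period) cos(2 * pi * grid_x(n) / period)

# Interior RMS between two rasters.
rms_in <- function(a, b, border = 16) {
  m <- interior_mask(dim(a), border)
  sqrt(mean((a - b)[m]^2))
}

# Concentric-fringe phantom phase (radial quadratic, carrier-free).
concentric_phase <- function(n, c = 1.5e-3) {
  c0 <- (n - 1) / 2
  c * ((grid_x(n) - c0)^2 + (grid_y(n) - c0)^2)
}

# Compact-cell phantom for aberration tests: the cell occupies ~32 px of
# the field (small object in a wide field, as in dynamic-cell imaging).
compact_cell_phase <- function(n) {
  rbc_phase(n, synthetic_spec(size = n, period = 20, noise_amp = 0,
                              background = "none"),
            rbc_params(pixel_pitch = 7.82 / 32))
}
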