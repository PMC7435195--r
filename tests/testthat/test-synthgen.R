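test_that("rbc_height matches the closed form at the centre, rim and outside", {
  expect_equal(rbc_height(0, 0), 7.82 * 0.0518, tolerance = 1e-12)
  expect_equal(rbc_height(7.82 / 2, 0), 0)
  expect_equal(rbc_height(0, 7.82 / 2), 0)
  expect_equal(rbc_height(5, 5), 0)   # r > D0/2, outside the support disk
  expect_error(rbc_height(NaN, 0), "finite")
  expect_error(rbc_params(D0 = -1), "positive")
})

test_that("rbc_height is non-negative over its support", {
  s <- seq(-3.91, 3.91, length.out = 1024)
  z <- rbc_height(rep(s, each = 32), rep(seq(-3.9, 3.9, length.out = 32), 1024))
  expect_true(all(z >= 0))
})

test_that("rbc_phase samples phase_scale * z on the grid", {
  n <- 64
  pitch <- 7.82 / 1024
  # put the cell centre exactly on a pixel so the centre value is exact
  pr <- rbc_params(pixel_pitch = pitch, center = c(32 * pitch, 32 * pitch))
  sp <- synthetic_spec(size = n, period = 20)
  ph <- rbc_phase(n, sp, pr)
  expect_equal(ph[33, 33], 5 * 7.82 * 0.0518, tolerance = 1e-10)
  sp0 <- synthetic_spec(size = n, period = 20, phase_scale = 0)
  expect_true(all(rbc_phase(n, sp0) == 0))
  # radial symmetry about the (default) centre
  ph2 <- rbc_phase(n, sp)
  expect_lt(max(abs(ph2 - t(ph2))), 1e-10)
  expect_lt(max(abs(ph2 - ph2[n:1, n:1])), 1e-10)
  expect_error(rbc_phase(16, sp), "at least 32")
})

test_that("generate_interferogram composes the fringe model exactly", {
  n <- 64
  sp <- synthetic_spec(size = n, period = 8, noise_amp = 0, background = "none")
  ig <- generate_interferogram(sp, matrix(0, n, n))
  expect_identical(ig$interferogram,
                   with(ig$model, background + fringes + noise))
  expect_true(all(abs(ig$interferogram) <= 1))
  # period-8 columns: column j and j+8 identical
  expect_equal(ig$interferogram[, 1], ig$interferogram[, 9])
  expect_equal(ig$interferogram[1, 1], 1)   # cos(0)
  sp2 <- synthetic_spec(size = n, period = 8, noise_amp = 0.05, seed = 11)
  ig2 <- generate_interferogram(sp2, matrix(0, n, n))
  expect_lt(max(abs(ig2$interferogram -
                      with(ig2$model, background + fringes + noise))), 1e-12)
})

test_that("carrier below the Nyquist floor is rejected, Inf is carrier-free", {
  expect_error(synthetic_spec(period = 3.5), "Nyquist")
  n <- 64
  spInf <- synthetic_spec(size = n, period = Inf, noise_amp = 0,
                          background = "none")
  ig <- generate_interferogram(spInf, matrix(0, n, n))
  expect_true(all(ig$interferogram == 1))   # cos(0) everywhere
})

test_that("seeded noise is reproducible and has the declared amplitude", {
  sp <- synthetic_spec(size = 512, period = 20, noise_amp = 0.05, seed = 4)
  ph <- matrix(0, 512, 512)
  a <- generate_interferogram(sp, ph)
  b <- generate_interferogram(sp, ph)
  expect_identical(a$interferogram, b$interferogram)
  s <- sd(as.numeric(a$model$noise))
  expect_gt(s, 0.0495)
  expect_lt(s, 0.0505)
  # the generator must not disturb the global RNG stream
  set.seed(123); r1 <- rnorm(3)
  set.seed(123); invisible(generate_interferogram(sp, ph)); r2 <- rnorm(3)
  expect_identical(r1, r2)
})

test_that("ideal_direction returns the analytic fringe normal", {
  n <- 64
  sp <- synthetic_spec(size = n, period = 16)
  b <- ideal_direction(sp, matrix(0, n, n))
  m <- interior_mask(c(n, n), 4)
  expect_lt(max(abs(b[m])), 1e-6)          # carrier along +x
  # carrier along y, expressed through the phase argument
  spInf <- synthetic_spec(size = n, period = Inf)
  by <- ideal_direction(spInf, 2 * pi * grid_y(n) / 16)
  expect_lt(max(abs(by[m] - pi / 2)), 1e-6)
  # radial phantom: beta = atan2(y, x) mod 2pi
  c0 <- (n - 1) / 2
  br <- ideal_direction(spInf, 0.01 * ((grid_x(n) - c0)^2 + (grid_y(n) - c0)^2))
  ref <- (atan2(grid_y(n) - c0, grid_x(n) - c0)) %% (2 * pi)
  expect_lt(circular_rms(br, ref, interior_mask(c(n, n), 4,
                                                disk_center = c(c0 + 1, c0 + 1),
                                                disk_radius = 6)), 0.05)
  expect_true(all(b >= 0 & b < 2 * pi))
})

test_that("aberration_background evaluates low-order polynomials", {
  n <- 64
  expect_true(all(aberration_background(n, matrix(0, 3, 3)) == 0))
  expect_true(all(aberration_background(n, matrix(2, 1, 1)) == 2))
  cf <- matrix(0, 3, 3); cf[3, 1] <- 1; cf[1, 3] <- -1
  saddle <- aberration_background(n, cf)
  expect_lt(abs(mean(saddle)), 1e-12)      # zero mean on symmetric grid
  expect_error(aberration_background(n, matrix(0, 6, 6)), "order")
})
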