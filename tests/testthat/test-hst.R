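test_that("spiral phase function has the declared values and unit modulus", {
  spf <- spiral_phase_function(c(64, 64))
  expect_equal(spf[1, 2], 1 + 0i)     # (u, v) = (1, 0)
  expect_equal(spf[2, 1], 0 + 1i)     # (u, v) = (0, 1)
  expect_equal(spf[1, 1], 0 + 0i)     # DC nulled
  expect_equal(spf[1, 64], -1 + 0i)   # (u, v) = (-1, 0)
  mods <- Mod(spf[-1])
  expect_lt(max(abs(mods - 1)), 1e-12)
  expect_error(spiral_phase_function(c(1, 5)), "2x2")
})

test_that("spiral transform produces the quadrature of a carrier", {
  n <- 256
  f <- carrier(n, 16)
  q <- hilbert_spiral_transform(f, matrix(0, n, n))
  expect_lt(rms_in(q, sin(2 * pi * grid_x(n) / 16)), 0.05)
  expect_true(all(hilbert_spiral_transform(matrix(0, n, n),
                                           matrix(0, n, n)) == 0))
  # beta + pi negates the quadrature
  q2 <- hilbert_spiral_transform(f, matrix(pi, n, n))
  expect_lt(max(abs(q2 + q)), 1e-6)
  expect_error(hilbert_spiral_transform(f, matrix(0, 8, 8)), "shape")
})

test_that("spiral transform is linear and involutive on carriers", {
  n <- 128
  f <- carrier(n, 16)
  b0 <- matrix(0, n, n)
  expect_lt(max(abs(hilbert_spiral_transform(3 * f, b0) -
                      3 * hilbert_spiral_transform(f, b0))), 1e-10)
  qq <- hilbert_spiral_transform(hilbert_spiral_transform(f, b0), b0)
  expect_lt(rms_in(qq, -f), 0.05)
})

test_that("unit-modulus multiplier preserves spectral energy", {
  n <- 64
  f <- carrier(n, 16); f <- f - mean(f)
  spf <- spiral_phase_function(c(n, n))
  Ff <- fft(f)
  expect_lt(abs(sum(Mod(spf * Ff)^2) - sum(Mod(Ff)^2)) / sum(Mod(Ff)^2),
            1e-10)
})

test_that("analytic signal wraps fringes and quadrature coherently", {
  n <- 256
  f <- carrier(n, 16)
  afp <- analytic_signal(f, matrix(0, n, n))
  expect_identical(Re(afp$afp), f)
  m <- interior_mask(c(n, n), 16)
  expect_lt(max(abs(Mod(afp$afp)[m] - 1)), 0.05)
  w <- wrapped_phase(afp)
  ref <- (2 * pi * grid_x(n) / 16 + pi) %% (2 * pi) - pi
  d <- abs((w - ref + pi) %% (2 * pi) - pi)
  expect_lt(max(d[m]), 0.05)
})

test_that("wrapped_phase obeys the (-pi, pi] convention", {
  z <- matrix(c(1 + 0i, 0 + 1i, -1 + 0i, 0 + 0i), 2, 2)
  w <- wrapped_phase(z)
  expect_equal(w[1, 1], 0)
  expect_equal(w[2, 1], pi / 2)
  expect_equal(w[1, 2], pi)            # -1 maps to +pi, not -pi
  expect_equal(w[2, 2], 0)             # zero magnitude, flagged
  expect_true(attr(w, "degenerate")[2, 2])
  expect_true(all(w > -pi & w <= pi))
})

test_that("unwrap_phase is exact on ramps and always congruent", {
  n <- 128
  ramp <- 2 * pi * grid_x(n) / 16
  w <- (ramp + pi) %% (2 * pi) - pi
  u <- unwrap_phase(w)
  expect_lt(max(abs(u - ramp - (u[1, 1] - ramp[1, 1]))), 1e-6)
  expect_equal(attr(u, "residues"), 0L)
  const <- matrix(0.7, n, n)
  expect_equal(unwrap_phase(const)[1, ], rep(0.7, n))
  # rewrap invariant on a residue-rich noisy field
  set.seed(3)
  wn <- (matrix(rnorm(n * n, sd = 2), n) + pi) %% (2 * pi) - pi
  un <- unwrap_phase(wn)
  frac <- ((un - wn) / (2 * pi) + 0.5) %% 1 - 0.5
  expect_lt(max(abs(frac)), 1e-6)
})

test_that("remove_plane subtracts exactly the least-squares plane", {
  n <- 64
  plane <- 3 + 0.1 * grid_x(n) - 0.2 * grid_y(n)
  out <- remove_plane(plane)
  expect_lt(max(abs(out)), 1e-9)
  ph <- compact_cell_phase(n)
  rec <- remove_plane(ph + plane)
  expect_lt(max(abs(rec - remove_plane(ph))), 1e-9)
  expect_lt(max(abs(remove_plane(out) - out)), 1e-12)   # idempotent
})

test_that("Fourier-transform demodulation works off-axis and fails at DC", {
  n <- 256
  sp <- synthetic_spec(size = n, period = 8, noise_amp = 0,
                       background = "gaussian")
  ph <- rbc_phase(n, sp)
  ig <- generate_interferogram(sp, ph)
  ftp <- ft_demodulate(ig$interferogram, filter_center = c(n / 8, 0))
  expect_lt(rms_error(ftp, ph, interior_mask(c(n, n), 16)), 0.15)
  # pure carrier maps to the removed plane
  ig0 <- generate_interferogram(
    synthetic_spec(size = n, period = 8, noise_amp = 0, background = "none"),
    matrix(0, n, n))
  f0 <- ft_demodulate(ig0$interferogram, filter_center = c(n / 8, 0))
  expect_lt(sqrt(mean(f0[interior_mask(c(n, n), 16)]^2)), 0.02)
  # carrier-free input with a DC-centred filter: documented failure mode
  spc <- synthetic_spec(size = n, period = Inf, noise_amp = 0,
                        background = "none")
  igc <- generate_interferogram(spc, rbc_phase(n, spc))
  expect_warning(pc <- ft_demodulate(igc$interferogram,
                                     filter_center = c(0, 0),
                                     filter_radius = 10),
                 "autocorrelation")
  expect_gt(rms_error(pc, rbc_phase(n, spc), interior_mask(c(n, n), 16)), 1)
})
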