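test_that("denoise splits additively and respects its backends", {
  n <- 64
  const <- matrix(3.5, n, n)
  d <- denoise(const)
  expect_equal(d$denoised, const)
  expect_true(all(d$noise == 0))
  img <- carrier(n, 8)
  d0 <- denoise(img, method = "none")
  expect_identical(d0$denoised, img)
  expect_error(denoise(img, method = "bm3d"), "wavelet")
  set.seed(5)
  noisy <- img + 0.05 * matrix(rnorm(n * n), n)
  dn <- denoise(noisy)
  expect_lt(max(abs(dn$denoised + dn$noise - noisy)), 1e-12)
  expect_gt(cor(as.numeric(dn$denoised), as.numeric(img)),
            cor(as.numeric(noisy), as.numeric(img)))
})

test_that("noise sd estimate recovers the injected level", {
  set.seed(8)
  x <- carrier(256, 16) + 0.05 * matrix(rnorm(256^2), 256)
  expect_equal(estimate_noise_sd(x), 0.05, tolerance = 0.15)
})

test_that("structure_texture separates a smooth bump from fringes", {
  n <- 128
  const <- matrix(2, n, n)
  st <- structure_texture(const)
  expect_lt(max(abs(st$texture)), 1e-10)
  bump <- 1.5 * exp(-((grid_x(n) - 64)^2 + (grid_y(n) - 64)^2) / (2 * 40^2))
  f <- carrier(n, 8)
  st2 <- structure_texture(bump + f)
  expect_lt(max(abs(st2$structure + st2$texture - (bump + f))), 1e-10)
  m <- interior_mask(c(n, n), 8)
  expect_gt(cor(st2$texture[m], f[m]), 0.9)
  expect_gt(cor(st2$structure[m], bump[m]), 0.9)
  expect_gte(st2$NI, 1)
  expect_error(structure_texture(matrix(1, 8, 8)), "16x16")
})

test_that("auto_stop returns the first sub-tolerance iteration", {
  expect_equal(auto_stop(rep(0, 10)), 1)
  hist <- 0.5^(0:19)                      # crosses 1e-3 at index 11
  expect_equal(auto_stop(hist, tol = 1e-3), 11)
  expect_equal(auto_stop(rep(0.5, 7), tol = 1e-3), 7)
  expect_equal(auto_stop(rep(0.5, 7), tol = 1e-3, max_iters = 50), 50)
  expect_error(auto_stop(numeric(0)), "empty")
})

test_that("uvid_filter satisfies the decomposition contract", {
  n <- 128
  sp <- synthetic_spec(size = n, period = 20, noise_amp = 0.05, seed = 2)
  ph <- rbc_phase(n, sp)
  ig <- generate_interferogram(sp, ph)
  dec <- uvid_filter(ig$interferogram)
  expect_s3_class(dec, "uvid_decomposition")
  # exact additivity
  expect_lt(max(abs(dec$background + dec$fringes + dec$noise -
                      ig$interferogram)), 1e-12)
  # zero-mean fringes relative to the dynamic range
  expect_lt(abs(mean(dec$fringes)),
            1e-3 * diff(range(ig$interferogram)))
  # closer to the true fringe term than the raw input is
  truth <- ig$model$fringes
  expect_lt(rms_in(dec$fringes, truth), rms_in(ig$interferogram, truth))
  expect_identical(dec$params, c(mu = 100, tau = 0.25))
  expect_error(uvid_filter(matrix(1, 16, 16)), "32x32")
})

test_that("clean background-free carrier leaves almost nothing in the structure", {
  n <- 128
  sp <- synthetic_spec(size = n, period = 8, noise_amp = 0, background = "none")
  ig <- generate_interferogram(sp, matrix(0, n, n))
  dec <- uvid_filter(ig$interferogram)
  expect_lt(sqrt(mean(dec$background^2)), 0.05)  # fringe amplitude is 1
})

test_that("re-filtering its own fringe output is nearly idempotent", {
  n <- 128
  sp <- synthetic_spec(size = n, period = 20, noise_amp = 0.05, seed = 2)
  ig <- generate_interferogram(sp, rbc_phase(n, sp))
  dec <- uvid_filter(ig$interferogram)
  dec2 <- uvid_filter(dec$fringes)
  rel <- sqrt(mean((dec2$fringes - dec$fringes)^2)) /
    sqrt(mean(dec$fringes^2))
  expect_lt(rel, 0.1)
})

test_that("extracted background is low-pass relative to the carrier", {
  n <- 256
  for (T in c(8, 20, 60)) {
    sp <- synthetic_spec(size = n, period = T, noise_amp = 0.05, seed = 2)
    ig <- generate_interferogram(sp, rbc_phase(n, sp))
    dec <- uvid_filter(ig$interferogram)
    F <- fft(dec$background)
    u <- matrix(vhqpi:::fft_freq(n), n, n, byrow = TRUE)
    v <- matrix(vhqpi:::fft_freq(n), n, n)
    hi <- sqrt(u^2 + v^2) >= n / T
    expect_lt(sum(Mod(F[hi])^2) / sum(Mod(F)^2), 0.1)
  }
})
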