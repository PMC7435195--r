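# Synthetic interferogram generator: red-blood-cell phantom, carrier
# fringes, Gaussian background, seeded noise, ideal direction maps and
# polynomial aberration backgrounds.  Everything downstream is testable
# against these analytic fixtures.

#' Red blood cell phantom parameters
#'
#' Parameters of the Evans--Skalak closed-form model of the unstressed
#' erythrocyte thickness profile. The defaults are the experimentally
#' derived constants of that model: average cell diameter
#' `D0 = 7.82` micrometres and shape constants `a0 = 0.0518`,
#' `a1 = 2.0026`, `a2 = -4.491`.
#'
#' @param D0 cell diameter, micrometres; must be positive.
#' @param a0,a1,a2 dimensionless shape constants.
#' @param pixel_pitch micrometres per pixel used when the cell is sampled
#'   on a raster grid. The default (`D0/1024`) images the central region
#'   of the cell at high magnification — the cell diameter is twice a
#'   512-pixel field — so that every visible phase gradient of the `5 z`
#'   object stays below the weakest carrier of the 4--150 px period range
#'   (no fringe reversal anywhere in view; the divergent-slope rim of the
#'   profile lies outside the raster). Set a larger pitch explicitly to
#'   image the whole cell including its rim.
#' @param center cell centre `c(x, y)` in micrometres; `NULL` centres the
#'   cell on the raster.
#' @return an object of class `rbc_params`.
#' @export
rbc_params <- function(D0 = 7.82, a0 = 0.0518, a1 = 2.0026, a2 = -4.491,
                       pixel_pitch = 7.82 / 1024, center = NULL) {
  if (!is.finite(D0) || D0 <= 0) stop("D0 must be a positive finite diameter")
  structure(list(D0 = D0, a0 = a0, a1 = a1, a2 = a2,
                 pixel_pitch = pixel_pitch, center = center),
            class = "rbc_params")
}

#' Evans--Skalak red blood cell height profile
#'
#' Evaluates the closed-form biconcave thickness profile
#' \deqn{z = D_0 \sqrt{1 - 4 r^2 / D_0^2}\,
#'   \left(a_0 + a_1 r^2 / D_0^2 + a_2 r^4 / D_0^4\right),}
#' with \eqn{r^2 = x^2 + y^2}. Outside the support disk
#' \eqn{r > D_0/2} the square root turns imaginary; by convention the
#' height is zero there (the cell rests on a flat substrate), which keeps
#' the phantom real and continuous.
#'
#' @param x,y coordinates in micrometres (vectorised, recycled).
#' @param params an [rbc_params()] object.
#' @return height in micrometres, same shape as `x`.
#' @examples
#' rbc_height(0, 0, rbc_params())  # D0 * a0 = 0.405
#' @export
rbc_height <- function(x, y, params = rbc_params()) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite")
  r2 <- (x^2 + y^2) / params$D0^2          # r^2 / D0^2
  inside <- r2 <= 0.25
  z <- x * 0
  u <- r2[inside]
  z[inside] <- params$D0 * sqrt(pmax(1 - 4 * u, 0)) *
    (params$a0 + params$a1 * u + params$a2 * u^2)
  z
}

#' Synthetic interferogram specification
#'
#' Describes one synthetic interferogram: raster size, carrier period,
#' the multiplier converting cell height to phase, noise level,
#' background model and random seed. The composed intensity follows
#' `I = a + cos(phase + 2*pi*x/T) + noise_amp * G` with `G` a seeded
#' standard-normal raster.
#'
#' @param size raster side, pixels.
#' @param period carrier fringe period `T` in pixels; `Inf` means
#'   carrier-free (closed fringes only). Finite periods below 4 px are
#'   rejected as beyond the Nyquist-safe floor.
#' @param phase_scale multiplier applied to the phantom height (default 5,
#'   giving a peak object phase of a few radians for the default cell).
#' @param noise_amp standard deviation of the additive Gaussian noise in
#'   intensity units (default 0.05).
#' @param background `"gaussian"` (amplitude `bg_amplitude`, standard
#'   deviation `bg_sigma` pixels, centred) or `"none"`.
#' @param bg_amplitude,bg_sigma Gaussian background shape; defaults are
#'   amplitude 1 and `size/3`.
#' @param seed integer seed; fully determines the noise raster.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = 512, period = 20, phase_scale = 5,
                           noise_amp = 0.05,
                           background = c("gaussian", "none"),
                           bg_amplitude = 1, bg_sigma = size / 3,
                           seed = 1L) {
  background <- match.arg(background)
  if (is.finite(period) && period < 4)
    stop("carrier beyond Nyquist floor: period must be >= 4 px (or Inf)")
  if (size < 32) stop("size must be at least 32 px")
  structure(list(size = as.integer(size), period = period,
                 phase_scale = phase_scale, noise_amp = noise_amp,
                 background = background, bg_amplitude = bg_amplitude,
                 bg_sigma = bg_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Pixel coordinate grids, 0-based: x = column index, y = row index.
pixel_grid <- function(n) {
  list(x = matrix(0:(n - 1), n, n, byrow = TRUE),
       y = matrix(0:(n - 1), n, n))
}

#' Sample the red blood cell phase on a pixel grid
#'
#' Returns `phase_scale * z` sampled on a `grid_size` x `grid_size` raster,
#' where `z` is the [rbc_height()] profile. Pixel coordinates map to
#' micrometres through `params$pixel_pitch`, and the cell is centred on
#' the raster unless `params$center` says otherwise.
#'
#' @param grid_size raster side, pixels (at least 32).
#' @param spec a [synthetic_spec()]; supplies `phase_scale`.
#' @param params an [rbc_params()].
#' @return phase raster in radians.
#' @export
rbc_phase <- function(grid_size = spec$size, spec = synthetic_spec(),
                      params = rbc_params()) {
  if (grid_size < 32) stop("grid_size must be at least 32")
  g <- pixel_grid(grid_size)
  pitch <- params$pixel_pitch
  center <- params$center
  if (is.null(center)) center <- rep(((grid_size - 1) / 2) * pitch, 2)
  z <- rbc_height(g$x * pitch - center[1], g$y * pitch - center[2], params)
  spec$phase_scale * z
}

gaussian_background <- function(n, amplitude, sigma) {
  g <- pixel_grid(n)
  c0 <- (n - 1) / 2
  amplitude * exp(-(((g$x - c0)^2 + (g$y - c0)^2) / (2 * sigma^2)))
}

#' Compose a synthetic interferogram
#'
#' Builds `I = a + cos(phase + 2*pi*x/T) + noise_amp * G` and returns both
#' the composed intensity and its exact ground-truth decomposition (the
#' additive fringe model `a + b cos(theta) + n` with `b = 1`). The same
#' seed always reproduces the identical raster.
#'
#' @param spec a [synthetic_spec()].
#' @param phase object phase raster in radians, `spec$size` square;
#'   defaults to the red blood cell phantom.
#' @return a list with components `interferogram` (intensity raster) and
#'   `model` (class `fringe_model`: `background`, `amplitude`, `phase`
#'   (total phase theta including the carrier), `fringes`, `noise`).
#' @export
generate_interferogram <- function(spec = synthetic_spec(),
                                   phase = rbc_phase(spec = spec)) {
  n <- spec$size
  if (!is.matrix(phase) || any(dim(phase) != n))
    stop("phase raster does not match spec$size")
  if (is.finite(spec$period) && spec$period < 4)
    stop("carrier beyond Nyquist floor")
  g <- pixel_grid(n)
  carrier <- if (is.finite(spec$period)) 2 * pi * g$x / spec$period else 0
  theta <- phase + carrier
  a <- if (spec$background == "gaussian")
    gaussian_background(n, spec$bg_amplitude, spec$bg_sigma)
  else matrix(0, n, n)
  noise <- if (spec$noise_amp > 0)
    spec$noise_amp * with_seed(spec$seed, matrix(rnorm(n * n), n, n))
  else matrix(0, n, n)
  fringes <- cos(theta)
  model <- structure(list(background = a, amplitude = matrix(1, n, n),
                          phase = theta, fringes = fringes, noise = noise),
                     class = "fringe_model")
  list(interferogram = a + fringes + noise, model = model)
}

#' Ideal fringe direction map of a synthetic interferogram
#'
#' The reference direction map used to validate the estimated one:
#' `beta = atan2(d theta/dy, d theta/dx) mod 2*pi`, the angle between the
#' local fringe normal and the OX axis, computed by central finite
#' differences of the known total phase `theta = phase + 2*pi*x/T`.
#' Pixels with vanishing gradient take the value of their nearest valid
#' neighbour and are flagged in the `validity` attribute.
#'
#' @param spec a [synthetic_spec()] (supplies the carrier).
#' @param phase object phase raster, radians.
#' @return direction raster in `[0, 2*pi)` with a logical `validity`
#'   attribute.
#' @export
ideal_direction <- function(spec, phase) {
  n <- spec$size
  g <- pixel_grid(n)
  carrier <- if (is.finite(spec$period)) 2 * pi * g$x / spec$period else 0
  theta <- phase + carrier
  gr <- raster_gradient(theta)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  valid <- mag > 1e-12
  beta <- wrap_2pi(atan2(gr$gy, gr$gx))
  if (!all(valid)) beta <- fill_nearest(beta, valid)
  attr(beta, "validity") <- valid
  beta
}

# Replace invalid pixels by the value of the nearest valid pixel
# (iterative 4-neighbour dilation; adequate for the small invalid sets
# this package produces).
fill_nearest <- function(x, valid) {
  nr <- nrow(x); nc <- ncol(x)
  while (!all(valid)) {
    shifted <- list(
      rbind(x[1, , drop = FALSE], x[-nr, , drop = FALSE]),
      rbind(x[-1, , drop = FALSE], x[nr, , drop = FALSE]),
      cbind(x[, 1, drop = FALSE], x[, -nc, drop = FALSE]),
      cbind(x[, -1, drop = FALSE], x[, nc, drop = FALSE]))
    vshift <- list(
      rbind(valid[1, , drop = FALSE], valid[-nr, , drop = FALSE]),
      rbind(valid[-1, , drop = FALSE], valid[nr, , drop = FALSE]),
      cbind(valid[, 1, drop = FALSE], valid[, -nc, drop = FALSE]),
      cbind(valid[, -1, drop = FALSE], valid[, nc, drop = FALSE]))
    newly <- !valid & (vshift[[1]] | vshift[[2]] | vshift[[3]] | vshift[[4]])
    if (!any(newly)) break
    for (k in 1:4) {
      take <- newly & vshift[[k]]
      x[take] <- shifted[[k]][take]
      newly <- newly & !take
      valid <- valid | take
    }
  }
  x
}

#' Polynomial aberration background
#'
#' Evaluates a low-order bivariate polynomial on centred, normalised
#' coordinates (`x`, `y` in `[-1, 1]`), used to contaminate phantoms with
#' instrument-like slowly varying phase backgrounds (tilt, defocus,
#' astigmatism) for aberration-correction tests.
#'
#' @param grid_size raster side, pixels.
#' @param coeffs numeric matrix; `coeffs[i, j]` multiplies
#'   `x^(i-1) * y^(j-1)`. Total polynomial order at most 4.
#' @return phase raster in radians.
#' @examples
#' # ~1 rad astigmatic saddle: x^2 - y^2
#' cf <- matrix(0, 3, 3); cf[3, 1] <- 1; cf[1, 3] <- -1
#' ab <- aberration_background(128, cf)
#' @export
aberration_background <- function(grid_size, coeffs) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) > 5 || ncol(coeffs) > 5)
    stop("polynomial order above 4 is not supported")
  g <- pixel_grid(grid_size)
  c0 <- (grid_size - 1) / 2
  x <- (g$x - c0) / c0
  y <- (g$y - c0) / c0
  out <- matrix(0, grid_size, grid_size)
  for (i in seq_len(nrow(coeffs))) {
    for (j in seq_len(ncol(coeffs))) {
      if (coeffs[i, j] != 0) out <- out + coeffs[i, j] * x^(i - 1) * y^(j - 1)
    }
  }
  out
}
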