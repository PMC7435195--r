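# Hilbert spiral transform demodulation: spiral phase function,
# direction-guided quadrature, analytic fringe pattern, wrapped phase,
# quality-guided unwrapping, plane removal, and the classical Fourier
# transform demodulator used as the off-axis reference.

#' Spiral phase function
#'
#' The unit-modulus Fourier multiplier of the 2D vortex (Riesz)
#' transform, `SPF(u, v) = (u + i v) / sqrt(u^2 + v^2)`, evaluated on the
#' DFT frequency grid of the given shape (frequencies in cycles per
#' raster, unshifted storage order, the Nyquist bin of an even dimension
#' in the negative half). The DC bin is set to 0; zero-mean fringes are
#' unaffected by this convention.
#'
#' @param shape raster dimensions `c(nrow, ncol)`; rows index `v` (y
#'   frequency), columns `u` (x frequency).
#' @return complex matrix multiplier.
#' @export
spiral_phase_function <- function(shape) {
  nr <- shape[1]; nc <- shape[2]
  if (nr < 2 || nc < 2) stop("shape must be at least 2x2")
  u <- matrix(fft_freq(nc), nr, nc, byrow = TRUE)
  v <- matrix(fft_freq(nr), nr, nc)
  mag <- sqrt(u^2 + v^2)
  mag[1, 1] <- 1
  spf <- (u + 1i * v) / mag
  spf[1, 1] <- 0
  spf
}

# Vortex transform with mirror padding to double size (suppresses the
# periodic-extension ringing of the bare DFT at the raster borders).
vortex_transform <- function(fringes) {
  nr <- nrow(fringes); nc <- ncol(fringes)
  pr <- floor(nr / 2); pc <- floor(nc / 2)
  xp <- mirror_pad(fringes, min(pr, pc))
  m <- min(pr, pc)
  spf <- spiral_phase_function(dim(xp))
  full <- fft(spf * fft(xp), inverse = TRUE) / length(xp)
  full[(m + 1):(m + nr), (m + 1):(m + nc)]
}

#' Hilbert spiral transform quadrature
#'
#' Computes the quadrature partner of a zero-mean fringe pattern,
#' guided by the local fringe direction map `beta`:
#' `q = Re(-i * exp(-i*beta) * F^{-1}{ SPF . F[fringes] })`.
#' For a pure carrier `cos(2*pi*x/T)` with `beta = 0` this returns
#' `sin(2*pi*x/T)`. The operator is linear in `fringes` for fixed `beta`.
#'
#' @param fringes zero-mean fringe raster (uVID texture).
#' @param beta direction map (`direction_map` or radian matrix) of the
#'   same shape.
#' @return quadrature raster.
#' @export
hilbert_spiral_transform <- function(fringes, beta) {
  stopifnot_matrix(fringes)
  bv <- if (inherits(beta, "direction_map")) beta$angles else beta
  if (!all(dim(bv) == dim(fringes))) stop("shape mismatch between fringes and beta")
  vt <- vortex_transform(fringes)
  Re(-1i * exp(-1i * bv) * vt)
}

#' Assemble the complex analytic fringe pattern
#'
#' The analytic fringe pattern has the filtered fringes as its real part
#' and the spiral-transform quadrature as its imaginary part; its
#' argument is the wrapped phase.
#'
#' @inheritParams hilbert_spiral_transform
#' @return object of class `analytic_fringe_pattern`: complex matrix
#'   `afp` plus the `direction_used`.
#' @export
analytic_signal <- function(fringes, beta) {
  q <- hilbert_spiral_transform(fringes, beta)
  structure(list(afp = fringes + 1i * q, direction_used = beta),
            class = "analytic_fringe_pattern")
}

#' Wrapped phase of an analytic fringe pattern
#'
#' Four-quadrant argument, in `(-pi, pi]`. Pixels of zero magnitude get
#' phase 0 and are flagged in the `degenerate` attribute.
#'
#' @param afp an `analytic_fringe_pattern` (or complex matrix).
#' @return phase matrix in `(-pi, pi]` with attribute `degenerate`.
#' @export
wrapped_phase <- function(afp) {
  z <- if (inherits(afp, "analytic_fringe_pattern")) afp$afp else afp
  if (any(!is.finite(z))) stop("analytic fringe pattern must be finite")
  ph <- Arg(z)
  degen <- Mod(z) == 0
  ph[degen] <- 0
  ph[ph == -pi] <- pi
  attr(ph, "degenerate") <- degen
  ph
}

#' Unwrap a wrapped phase map
#'
#' Quality-guided region-growing unwrapper: pixels are admitted in order
#' of smoothness (negated local wrapped-gradient magnitude), each made
#' congruent modulo 2*pi with its best already-unwrapped neighbour. The
#' output always rewraps to the input exactly; on residue-free inputs the
#' result is the exact unwrapped surface up to a 2*pi*k offset. The
#' number of phase residues found is reported as an attribute.
#'
#' @param wrapped phase matrix in `(-pi, pi]`.
#' @return unwrapped phase matrix, attributes `residues` (count).
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot_matrix(wrapped)
  gr <- raster_gradient(wrapped)
  rough <- box_filter(abs(wrap_pi(gr$gx)) + abs(wrap_pi(gr$gy)), 3)
  out <- cpp_quality_unwrap(wrapped, -rough)
  attr(out, "residues") <- cpp_count_residues(wrapped)
  out
}

#' Remove the best-fit plane from a phase map
#'
#' Subtracts the least-squares plane (piston plus tilt) to eliminate the
#' residual linear carrier term. Idempotent; the fitted coefficients of
#' the output are zero to numerical precision.
#'
#' @param phase numeric matrix.
#' @return plane-free matrix, attribute `plane` = c(piston, slope_x,
#'   slope_y) of the removed plane (x = column, y = row, 0-based).
#' @export
remove_plane <- function(phase) {
  stopifnot_matrix(phase)
  nr <- nrow(phase); nc <- ncol(phase)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  y <- matrix(0:(nr - 1), nr, nc)
  xc <- x - mean(x[1, ]); yc <- y - mean(y[, 1])
  sx <- sum(xc * phase) / sum(xc * xc)
  sy <- sum(yc * phase) / sum(yc * yc)
  piston <- mean(phase)
  out <- phase - piston - sx * xc - sy * yc
  attr(out, "plane") <- c(piston = piston - sx * mean(x[1, ]) - sy * mean(y[, 1]),
                          slope_x = sx, slope_y = sy)
  attr(out, "residues") <- NULL
  out
}

#' Classical Fourier-transform demodulation (off-axis reference)
#'
#' The 1D simplification of the spiral transform valid when the carrier
#' separates the cross-correlation lobe from DC: mask a circular region
#' around the lobe centre in the spectrum, shift it to DC, take the
#' argument of the inverse transform, unwrap and remove the residual
#' plane. Used as the independent off-axis reference for the
#' direction-guided demodulator.
#'
#' @param interferogram intensity raster (mean is subtracted internally).
#' @param filter_center lobe centre `c(u, v)` in cycles per raster; when
#'   `NULL` the strongest non-DC spectral peak in the `u > 0` half-plane
#'   is used.
#' @param filter_radius mask radius in frequency bins; default one third
#'   of the carrier magnitude.
#' @return unwrapped, plane-free phase matrix; attribute `filter` records
#'   the centre/radius used.
#' @export
ft_demodulate <- function(interferogram, filter_center = NULL,
                          filter_radius = NULL) {
  stopifnot_matrix(interferogram)
  nr <- nrow(interferogram); nc <- ncol(interferogram)
  spec <- fft(interferogram - mean(interferogram))
  u <- matrix(fft_freq(nc), nr, nc, byrow = TRUE)
  v <- matrix(fft_freq(nr), nr, nc)
  if (is.null(filter_center)) {
    half <- Mod(spec)
    half[u <= 0] <- 0                      # keep one sideband
    idx <- which.max(half)
    filter_center <- c(u[idx], v[idx])
  }
  cu <- filter_center[1]; cv <- filter_center[2]
  if (is.null(filter_radius))
    filter_radius <- max(2, sqrt(cu^2 + cv^2) / 3)
  if (sqrt(cu^2 + cv^2) <= filter_radius)
    warning("autocorrelation leakage: filter mask touches the DC term")
  mask <- (u - cu)^2 + (v - cv)^2 <= filter_radius^2
  lobe <- fft(spec * mask, inverse = TRUE) / length(spec)
  # shift the lobe centre to DC in the space domain
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  y <- matrix(0:(nr - 1), nr, nc)
  demod <- lobe * exp(-2i * pi * (cu * x / nc + cv * y / nr))
  ph <- unwrap_phase(wrapped_phase(demod))
  out <- remove_plane(ph)
  attr(out, "filter") <- c(u = cu, v = cv, radius = filter_radius)
  out
}
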