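# Local fringe direction estimation: windowed plane-fit orientation
# (modulo pi), orientation unwrapping to a direction map (modulo 2*pi),
# and sine-cosine smoothing.

#' Local fringe orientation by combined gradient and plane fitting
#'
#' For every pixel, a plane is fitted by least squares to the intensities
#' of the `w` x `w` neighbourhood; the gradient of that plane (a smoothed
#' image gradient) feeds a structure tensor averaged over the same
#' window, whose principal axis gives the local orientation of the fringe
#' normal, folded to `[0, pi)`. Small windows resolve denser fringes but
#' pass more noise into the orientation; the window sweep of the pipeline
#' arbitrates.
#'
#' @param fringes zero-mean fringe raster (uVID texture output).
#' @param w plane-fitting window, odd, between 3 and 13.
#' @return object of class `orientation_map`: `angles` in `[0, pi)`,
#'   logical `validity` (gradient above the degeneracy threshold),
#'   `quality` (local mean gradient magnitude, used to guide unwrapping)
#'   and `w`.
#' @export
estimate_orientation <- function(fringes, w = 3) {
  stopifnot_matrix(fringes)
  if (w %% 2 != 1 || w < 3 || w > 13)
    stop("window must be odd and between 3 and 13")
  dr <- dynamic_range(fringes)
  if (dr < .Machine$double.eps)
    stop("no fringes: gradient everywhere degenerate")
  # least-squares plane slope over the w x w window == correlation of the
  # window with a linear ramp; separable kernel: ramp along one axis, box
  # along the other.
  half <- (w - 1) / 2
  ramp <- (-half):half
  s2 <- sum(ramp^2) * w
  kx <- matrix(rep(ramp, each = w), w, w) / s2        # varies along columns
  ky <- t(kx)
  px <- as.matrix(EBImage::filter2(fringes, kx, boundary = "replicate"))
  py <- as.matrix(EBImage::filter2(fringes, ky, boundary = "replicate"))
  # structure tensor of the plane-fit gradients, averaged over the window
  jxx <- box_filter(px * px, w)
  jyy <- box_filter(py * py, w)
  jxy <- box_filter(px * py, w)
  ang <- 0.5 * atan2(2 * jxy, jxx - jyy)    # in (-pi/2, pi/2]
  ang <- ang %% pi
  ang[ang >= pi] <- 0                       # guard float rounding of %%
  mag <- box_filter(sqrt(px^2 + py^2), w)
  valid <- mag > 1e-6 * dr
  structure(list(angles = ang, validity = valid, quality = mag, w = w),
            class = "orientation_map")
}

#' Unwrap an orientation map into a direction map
#'
#' Resolves the modulo-pi ambiguity of the fringe orientation into the
#' modulo-2*pi fringe direction `beta` (does the fringe normal point left
#' or right, up or down) by the angle-doubling reduction: the doubled
#' orientation is treated as a wrapped phase, unwrapped by the
#' quality-guided path follower, halved and reduced modulo 2*pi.
#'
#' Orientation noise plants spurious residues in the doubled field that
#' a path unwrapper would turn into regional half-turn flips of `beta`,
#' so the doubled field is first smoothed as a complex phasor
#' (`exp(i * 2 * phi)` under a Gaussian) and the phasor coherence — near
#' 1 where the orientation is locally consistent, small at noise and at
#' genuine direction vortices — guides the unwrapping order. Invalid
#' pixels are reached last (quality `-Inf`) and take the direction
#' propagated from their nearest valid neighbours.
#'
#' @param orientation an `orientation_map` from [estimate_orientation()].
#' @param smooth_sigma Gaussian width (pixels) of the phasor smoothing.
#' @return object of class `direction_map`: `angles` in `[0, 2*pi)`,
#'   `validity`, `w`.
#' @export
unwrap_orientation <- function(orientation, smooth_sigma = 3) {
  stopifnot(inherits(orientation, "orientation_map"))
  if (mean(orientation$validity) <= 0.5)
    stop("orientation map too degenerate: less than half the pixels valid")
  doubled <- wrap_pi(2 * orientation$angles)
  z <- gaussian_smooth(cos(doubled), smooth_sigma) +
    1i * gaussian_smooth(sin(doubled), smooth_sigma)
  coh <- Mod(z)
  q <- coh
  q[!orientation$validity] <- -Inf
  unwrapped <- cpp_quality_unwrap(Arg(z), q)
  structure(list(angles = wrap_2pi(unwrapped / 2),
                 validity = orientation$validity, w = orientation$w),
            class = "direction_map")
}

direction_map <- function(angles, w = NA_integer_, validity = NULL) {
  if (is.null(validity)) validity <- matrix(TRUE, nrow(angles), ncol(angles))
  structure(list(angles = wrap_2pi(angles), validity = validity, w = w),
            class = "direction_map")
}

#' Sine--cosine smoothing of a direction map
#'
#' Filters the direction field without disturbing its circular topology:
#' `sin(beta)` and `cos(beta)` are smoothed independently by removing the
#' `n_modes` locally highest-frequency empirical detail components (each
#' detail is the difference between the field and its 3x3-median-then-
#' Gaussian smoothing), and the direction is reassembled as
#' `atan2(sin_f, cos_f) mod 2*pi`. Filtering in the sine-cosine domain is
#' equivariant under global rotations of the direction field.
#'
#' @param direction a `direction_map`.
#' @param n_modes number of detail components to remove (default 3).
#' @return smoothed `direction_map`.
#' @export
sincos_filter <- function(direction, n_modes = 3) {
  stopifnot(inherits(direction, "direction_map"))
  s <- sin(direction$angles)
  c_ <- cos(direction$angles)
  for (k in seq_len(n_modes)) {
    s <- gaussian_smooth(median3(s), sigma = 1)
    c_ <- gaussian_smooth(median3(c_), sigma = 1)
  }
  direction$angles <- wrap_2pi(atan2(s, c_))
  direction
}

#' Circular root-mean-square difference between two direction maps
#'
#' RMS of the pointwise angular difference wrapped to `(-pi, pi]`;
#' invariant under adding full turns to either argument.
#'
#' @param a,b direction maps (`direction_map` objects or plain radian
#'   matrices of identical shape).
#' @param mask optional logical matrix restricting the comparison.
#' @return RMS angle in radians.
#' @export
circular_rms <- function(a, b, mask = NULL) {
  av <- if (inherits(a, "direction_map")) a$angles else a
  bv <- if (inherits(b, "direction_map")) b$angles else b
  if (!all(dim(av) == dim(bv))) stop("shape mismatch")
  d <- wrap_pi(av - bv)
  if (!is.null(mask)) d <- d[mask]
  sqrt(mean(d^2))
}

#' @export
print.direction_map <- function(x, ...) {
  cat(sprintf("fringe direction map %d x %d (window w = %s)\n",
              nrow(x$angles), ncol(x$angles), format(x$w)))
  cat(sprintf("  range [%.3f, %.3f] rad, %.1f%% valid\n",
              min(x$angles), max(x$angles), 100 * mean(x$validity)))
  invisible(x)
}
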