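# Internal raster helpers shared across modules.

# Wrap angles to (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Wrap angles to [0, 2*pi).  The modulo of a tiny negative value can
# round up to exactly 2*pi; fold that back to 0.
wrap_2pi <- function(x) {
  y <- x %% (2 * pi)
  y[y >= 2 * pi] <- 0
  y
}

dynamic_range <- function(x) diff(range(x, finite = TRUE))

stopifnot_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

# Mirror (symmetric) padding by m pixels on every side.
mirror_pad <- function(x, m) {
  nr <- nrow(x); nc <- ncol(x)
  if (m >= nr || m >= nc) stop("padding exceeds raster size")
  ri <- c(rev(seq_len(m) + 1L), seq_len(nr), nr - seq_len(m))
  ci <- c(rev(seq_len(m) + 1L), seq_len(nc), nc - seq_len(m))
  x[ri, ci, drop = FALSE]
}

# DFT sample frequencies in cycles per raster extent (unshifted order,
# Nyquist of an even length placed in the negative half).
fft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k >= n / 2] <- k[k >= n / 2] - n
  k
}

# Central-difference gradient with one-sided stencils at the borders.
# Returns list(gx, gy): gx is d/dx (along columns), gy is d/dy (rows).
raster_gradient <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (x[, 3:nc] - x[, 1:(nc - 2)]) / 2
  gx[, 1] <- x[, 2] - x[, 1]
  gx[, nc] <- x[, nc] - x[, nc - 1]
  gy[2:(nr - 1), ] <- (x[3:nr, ] - x[1:(nr - 2), ]) / 2
  gy[1, ] <- x[2, ] - x[1, ]
  gy[nr, ] <- x[nr, ] - x[nr - 1, ]
  list(gx = gx, gy = gy)
}

# Box (moving-average) filter with replicated borders, via EBImage.
box_filter <- function(x, w) {
  k <- matrix(1 / (w * w), w, w)
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

# 3x3 median with value-range normalisation (EBImage's median filter
# operates on [0,1] data).
median3 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo < .Machine$double.eps) return(x)
  y <- (x - lo) / (hi - lo)
  z <- as.matrix(EBImage::medianFilter(y, size = 1))
  z * (hi - lo) + lo
}

gaussian_smooth <- function(x, sigma) {
  as.matrix(EBImage::gblur(x, sigma = sigma, boundary = "replicate"))
}

# Run an expression with a private, seeded RNG stream; global state is
# untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Boolean interior mask: drop a fixed border and optionally a central
# disk (used around direction vortices of closed-fringe phantoms).
#' Interior evaluation mask
#'
#' Builds a logical mask that excludes a border margin and, optionally, a
#' disk around a given centre (in pixels, 1-based row/column), the regions
#' where demodulation of closed fringes is intrinsically ill-posed.
#'
#' @param dim raster dimensions `c(nrow, ncol)`.
#' @param border margin to exclude on every side, pixels.
#' @param disk_center optional `c(row, col)` centre of an excluded disk.
#' @param disk_radius radius of the excluded disk, pixels.
#' @return logical matrix, `TRUE` where evaluation should happen.
#' @export
interior_mask <- function(dim, border = 16, disk_center = NULL, disk_radius = 10) {
  nr <- dim[1]; nc <- dim[2]
  m <- matrix(FALSE, nr, nc)
  m[(border + 1):(nr - border), (border + 1):(nc - border)] <- TRUE
  if (!is.null(disk_center)) {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    m[(rr - disk_center[1])^2 + (cc - disk_center[2])^2 <= disk_radius^2] <- FALSE
  }
  m
}
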