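# Evaluation metrics: RMS against a reference phase (with the sign and
# piston alignment that the single-shot conjugate ambiguity requires)
# and the noise level of sample-free regions.

align_phase <- function(phase, reference, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase), ncol(phase))
  best <- NULL; best_rms <- Inf
  for (s in c(1, -1)) {
    r <- s * phase - reference
    r <- r - mean(r[mask])
    rms <- sqrt(mean(r[mask]^2))
    if (rms < best_rms) {
      best_rms <- rms
      best <- s * phase - mean((s * phase - reference)[mask])
    }
  }
  best
}

#' RMS error between a phase map and a reference
#'
#' Root-mean-square pointwise difference over the masked pixels. With
#' `align = TRUE` (the default) the global sign and piston are first
#' chosen to minimise the RMS, which quotient out the conjugate and
#' offset ambiguities inherent to single-shot demodulation.
#'
#' @param phase,reference numeric matrices of identical shape (radians).
#' @param mask optional logical matrix; defaults to all pixels.
#' @param align resolve the sign/piston ambiguity before scoring.
#' @return RMS in radians.
#' @export
rms_error <- function(phase, reference, mask = NULL, align = TRUE) {
  if (!all(dim(phase) == dim(reference))) stop("shape mismatch")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase), ncol(phase))
  if (!any(mask)) stop("empty mask")
  p <- if (align) align_phase(phase, reference, mask) else phase
  sqrt(mean((p - reference)[mask]^2))
}

#' Standard deviation of a sample-free region
#'
#' Sample standard deviation of the phase over the masked (sample-free)
#' pixels — the conventional noise figure of a reconstruction. Invariant
#' under piston offsets.
#'
#' @param phase numeric matrix (radians).
#' @param mask logical matrix marking sample-free pixels.
#' @return standard deviation in radians.
#' @export
background_std <- function(phase, mask) {
  if (!any(mask)) stop("empty mask")
  sd(phase[mask])
}

#' Pointwise phase error map
#'
#' The aligned difference `phase - reference`, for visualising where a
#' reconstruction deviates from its reference.
#'
#' @inheritParams rms_error
#' @return numeric matrix of signed errors (radians).
#' @export
error_map <- function(phase, reference, align = TRUE) {
  if (!all(dim(phase) == dim(reference))) stop("shape mismatch")
  p <- if (align) align_phase(phase, reference) else phase
  p - reference
}
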