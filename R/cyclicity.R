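# Core cyclicity analysis: path closing, lead-matrix construction, and
# spectral extraction of per-channel cyclic strengths and phases.
#
# A multichannel time course is treated as a d-dimensional path; the lead
# matrix is the antisymmetric part of its second-order iterated integral.
# Entry A[i, j] is the signed area enclosed by the projection of the closed
# path onto the (i, j) coordinate plane; its sign encodes which channel
# leads.  Everything downstream (strengths, phase orderings) comes from the
# eigendecomposition of this matrix.

.as_timecourse <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("time course must be numeric", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("ch", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("channel labels must be unique", call. = FALSE)
  x
}

#' Mean-centre and linearly close a multichannel time course
#'
#' Per channel, subtracts the linear ramp connecting the first and last
#' samples (so the path becomes closed) and then removes the mean of the
#' closed signal.  The lead matrix is only meaningful for closed paths;
#' this is the standard adjustment applied before computing it.
#'
#' @param tc numeric matrix, channels in rows, samples in columns.  Row
#'   names are the channel labels.
#' @return matrix of the same shape with equal first/last samples and zero
#'   channel means.
#' @examples
#' x <- rbind(a = sin(seq(0, 4 * pi, length.out = 100)) + 0.5 * (1:100))
#' cc <- center_and_close(x)
#' abs(cc[1] - cc[100]) < 1e-10
#' @export
center_and_close <- function(tc) {
  tc <- .as_timecourse(tc)
  if (ncol(tc) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(tc))) stop("non-finite values in time course", call. = FALSE)
  n <- ncol(tc)
  ramp_unit <- (seq_len(n) - 1) / (n - 1)
  drift <- tc[, n] - tc[, 1]
  closed <- tc - outer(drift, ramp_unit)
  closed - rowMeans(closed)
}

#' Lead matrix of a multichannel time course
#'
#' Computes the antisymmetric matrix of pairwise signed areas of the closed
#' path: \code{A[i, j] = 1/2 * sum_k (x_i(k) dx_j(k) - x_j(k) dx_i(k))},
#' summed over consecutive samples with wraparound.  This is the shoelace
#' formula for the signed area of the (i, j) projection, exact for the
#' piecewise-linear interpolation of the samples, and discretises the
#' second-order iterated path integral.  For a pair of sinusoids
#' \code{a*sin(t + phi_i)}, \code{b*sin(t + phi_j)} over \code{n} full
#' periods the entry converges to \code{n * pi * a * b * sin(phi_i - phi_j)}.
#'
#' The input is centred and closed internally (the operation is idempotent
#' on already-closed input).
#'
#' @param tc channels-by-samples numeric matrix.
#' @param normalize if TRUE, each channel is scaled to unit variance before
#'   the area computation (off by default; useful when channels mix very
#'   different amplitude scales).
#' @return antisymmetric channels-by-channels matrix with channel dimnames.
#' @export
lead_matrix <- function(tc, normalize = FALSE) {
  tc <- .as_timecourse(tc)
  if (nrow(tc) < 2L) stop("need at least 2 channels", call. = FALSE)
  if (ncol(tc) < 3L) stop("need at least 3 samples to enclose area", call. = FALSE)
  x <- center_and_close(tc)
  if (normalize) {
    s <- apply(x, 1L, stats::sd)
    s[s == 0] <- 1
    x <- x / s
  }
  n <- ncol(x)
  dx <- x[, c(2:n, 1L), drop = FALSE] - x    # increments, wrapping to close
  a <- 0.5 * (x %*% t(dx) - dx %*% t(x))
  a <- 0.5 * (a - t(a))                      # enforce exact antisymmetry
  dimnames(a) <- list(rownames(tc), rownames(tc))
  a
}

#' Spectral decomposition of a lead matrix
#'
#' A real antisymmetric matrix has purely imaginary eigenvalues in
#' conjugate pairs \code{+/- i*mu}.  The eigenvector of the leading
#' \code{+i*mu} carries one complex number per channel: its modulus is the
#' channel's cyclic strength and its argument encodes the channel's place
#' in the cyclic ordering.  Phases are determined only up to one global
#' rotation and a global sign (the direction of the cycle is not
#' identifiable); the rotation is fixed deterministically by rotating the
#' largest-modulus component to argument zero.
#'
#' @param lm antisymmetric numeric matrix.
#' @param n_vectors number of leading eigenvector pairs to retain (2 covers
#'   the multi-harmonic regime).
#' @param tol relative tolerance for the antisymmetry check.
#' @return list with \code{eigen_magnitudes} (all pair magnitudes,
#'   descending), \code{strengths} and \code{phases} (channels x n_vectors
#'   matrices for the leading pairs), \code{defined} (FALSE when the matrix
#'   is numerically zero, in which case strengths/phases are NA), and
#'   \code{channels}.
#' @export
spectral_decomposition <- function(lm, n_vectors = 2L, tol = 1e-8) {
  if (!is.matrix(lm) || nrow(lm) != ncol(lm))
    stop("lead matrix must be square", call. = FALSE)
  m <- nrow(lm)
  scale0 <- max(abs(lm))
  if (max(abs(lm + t(lm))) > tol * max(scale0, 1))
    stop("input is not antisymmetric", call. = FALSE)
  labels <- rownames(lm)
  if (is.null(labels)) labels <- paste0("ch", seq_len(m))
  n_pairs <- m %/% 2L
  n_vectors <- min(n_vectors, n_pairs)

  if (scale0 == 0) {
    return(list(
      eigen_magnitudes = rep(0, n_pairs),
      strengths = matrix(NA_real_, m, n_vectors, dimnames = list(labels, NULL)),
      phases = matrix(NA_real_, m, n_vectors, dimnames = list(labels, NULL)),
      defined = FALSE, channels = labels))
  }

  e <- eigen(lm, symmetric = FALSE)
  imag <- Im(e$values)
  # keep the +i*mu member of each conjugate pair, sorted by mu descending;
  # ties resolved by first occurrence in the decomposition output
  pos <- order(imag, decreasing = TRUE)[seq_len(n_pairs)]
  mags <- imag[pos]
  strengths <- matrix(NA_real_, m, n_vectors, dimnames = list(labels, NULL))
  phases <- matrix(NA_real_, m, n_vectors, dimnames = list(labels, NULL))
  for (k in seq_len(n_vectors)) {
    w <- e$vectors[, pos[k]]
    anchor <- which.max(Mod(w))
    w <- w * exp(-1i * Arg(w[anchor]))  # fix global rotation
    strengths[, k] <- Mod(w)
    phases[, k] <- Arg(w)
  }
  list(eigen_magnitudes = pmax(mags, 0), strengths = strengths,
       phases = phases, defined = mags[1L] > tol * scale0, channels = labels)
}

#' Recover per-channel phase offsets from the leading eigenvector
#'
#' Converts the leading eigenvector arguments into phase offsets in
#' \code{[0, 2*pi)} relative to a reference channel (whose offset is 0 by
#' construction).  For noiseless phase-shifted sinusoids the offsets equal
#' the generating phases relative to the reference.  The global direction
#' of the cycle remains undetermined: callers comparing against known
#' phases must also consider the negated ordering.
#'
#' @param ss result of [spectral_decomposition()].
#' @param reference_channel channel label (or index) mapped to offset 0.
#' @return named numeric vector of offsets in radians, \code{[0, 2*pi)}.
#' @export
recover_phase_offsets <- function(ss, reference_channel = 1L) {
  if (!isTRUE(ss$defined))
    stop("phases undefined: leading eigenvalue is zero", call. = FALSE)
  ref <- if (is.character(reference_channel)) {
    match(reference_channel, ss$channels)
  } else as.integer(reference_channel)
  if (is.na(ref) || ref < 1L || ref > length(ss$channels))
    stop("unknown reference channel", call. = FALSE)
  arg <- ss$phases[, 1L]
  # eigenvector components of +i*mu go as exp(-i*phi): negate to get phases
  offs <- (arg[ref] - arg) %% (2 * pi)
  names(offs) <- ss$channels
  offs
}

#' Circular root-mean-square error between two phase vectors
#'
#' Helper for assessing phase recovery: aligns \code{estimate} to
#' \code{truth} by the optimal global rotation (circular mean of the
#' difference), for both the estimate and its negation, and returns the
#' smaller RMSE of wrapped residuals.  Respects the global rotation and
#' direction ambiguities inherent to lead-matrix phases.
#'
#' @param estimate,truth numeric vectors of radians, equal length.
#' @return nonnegative scalar (radians).
#' @export
circular_rmse <- function(estimate, truth) {
  stopifnot(length(estimate) == length(truth))
  one_dir <- function(est) {
    d <- est - truth
    rot <- Arg(mean(exp(1i * d)))
    r <- Arg(exp(1i * (d - rot)))  # wrapped residuals in (-pi, pi]
    sqrt(mean(r^2))
  }
  min(one_dir(estimate), one_dir(-estimate))
}
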