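# Feature engineering over lead matrices: upper-triangle vectorisation,
# channel-strength rankings, channel removal, and group-wise PCA with
# loading-matrix reconstruction for display.

#' Pair labels for the strict upper triangle of a channel set
#'
#' Row-major ordering: (1,2), (1,3), ..., (1,m), (2,3), ...
#'
#' @param channels character vector of channel labels.
#' @return character vector of length \code{m*(m-1)/2}, \code{"a->b"}.
#' @export
pair_labels <- function(channels) {
  idx <- pair_index(length(channels))
  paste0(channels[idx[, 1L]], "->", channels[idx[, 2L]])
}

#' Strict-upper-triangle pair index in row-major order
#'
#' @param m channel count.
#' @return two-column integer matrix (i, j), i < j, ordered by i then j.
#' @export
pair_index <- function(m) {
  idx <- which(upper.tri(diag(m)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}

#' Vectorise a lead matrix into its upper-triangle feature vector
#'
#' A 33-channel lead matrix yields a 528-dimensional vector.  The mapping
#' is invertible given the channel count because the matrix is
#' antisymmetric with zero diagonal.
#'
#' @param lm antisymmetric matrix.
#' @return named numeric vector of length \code{m*(m-1)/2} in row-major
#'   pair order.
#' @export
vectorize_lead <- function(lm) {
  m <- nrow(lm)
  idx <- pair_index(m)
  v <- lm[idx]
  names(v) <- if (!is.null(rownames(lm))) pair_labels(rownames(lm))
  v
}

#' Rebuild an antisymmetric matrix from an upper-triangle vector
#'
#' Inverse of [vectorize_lead()]; also used to display PCA loading
#' vectors in lead-matrix form (the contribution of each channel pair to
#' a direction of variation).
#'
#' @param v numeric vector of length \code{m*(m-1)/2}.
#' @param channels optional channel labels (length m).
#' @return antisymmetric m-by-m matrix.
#' @export
loading_to_matrix <- function(v, channels = NULL) {
  p <- length(v)
  m <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(m - round(m)) > 1e-9)
    stop("vector length is not m*(m-1)/2 for any integer m", call. = FALSE)
  m <- as.integer(round(m))
  if (!is.null(channels) && length(channels) != m)
    stop("channel labels do not match vector length", call. = FALSE)
  a <- matrix(0, m, m)
  idx <- pair_index(m)
  a[idx] <- v
  a <- a - t(a)
  if (!is.null(channels)) dimnames(a) <- list(channels, channels)
  a
}

#' Remove channels from a time course before lead-matrix computation
#'
#' Channel removal is applied to the time course (not to precomputed lead
#' matrices), so downstream matrices are recomputed at the reduced
#' dimension.
#'
#' @param tc channels-by-samples matrix with row names.
#' @param labels channel labels to drop.
#' @return reduced matrix.
#' @export
drop_channels <- function(tc, labels) {
  tc <- .as_timecourse(tc)
  if (length(labels) == 0L) return(tc)
  missing <- setdiff(labels, rownames(tc))
  if (length(missing))
    stop("unknown channel label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tc[!(rownames(tc) %in% labels), , drop = FALSE]
}

#' Proportion of records ranking each channel in the top strengths
#'
#' For each group, the fraction of records (runs) in which a channel's
#' cyclic strength falls within the \code{top_n} largest.  Ties are broken
#' deterministically by channel order.
#'
#' @param strengths records-by-channels matrix of leading-eigenvector
#'   moduli (one row per run/record).
#' @param groups group label per record.
#' @param top_n rank cutoff.
#' @return groups-by-channels matrix of proportions in \code{[0, 1]}.
#' @export
strength_ranking <- function(strengths, groups, top_n = 10L) {
  strengths <- as.matrix(strengths)
  if (nrow(strengths) == 0L) stop("no records", call. = FALSE)
  if (anyNA(strengths)) stop("undefined strengths in input", call. = FALSE)
  stopifnot(length(groups) == nrow(strengths))
  top_n <- min(top_n, ncol(strengths))
  in_top <- t(apply(strengths, 1L, function(s) {
    r <- order(s, decreasing = TRUE)  # stable: ties by channel order
    hit <- logical(length(s)); hit[r[seq_len(top_n)]] <- TRUE; hit
  }))
  glev <- unique(groups)
  out <- t(vapply(glev, function(g)
    colMeans(in_top[groups == g, , drop = FALSE]), numeric(ncol(strengths))))
  rownames(out) <- glev
  colnames(out) <- colnames(strengths)
  out
}

#' Group-wise PCA of run-level feature vectors
#'
#' Centred covariance eigendecomposition of the feature matrix.  Loadings
#' are unit-norm with a deterministic sign convention (largest-magnitude
#' coefficient positive); eigenvalue ratios lambda1/lambda2 and
#' lambda1/lambda3 summarise how dominant the first direction is.
#'
#' @param features runs-by-pairs numeric matrix (one group's runs).
#' @param n_components how many loading vectors to retain.
#' @return list with \code{loadings} (pairs x k), \code{eigenvalues}
#'   (variances, descending), \code{ratio_12}, \code{ratio_13} (Inf when
#'   the trailing eigenvalue is zero), and \code{center}.
#' @export
group_pca <- function(features, n_components = 10L) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 samples for PCA", call. = FALSE)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                 # sign convention
    a <- which.max(abs(load[, j]))
    if (load[a, j] < 0) load[, j] <- -load[, j]
  }
  # eigenvalues below numerical noise are treated as zero for the ratios
  ratio <- function(i) {
    if (length(ev) >= i && ev[i] > 1e-12 * ev[1L]) ev[1L] / ev[i] else Inf
  }
  list(loadings = load, eigenvalues = ev, ratio_12 = ratio(2L),
       ratio_13 = ratio(3L), center = pc$center)
}
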