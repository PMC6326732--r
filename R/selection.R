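# Wilks'-lambda discriminability ranking of channel-pair features and
# Monte Carlo stability selection over random half-subsets.

#' Univariate Wilks' lambda for a two-group feature
#'
#' \code{lambda = SS_within / SS_total} for the one-way two-group layout.
#' Values near 0 mark features whose group means are far apart relative
#' to within-group spread; 1 means no separation.  Monotone in the
#' one-way F statistic: \code{F = (N - 2) * (1 - lambda) / lambda}.
#'
#' @param x numeric feature values (one per run).
#' @param labels two-level group labels, both levels nonempty.
#' @return scalar in \code{(0, 1]} (0 only with zero within-group
#'   variance).
#' @export
wilks_lambda <- function(x, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L || any(tabulate(factor(labels, lev)) == 0L))
    stop("need exactly two nonempty groups", call. = FALSE)
  sst <- sum((x - mean(x))^2)
  if (sst == 0) stop("constant feature: lambda undefined", call. = FALSE)
  ssw <- sum(vapply(lev, function(g) {
    xi <- x[labels == g]
    sum((xi - mean(xi))^2)
  }, 0))
  ssw / sst
}

.wilks_matrix <- function(features, labels) {
  # vectorised lambda per column; constant columns -> NA
  lev <- unique(labels)
  x1 <- features[labels == lev[1L], , drop = FALSE]
  x2 <- features[labels == lev[2L], , drop = FALSE]
  css <- function(x) colSums(x^2) - nrow(x) * colMeans(x)^2
  sst <- css(features)
  ssw <- css(x1) + css(x2)
  lam <- ssw / sst
  lam[sst <= 0] <- NA_real_
  lam
}

#' Rank channel pairs by Wilks' lambda
#'
#' @param features runs-by-pairs matrix.
#' @param labels two-group labels per run.
#' @return list with \code{lambda} (per pair), \code{ranks} (pair indices
#'   ordered ascending by lambda, ties broken by pair index), and
#'   \code{pairs} (column names).
#' @export
rank_pairs <- function(features, labels) {
  features <- as.matrix(features)
  lev <- unique(as.character(labels))
  if (length(lev) != 2L) stop("need exactly two groups", call. = FALSE)
  lam <- .wilks_matrix(features, as.character(labels))
  if (all(is.na(lam))) stop("all features constant", call. = FALSE)
  ord <- order(lam, seq_along(lam), na.last = TRUE)
  list(lambda = lam, ranks = ord, pairs = colnames(features))
}

#' Monte Carlo stability of Wilks'-lambda selection
#'
#' Repeatedly draws a random half of the dataset (subject-level,
#' stratified by group so both groups stay represented), ranks the pairs
#' by lambda on the half, and counts how often each pair lands in the
#' \code{top_k} most discriminating.  Pairs that are frequently selected
#' across subsets are stable discriminators rather than sample-specific
#' ones.
#'
#' @param features runs-by-pairs matrix.
#' @param labels group label per run.
#' @param subject subject id per run (runs of one subject move together).
#' @param n_trials number of random subsets.
#' @param top_k rank cutoff recorded per trial.
#' @param seed integer seed.
#' @return list with \code{counts} (per pair, <= n_trials),
#'   \code{n_trials_run} (trials actually used), and \code{skipped}
#'   (degenerate trials dropped).
#' @export
monte_carlo_stability <- function(features, labels, subject,
                                  n_trials = 1000L, top_k = 20L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  subject <- as.character(subject)
  set.seed(as.integer(seed))
  subj_tab <- unique(data.frame(subject = subject, group = labels,
                                stringsAsFactors = FALSE))
  lev <- unique(subj_tab$group)
  if (length(lev) != 2L) stop("need exactly two groups", call. = FALSE)
  counts <- integer(ncol(features))
  skipped <- 0L
  for (trial in seq_len(n_trials)) {
    take <- unlist(lapply(lev, function(g) {
      ids <- subj_tab$subject[subj_tab$group == g]
      sample(ids, max(1L, floor(length(ids) / 2)))
    }))
    sel <- subject %in% take
    if (length(unique(labels[sel])) != 2L) { skipped <- skipped + 1L; next }
    lam <- .wilks_matrix(features[sel, , drop = FALSE], labels[sel])
    if (all(is.na(lam))) { skipped <- skipped + 1L; next }
    top <- order(lam, seq_along(lam), na.last = TRUE)[seq_len(top_k)]
    top <- top[!is.na(lam[top])]
    counts[top] <- counts[top] + 1L
  }
  names(counts) <- colnames(features)
  list(counts = counts, n_trials_run = n_trials - skipped, skipped = skipped)
}

#' Select the most stable discriminating pairs
#'
#' @param counts per-pair stability counts from [monte_carlo_stability()].
#' @param n_select how many pairs to keep.
#' @param lambda_full optional full-data lambda values used to break count
#'   ties (lower lambda wins); defaults to pair order.
#' @return integer vector of selected pair indices (named if counts are).
#' @export
select_stable <- function(counts, n_select = 10L, lambda_full = NULL) {
  if (length(counts) == 0L) stop("empty counts", call. = FALSE)
  n_select <- min(n_select, length(counts))
  tie <- if (is.null(lambda_full)) seq_along(counts) else lambda_full
  ord <- order(-counts, tie, seq_along(counts))
  sel <- ord[seq_len(n_select)]
  names(sel) <- names(counts)[sel]
  sel
}
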