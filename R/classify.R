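# Group classification protocols: subject-level half splits with optional
# class balancing, dimension reduction (train-fitted PCA-10 or Wilks-
# selected pairs), five classifiers, and Monte Carlo averaging of
# row-normalised confusion matrices.

#' Define a classification protocol
#'
#' @param feature_mode one of \code{"pca10"} (PCA fitted on the training
#'   half, 10 components), \code{"wilks_top20_whole"} (pairs selected by
#'   whole-data Wilks' lambda — note this reuses the test data for
#'   selection), \code{"wilks_top10_stable"} (pairs from Monte Carlo
#'   stability selection), or \code{"raw"}.
#' @param classifier one of \code{"linear_svm"}, \code{"quadratic_svm"},
#'   \code{"lda"}, \code{"qda"}, \code{"plsda"}.
#' @param plsda_components latent components for PLS-DA (capped at the
#'   feature count and training size at fit time).
#' @param balance_classes if TRUE, majority-group training subjects are
#'   subsampled to the minority count before fitting.
#' @param n_trials Monte Carlo half-split trials to average.
#' @param n_pcs components kept in \code{"pca10"} mode.
#' @param seed integer seed for the trial splits.
#' @return list of class \code{classification_protocol}.
#' @export
classification_protocol <- function(feature_mode = c("pca10", "wilks_top20_whole",
                                                     "wilks_top10_stable", "raw"),
                                    classifier = c("linear_svm", "quadratic_svm",
                                                   "lda", "qda", "plsda"),
                                    plsda_components = 20L,
                                    balance_classes = FALSE,
                                    n_trials = 100L, n_pcs = 10L, seed = 1L) {
  structure(list(feature_mode = match.arg(feature_mode),
                 classifier = match.arg(classifier),
                 plsda_components = as.integer(plsda_components),
                 balance_classes = isTRUE(balance_classes),
                 n_trials = as.integer(n_trials), n_pcs = as.integer(n_pcs),
                 seed = as.integer(seed)),
            class = "classification_protocol")
}

#' Subject-level half split with optional class balancing
#'
#' Half the subjects of each group (rounded up) form the training side;
#' all of a subject's runs stay on one side so no identity leaks across
#' the split.  With \code{balance = TRUE} the majority group's training
#' subjects are subsampled to the minority group's training count.
#'
#' @param meta data frame with columns \code{subject_id} and \code{group}
#'   (one row per run).
#' @param balance balance training group sizes.
#' @param seed integer seed.
#' @return list with logical run masks \code{train} and \code{test}.
#' @export
split_half <- function(meta, balance = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  subj <- unique(meta[, c("subject_id", "group")])
  lev <- unique(subj$group)
  if (length(lev) != 2L) stop("need exactly two groups", call. = FALSE)
  train_subj <- unlist(lapply(lev, function(g) {
    ids <- subj$subject_id[subj$group == g]
    if (length(ids) < 2L) stop("group too small to split", call. = FALSE)
    sample(ids, ceiling(length(ids) / 2))
  }))
  test <- !(meta$subject_id %in% train_subj)
  if (balance) {
    per_group <- split(intersect(subj$subject_id, train_subj),
                       subj$group[match(intersect(subj$subject_id, train_subj),
                                        subj$subject_id)])
    n_min <- min(lengths(per_group))
    train_subj <- unlist(lapply(per_group, function(ids)
      if (length(ids) > n_min) sample(ids, n_min) else ids))
  }
  list(train = meta$subject_id %in% train_subj, test = test)
}

# --- PLS1 regression on +/-1 class coding (NIPALS) ------------------------

.pls1_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  ncomp <- min(ncomp, ncol(x), nrow(x) - 1L)
  mx <- colMeans(x); my <- mean(y)
  xc <- sweep(x, 2L, mx); yc <- y - my
  p <- ncol(x)
  w_mat <- matrix(0, p, ncomp); p_mat <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_sc <- drop(xc %*% w)
    tt <- sum(t_sc^2)
    pl <- drop(crossprod(xc, t_sc)) / tt
    qa <- sum(yc * t_sc) / tt
    xc <- xc - tcrossprod(t_sc, pl)
    yc <- yc - qa * t_sc
    w_mat[, a] <- w; p_mat[, a] <- pl; q[a] <- qa
  }
  if (ncomp == 0L) return(list(coef = numeric(p), mx = mx, my = my))
  w_mat <- w_mat[, seq_len(ncomp), drop = FALSE]
  p_mat <- p_mat[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  r_mat <- w_mat %*% solve(crossprod(p_mat, w_mat))
  list(coef = drop(r_mat %*% q), mx = mx, my = my, ncomp = ncomp)
}

.pls1_predict <- function(fit, x) {
  drop(sweep(as.matrix(x), 2L, fit$mx) %*% fit$coef) + fit$my
}

#' Fit a classifier on training runs and predict test labels
#'
#' Implements the five classifiers of the protocol: linear and degree-2
#' polynomial SVM (via e1071), linear and quadratic discriminant analysis
#' (via MASS; QDA falls back to a small ridge on the features if a class
#' covariance is singular, with a warning), and PLS-DA (PLS1 regression on
#' +/-1 class coding, decision threshold 0, components capped at the
#' feature count).
#'
#' @param classifier classifier name (see [classification_protocol()]).
#' @param train_x,train_y training features and two-level factor labels.
#' @param test_x test features.
#' @param plsda_components latent components for \code{"plsda"}.
#' @return factor of predicted labels with the training levels.
#' @export
fit_predict <- function(classifier, train_x, train_y, test_x,
                        plsda_components = 20L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- factor(train_y)
  lev <- levels(train_y)
  if (length(lev) != 2L) stop("need two classes", call. = FALSE)
  colnames(train_x) <- colnames(test_x) <- paste0("f", seq_len(ncol(train_x)))
  pred <- switch(classifier,
    linear_svm = {
      fit <- e1071::svm(train_x, train_y, kernel = "linear", scale = TRUE)
      stats::predict(fit, test_x)
    },
    quadratic_svm = {
      fit <- e1071::svm(train_x, train_y, kernel = "polynomial", degree = 2,
                        coef0 = 1, scale = TRUE)
      stats::predict(fit, test_x)
    },
    lda = {
      fit <- MASS::lda(train_x, grouping = train_y)
      stats::predict(fit, test_x)$class
    },
    qda = {
      fit <- tryCatch(MASS::qda(train_x, grouping = train_y),
        error = function(e) {
          warning("qda covariance singular; refitting with ridge jitter",
                  call. = FALSE)
          ridge <- 1e-6 * stats::sd(train_x)
          MASS::qda(train_x + matrix(stats::rnorm(length(train_x), 0, ridge),
                                     nrow(train_x)), grouping = train_y)
        })
      stats::predict(fit, test_x)$class
    },
    plsda = {
      y <- ifelse(train_y == lev[2L], 1, -1)
      fit <- .pls1_fit(train_x, y, plsda_components)
      factor(lev[(.pls1_predict(fit, test_x) > 0) + 1L], levels = lev)
    },
    stop("unknown classifier: ", classifier, call. = FALSE))
  factor(as.character(pred), levels = lev)
}

#' Monte Carlo half-split classification
#'
#' Runs \code{n_trials} fresh subject-level half splits; per trial,
#' reduces dimension according to the protocol's feature mode (PCA fitted
#' on the training half only, or a fixed set of selected pairs), fits the
#' classifier, and accumulates the row-normalised 2x2 confusion matrix.
#' The report averages percentages across trials, in the convention where
#' rows are the true class and the overall accuracy is the class-size-
#' weighted mean of the diagonal.
#'
#' For \code{feature_mode = "wilks_top20_whole"} the selection uses the
#' whole dataset before splitting, which reuses test data during feature
#' selection (double dipping); a warning is emitted.
#'
#' @param features runs-by-pairs feature matrix.
#' @param meta data frame with \code{subject_id} and \code{group} per run.
#' @param protocol a [classification_protocol()].
#' @param pairs optional preselected pair indices (required for
#'   \code{"wilks_top10_stable"}; computed internally for
#'   \code{"wilks_top20_whole"} when missing).
#' @return a confusion report, see [report_confusion()]; also carries
#'   \code{per_trial} accuracies and the protocol.
#' @export
monte_carlo_classification <- function(features, meta, protocol, pairs = NULL) {
  features <- as.matrix(features)
  lev <- unique(meta$group)
  stopifnot(length(lev) == 2L)
  if (protocol$feature_mode == "wilks_top20_whole" && is.null(pairs)) {
    warning("whole-data Wilks selection before split-half classification ",
            "constitutes double dipping; interpret accuracies accordingly",
            call. = FALSE)
    rk <- rank_pairs(features, meta$group)
    pairs <- rk$ranks[seq_len(20L)]
  }
  if (protocol$feature_mode == "wilks_top10_stable" && is.null(pairs))
    stop("wilks_top10_stable requires precomputed stable pair indices",
         call. = FALSE)
  if (!is.null(pairs) && protocol$feature_mode %in%
        c("wilks_top20_whole", "wilks_top10_stable"))
    features <- features[, pairs, drop = FALSE]

  counts <- matrix(0, 2L, 2L, dimnames = list(lev, lev))
  rates_sum <- matrix(0, 2L, 2L, dimnames = list(lev, lev))
  per_trial <- numeric(protocol$n_trials)
  # class sizes in subjects, for the weighted overall accuracy
  subj <- unique(meta[, c("subject_id", "group")])
  class_sizes <- vapply(lev, function(g) sum(subj$group == g), 0L)

  for (trial in seq_len(protocol$n_trials)) {
    sp <- split_half(meta, balance = protocol$balance_classes,
                     seed = protocol$seed + trial)
    tr_x <- features[sp$train, , drop = FALSE]
    te_x <- features[sp$test, , drop = FALSE]
    tr_y <- meta$group[sp$train]
    te_y <- meta$group[sp$test]
    if (protocol$feature_mode == "pca10") {
      pc <- stats::prcomp(tr_x, center = TRUE, scale. = FALSE)
      k <- min(protocol$n_pcs, ncol(pc$rotation))
      rot <- pc$rotation[, seq_len(k), drop = FALSE]
      te_x <- sweep(te_x, 2L, pc$center) %*% rot
      tr_x <- pc$x[, seq_len(k), drop = FALSE]
    }
    pred <- fit_predict(protocol$classifier, tr_x, factor(tr_y, lev), te_x,
                        plsda_components = protocol$plsda_components)
    tab <- table(factor(te_y, lev), pred)
    counts <- counts + tab
    rates_sum <- rates_sum + 100 * sweep(tab, 1L, pmax(rowSums(tab), 1L), "/")
    per_trial[trial] <- sum(diag(tab)) / sum(tab)
  }
  rep <- report_confusion(rates_sum / protocol$n_trials, class_sizes)
  rep$raw_counts <- counts
  rep$per_trial <- per_trial
  rep$protocol <- protocol
  rep
}

#' Confusion report in row-percentage convention
#'
#' Rows are the true class, columns the predicted class, entries
#' row-normalised percentages.  The overall accuracy is the class-size-
#' weighted mean of the diagonal rates: \code{sum_g (n_g / N) * diag_g}.
#'
#' @param rates 2x2 matrix of row percentages (rows sum to 100), or raw
#'   counts (normalised internally).
#' @param class_sizes class sizes (e.g. subjects per group) used as
#'   weights.
#' @return list with \code{matrix} (percentages) and
#'   \code{overall_accuracy} (percentage).
#' @export
report_confusion <- function(rates, class_sizes) {
  rates <- as.matrix(rates)
  stopifnot(all(rates >= 0), length(class_sizes) == nrow(rates))
  rs <- rowSums(rates)
  if (any(rs == 0)) stop("empty confusion row", call. = FALSE)
  if (max(abs(rs - 100)) > 1e-6)  # raw counts: normalise
    rates <- 100 * sweep(rates, 1L, rs, "/")
  w <- class_sizes / sum(class_sizes)
  list(matrix = rates,
       overall_accuracy = sum(w * diag(rates)))
}
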