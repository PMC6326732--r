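# Cross-session subject fingerprinting: 1-nearest-neighbour matching of
# run-level lead-matrix feature vectors under the cosine metric, training
# on one session and testing on the other in both directions.

.cosine_dist <- function(test, train) {
  tn <- sqrt(rowSums(test^2))
  rn <- sqrt(rowSums(train^2))
  if (any(tn == 0) || any(rn == 0))
    stop("zero-norm feature vector: cosine distance undefined", call. = FALSE)
  1 - (test %*% t(train)) / outer(tn, rn)
}

#' Cross-session subject identification by k-NN cosine matching
#'
#' Trains on every subject's session-1 runs and classifies session-2 runs
#' by the nearest training run's subject (cosine distance), then repeats
#' with the sessions swapped.  Groups are pooled.  With 2 runs per session
#' each subject can be correctly identified up to 4 times.  Nearest-
#' neighbour ties are broken by the lowest subject index.
#'
#' @param features runs-by-pairs feature matrix.
#' @param subject subject id per run.
#' @param session session index per run (exactly two distinct values).
#' @param k number of neighbours (k = 1 is the standard protocol; for
#'   k > 1 the majority subject among the k nearest wins, ties again to
#'   the lowest subject index).
#' @return list with \code{confusion} (true x predicted run counts),
#'   \code{per_subject_correct} (named counts), \code{runs_per_subject},
#'   and \code{overall_accuracy}.
#' @export
knn_session_identification <- function(features, subject, session, k = 1L) {
  features <- as.matrix(features)
  subject <- as.character(subject)
  stopifnot(length(subject) == nrow(features),
            length(session) == nrow(features))
  sess_lev <- sort(unique(session))
  if (length(sess_lev) != 2L)
    stop("exactly two sessions required", call. = FALSE)
  subj_lev <- sort(unique(subject))
  for (s in subj_lev) {
    have <- unique(session[subject == s])
    if (length(have) != 2L)
      stop("subject ", s, " is missing a session", call. = FALSE)
  }
  n_s <- length(subj_lev)
  confusion <- matrix(0L, n_s, n_s, dimnames = list(subj_lev, subj_lev))

  classify_dir <- function(train_sess, test_sess) {
    tr <- session == train_sess
    te <- session == test_sess
    d <- .cosine_dist(features[te, , drop = FALSE],
                      features[tr, , drop = FALSE])
    tr_subj <- subject[tr]
    apply(d, 1L, function(row) {
      nn <- order(row, match(tr_subj, subj_lev))[seq_len(k)]  # tie: low index
      votes <- table(factor(tr_subj[nn], levels = subj_lev))
      subj_lev[which.max(votes)]
    })
  }

  for (dir in list(c(1L, 2L), c(2L, 1L))) {
    pred <- classify_dir(sess_lev[dir[1L]], sess_lev[dir[2L]])
    truth <- subject[session == sess_lev[dir[2L]]]
    for (i in seq_along(pred))
      confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  }
  correct <- diag(confusion)
  list(confusion = confusion,
       per_subject_correct = correct,
       runs_per_subject = rowSums(confusion),
       overall_accuracy = sum(correct) / sum(confusion))
}
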