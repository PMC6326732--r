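# Shared fixtures, built in code at test time.

# Feature table with one planted discriminative pair: two groups of
# n_per_group rows, unit-variance noise everywhere, and a mean shift of
# `effect` standard deviations on the planted column for group "b".
planted_features <- function(n_per_group = 40L, n_pairs = 528L,
                             planted = 1L, effect = 2, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  x <- matrix(rnorm(n * n_pairs), n, n_pairs)
  g <- rep(c("a", "b"), each = n_per_group)
  x[g == "b", planted] <- x[g == "b", planted] + effect
  colnames(x) <- paste0("p", seq_len(n_pairs))
  list(features = x, labels = g,
       subject = paste0("s", seq_len(n)))  # one run per subject
}

# Small cohort for pipeline-level tests (fast to generate).
small_cohort_spec <- function(seed = 1L, ...) {
  args <- list(n_group_a = 4L, n_group_b = 6L, n_channels = 12L,
               n_samples = 150L, n_periods = 6L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}

# Run-level meta + Gaussian features separable at `effect` SDs along
# several coordinates, subject structure preserved (4 runs per subject).
separable_runs <- function(n_subj_a = 8L, n_subj_b = 8L, n_feat = 20L,
                           n_shifted = 5L, effect = 3, seed = 1L) {
  set.seed(seed)
  subj <- c(paste0("a", seq_len(n_subj_a)), paste0("b", seq_len(n_subj_b)))
  grp <- rep(c("a", "b"), c(n_subj_a, n_subj_b))
  meta <- data.frame(
    subject_id = rep(subj, each = 4L),
    group = rep(grp, each = 4L),
    session = rep(c(1L, 1L, 2L, 2L), times = length(subj)),
    run = rep(c(1L, 2L, 1L, 2L), times = length(subj)),
    stringsAsFactors = FALSE)
  x <- matrix(rnorm(nrow(meta) * n_feat), nrow(meta), n_feat)
  shift_cols <- seq_len(n_shifted)
  x[meta$group == "b", shift_cols] <- x[meta$group == "b", shift_cols] + effect
  list(features = x, meta = meta)
}
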