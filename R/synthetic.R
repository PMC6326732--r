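# Synthetic test signals and cohorts.
#
# The raw resting-state data behind the published analyses are not
# deposited, so every downstream stage is exercised on synthetic input:
# four toy regimes (phase-shifted sinusoids, two offset sets, two
# harmonics, cyclic-but-aperiodic) and a two-group, two-session cohort
# whose group contrast is carried purely by the variability of the
# phase ordering, not by amplitudes.

#' Specification for a bank of phase-shifted sinusoidal channels
#'
#' @param n_channels number of channels.
#' @param amplitudes per-channel amplitudes (recycled if scalar).
#' @param phases per-channel phase offsets in radians, \code{[0, 2*pi)};
#'   defaults to evenly spaced \code{2*pi*k/n_channels}.
#' @param n_periods number of full cycles spanned by the record.
#' @param n_samples number of samples, uniform in nominal time.
#' @param snr signal-to-noise power ratio of the added white Gaussian
#'   noise; \code{Inf} for noiseless.
#' @param harmonic_multiplier positive integer per channel; channels with
#'   multiplier h oscillate at h times the fundamental frequency.
#' @return list of class \code{sinusoid_spec}.
#' @export
sinusoid_spec <- function(n_channels = 8L, amplitudes = 1, phases = NULL,
                          n_periods = 4L, n_samples = 300L, snr = 20,
                          harmonic_multiplier = 1L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("n_channels must be positive", call. = FALSE)
  if (is.null(phases)) phases <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
  amplitudes <- rep_len(amplitudes, n_channels)
  harmonic_multiplier <- rep_len(as.integer(harmonic_multiplier), n_channels)
  if (length(phases) != n_channels)
    stop("phases length must equal n_channels", call. = FALSE)
  if (any(amplitudes <= 0)) stop("amplitudes must be positive", call. = FALSE)
  if (any(harmonic_multiplier < 1L))
    stop("harmonic multipliers must be positive integers", call. = FALSE)
  if (!(snr > 0)) stop("snr must be positive (possibly Inf)", call. = FALSE)
  if (n_samples < 4L * n_periods * max(harmonic_multiplier))
    stop("n_samples too small to resolve the fastest harmonic", call. = FALSE)
  structure(list(n_channels = n_channels, amplitudes = amplitudes,
                 phases = phases %% (2 * pi), n_periods = as.integer(n_periods),
                 n_samples = as.integer(n_samples), snr = snr,
                 harmonic_multiplier = harmonic_multiplier),
            class = "sinusoid_spec")
}

.sinusoid_clean <- function(spec, warp = NULL) {
  u <- (seq_len(spec$n_samples) - 1) / spec$n_samples  # nominal time in [0,1)
  if (!is.null(warp)) {
    wu <- warp(u)
    if (any(diff(wu) <= 0) || abs(warp(0)) > 1e-12 || abs(warp(1) - 1) > 1e-12)
      stop("warp must be strictly increasing with warp(0)=0, warp(1)=1",
           call. = FALSE)
    u <- wu
  }
  t <- 2 * pi * spec$n_periods * u
  x <- vapply(seq_len(spec$n_channels), function(k) {
    spec$amplitudes[k] * sin(spec$harmonic_multiplier[k] * t + spec$phases[k])
  }, numeric(spec$n_samples))
  x <- t(x)
  rownames(x) <- paste0("ch", seq_len(spec$n_channels))
  x
}

.add_noise <- function(x, snr) {
  if (is.infinite(snr)) return(x)
  sig_pow <- rowMeans(x^2)
  noise_sd <- sqrt(sig_pow / snr)
  x + noise_sd * matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
}

#' Phase-shifted sinusoids with additive white noise
#'
#' The basic single-harmonic regime: channel k is
#' \code{a_k * sin(h_k * t + phi_k)} sampled uniformly over
#' \code{n_periods} full cycles, plus white Gaussian noise scaled per
#' channel so that signal power / noise power equals \code{snr}.
#'
#' @param spec a [sinusoid_spec()].
#' @param seed integer seed; output is reproducible given the seed.
#' @return channels-by-samples matrix with channel row names.
#' @export
gen_phase_shifted_sinusoids <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sinusoid_spec"))
  x <- .sinusoid_clean(spec)
  set.seed(as.integer(seed))
  .add_noise(x, spec$snr)
}

#' Two sets of sinusoids with an inter-set phase offset
#'
#' Stacks two sinusoid banks sharing a sampling grid, shifting every phase
#' of the second set by \code{inter_set_offset}.  Amplitude differences
#' between the sets are preserved; this is the regime where per-channel
#' normalisation matters downstream.
#'
#' @param spec_a,spec_b [sinusoid_spec()]s with equal \code{n_periods} and
#'   \code{n_samples}.
#' @param inter_set_offset radians added to every phase of set b.
#' @param seed integer seed.
#' @return stacked channels-by-samples matrix; set-b channels are labelled
#'   with a \code{"b_"} prefix.
#' @export
gen_two_set_offset <- function(spec_a, spec_b, inter_set_offset, seed = 1L) {
  stopifnot(inherits(spec_a, "sinusoid_spec"), inherits(spec_b, "sinusoid_spec"))
  if (spec_a$n_periods != spec_b$n_periods || spec_a$n_samples != spec_b$n_samples)
    stop("both sets must share n_periods and n_samples", call. = FALSE)
  spec_b$phases <- (spec_b$phases + inter_set_offset) %% (2 * pi)
  xa <- .sinusoid_clean(spec_a)
  xb <- .sinusoid_clean(spec_b)
  rownames(xa) <- paste0("a_", seq_len(nrow(xa)))
  rownames(xb) <- paste0("b_", seq_len(nrow(xb)))
  x <- rbind(xa, xb)
  set.seed(as.integer(seed))
  snr <- spec_a$snr
  .add_noise(x, snr)
}

#' Mixed-harmonic sinusoid bank
#'
#' A regime containing two harmonics (the second at twice the fundamental
#' frequency).  Channels carrying the second harmonic live in a different
#' eigenspace of the lead matrix, so their components of the leading
#' eigenvector collapse towards the origin and two eigenvector pairs are
#' needed to recover all phases.
#'
#' @param base_spec [sinusoid_spec()] whose \code{harmonic_multiplier}
#'   contains both 1 and 2.
#' @param seed integer seed.
#' @return channels-by-samples matrix.
#' @export
gen_two_harmonics <- function(base_spec, seed = 1L) {
  stopifnot(inherits(base_spec, "sinusoid_spec"))
  h <- base_spec$harmonic_multiplier
  if (length(unique(h)) < 2L)
    stop("degenerate regime: harmonic_multiplier must mix harmonics",
         call. = FALSE)
  x <- .sinusoid_clean(base_spec)
  set.seed(as.integer(seed))
  .add_noise(x, base_spec$snr)
}

#' Cyclic but aperiodic signals via monotone time warping
#'
#' Evaluates the analytic periodic signals at warped times
#' \code{warp(u)}, producing a reparameterised — hence aperiodic — version
#' of the same closed path.  Because the lead matrix is invariant under
#' reparameterisation, downstream analysis of the warped record matches
#' the unwarped one at dense sampling.  The warp is applied to the
#' analytic signal (not by resampling), so no interpolation error enters.
#'
#' @param spec a [sinusoid_spec()].
#' @param warp strictly increasing function mapping \code{[0,1]} onto
#'   itself.
#' @param seed integer seed.
#' @return channels-by-samples matrix.
#' @export
gen_cyclic_aperiodic <- function(spec, warp = identity, seed = 1L) {
  stopifnot(inherits(spec, "sinusoid_spec"), is.function(warp))
  x <- .sinusoid_clean(spec, warp = warp)
  set.seed(as.integer(seed))
  .add_noise(x, spec$snr)
}

#' Specification of a synthetic two-group, two-session cohort
#'
#' Defaults mirror the dimensions of the study the generator emulates:
#' 15 control-like vs 32 patient-like subjects, 33 channels, 300 samples
#' per run, 2 sessions of 2 runs each.  The group contrast is encoded
#' purely in the run-level phase-ordering jitter (amplitudes equal across
#' groups): the control-like group keeps a consistent ordering while the
#' patient-like group's ordering is more variable.  Each subject carries a
#' persistent phase offset (the fingerprint that makes cross-session
#' identification possible).
#'
#' @param n_group_a,n_group_b subject counts (group a = control-like).
#' @param n_channels,n_samples run dimensions.
#' @param n_sessions,runs_per_session session structure.
#' @param n_periods full cycles per run.
#' @param ordering_jitter_a,ordering_jitter_b sd (radians) of the per-run
#'   phase perturbation around the subject template, by group.
#' @param subject_jitter sd (radians) of the persistent per-subject phase
#'   offset around the group template.
#' @param snr signal-to-noise power ratio of per-channel white noise.
#' @param seed integer seed governing all randomness in [gen_cohort()].
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_group_a = 15L, n_group_b = 32L, n_channels = 33L,
                        n_samples = 300L, n_sessions = 2L,
                        runs_per_session = 2L, n_periods = 10L,
                        ordering_jitter_a = 0.1, ordering_jitter_b = 0.6,
                        subject_jitter = 0.5, snr = 20, seed = 1L) {
  counts <- c(n_group_a, n_group_b, n_channels, n_samples, n_sessions,
              runs_per_session, n_periods)
  if (any(counts < 1L)) stop("all counts must be positive", call. = FALSE)
  jit <- c(ordering_jitter_a, ordering_jitter_b, subject_jitter)
  if (any(!is.finite(jit)) || any(jit < 0))
    stop("jitters must be finite and nonnegative", call. = FALSE)
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_sessions = as.integer(n_sessions),
                 runs_per_session = as.integer(runs_per_session),
                 n_periods = as.integer(n_periods),
                 ordering_jitter_a = ordering_jitter_a,
                 ordering_jitter_b = ordering_jitter_b,
                 subject_jitter = subject_jitter, snr = snr,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of multichannel runs
#'
#' Phase model: group template = evenly spaced phases
#' \code{2*pi*k/n_channels}; subject template = group template + N(0,
#' subject_jitter) per channel (persistent across sessions); each run's
#' phases = subject template + N(0, ordering jitter of the group).  Each
#' run is then a bank of unit-amplitude sinusoids at those phases with
#' white noise at \code{snr}.
#'
#' @param spec a [cohort_spec()].
#' @param channel_labels optional channel names (defaults to
#'   \code{roi01..}).
#' @return data frame of class \code{cohort} with columns subject_id,
#'   group ("a"/"b"), session, run, and a list column \code{timecourse}
#'   of channels-by-samples matrices.  One row per run:
#'   \code{(n_group_a + n_group_b) * n_sessions * runs_per_session} rows.
#' @export
gen_cohort <- function(spec, channel_labels = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$n_channels
  if (is.null(channel_labels))
    channel_labels <- sprintf("roi%02d", seq_len(m))
  stopifnot(length(channel_labels) == m)
  set.seed(spec$seed)
  template <- 2 * pi * (seq_len(m) - 1) / m
  groups <- rep(c("a", "b"), c(spec$n_group_a, spec$n_group_b))
  n_subj <- length(groups)
  subj_ids <- sprintf("s%02d", seq_len(n_subj))
  rows <- vector("list", n_subj * spec$n_sessions * spec$runs_per_session)
  i <- 0L
  for (s in seq_len(n_subj)) {
    subj_template <- template + stats::rnorm(m, 0, spec$subject_jitter)
    run_jit <- if (groups[s] == "a") spec$ordering_jitter_a else spec$ordering_jitter_b
    for (sess in seq_len(spec$n_sessions)) {
      for (r in seq_len(spec$runs_per_session)) {
        phases <- subj_template + stats::rnorm(m, 0, run_jit)
        sp <- sinusoid_spec(n_channels = m, amplitudes = 1,
                            phases = phases %% (2 * pi),
                            n_periods = spec$n_periods,
                            n_samples = spec$n_samples, snr = spec$snr)
        x <- .add_noise(.sinusoid_clean(sp), sp$snr)
        rownames(x) <- channel_labels
        i <- i + 1L
        rows[[i]] <- list(subject_id = subj_ids[s], group = groups[s],
                          session = sess, run = r, timecourse = x)
      }
    }
  }
  out <- data.frame(
    subject_id = vapply(rows, `[[`, "", "subject_id"),
    group = vapply(rows, `[[`, "", "group"),
    session = vapply(rows, `[[`, 0L, "session"),
    run = vapply(rows, `[[`, 0L, "run"),
    stringsAsFactors = FALSE)
  out$timecourse <- lapply(rows, `[[`, "timecourse")
  class(out) <- c("cohort", class(out))
  out
}

#' Lead-matrix feature table for a cohort
#'
#' Computes the lead matrix of every run and vectorises its strict upper
#' triangle, returning run-level feature vectors keyed by subject, group,
#' session and run.  This is the feature representation used by the
#' fingerprinting, selection and classification stages.
#'
#' @param cohort result of [gen_cohort()] (or any data frame with the same
#'   columns).
#' @param normalize passed to [lead_matrix()].
#' @return list with \code{features} (runs x pairs matrix), \code{pairs}
#'   (pair labels), and \code{meta} (subject/group/session/run data frame).
#' @export
cohort_features <- function(cohort, normalize = FALSE) {
  m <- nrow(cohort$timecourse[[1L]])
  feats <- t(vapply(cohort$timecourse, function(x)
    vectorize_lead(lead_matrix(x, normalize = normalize)),
    numeric(m * (m - 1) / 2)))
  pairs <- pair_labels(rownames(cohort$timecourse[[1L]]))
  colnames(feats) <- pairs
  meta <- as.data.frame(cohort)[, c("subject_id", "group", "session", "run")]
  list(features = feats, pairs = pairs, meta = meta)
}
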