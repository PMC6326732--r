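#!/usr/bin/env Rscript
# Stage 3: cross-session subject fingerprinting.
#
# 1-NN cosine matching of run feature vectors across the two sessions
# (both directions, groups pooled).  On the fingerprint cohort the
# persistent subject phase offsets dominate run-level jitter, so
# identification should vastly exceed the 1/47 chance level; on the
# contrast cohort the patient-like group's high run jitter erodes it.

library(cyclicity)

for (name in c("fingerprint", "contrast")) {
  cf <- cohort_features(read_cohort(sprintf("scratch/cohort_%s", name)))
  id <- knn_session_identification(cf$features, cf$meta$subject_id,
                                   cf$meta$session)
  n_subj <- nrow(id$confusion)
  cat(sprintf("%-12s accuracy %.3f (chance %.3f), %d/%d subjects perfect\n",
              name, id$overall_accuracy, 1 / n_subj,
              sum(id$per_subject_correct == id$runs_per_subject), n_subj))
  write.csv(id$confusion, sprintf("results/confusion_knn_%s.csv", name))
}
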