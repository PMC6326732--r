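#!/usr/bin/env Rscript
# Stage 6: leader-follower graphs over the 20 most discriminating pairs.
#
# Builds a consistency-weighted directed graph per group (edge direction =
# majority subject vote on the sign of the normalised lead entry, weight =
# vote proportion), layers it by longest path, and lists the pairs whose
# direction flips between the groups.

library(cyclicity)
cohort <- read_cohort("scratch/cohort_contrast")
cf <- cohort_features(cohort)

rk <- rank_pairs(cf$features, cf$meta$group)
top20 <- rk$ranks[1:20]
pidx <- pair_index(nrow(cohort$timecourse[[1]]))[top20, ]
lm_all <- lapply(cohort$timecourse, lead_matrix)

graphs <- lapply(c(a = "a", b = "b"), function(g) {
  keep <- cf$meta$group == g
  consistency_graph(lm_all[keep], cf$meta$subject_id[keep], pidx)
})

for (g in names(graphs)) {
  e <- graphs[[g]]$edges
  e$layer_source <- graphs[[g]]$layers[e$from]
  e$layer_target <- graphs[[g]]$layers[e$to]
  write.csv(e, sprintf("results/graph_%s.csv", g), row.names = FALSE)
  cat(sprintf("group %s: mean edge consistency %.3f, %d layers\n",
              g, mean(e$weight), max(graphs[[g]]$layers) + 1L))
}

flips <- flipped_edges(graphs$a, graphs$b)
write.csv(flips, "results/flipped_edges.csv", row.names = FALSE)
cat(nrow(flips), "of 20 pairs flip direction between groups\n")
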