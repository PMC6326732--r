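#!/usr/bin/env Rscript
# Stage 2: lead matrices, cyclic strengths, and group PCA.
#
# Computes per-run lead matrices for the contrast cohort, summarises which
# channels carry the strongest cyclic signal per group (top-10 ranking
# proportions), and runs group-wise PCA of the 528-dimensional run
# features, reporting leading-eigenvalue ratios.

library(cyclicity)
cohort <- read_cohort("scratch/cohort_contrast")
cf <- cohort_features(cohort)

m <- nrow(cohort$timecourse[[1]])
strengths <- t(vapply(cohort$timecourse, function(x)
  spectral_decomposition(lead_matrix(x))$strengths[, 1], numeric(m)))
rk <- strength_ranking(strengths, cf$meta$group, top_n = 10)
write.csv(t(rk), "results/strength_ranking.csv")
cat("channels most often in the top-10 strengths (group a):",
    head(colnames(rk)[order(rk["a", ], decreasing = TRUE)], 3), "\n")

pca_rows <- do.call(rbind, lapply(c("a", "b"), function(g) {
  p <- group_pca(cf$features[cf$meta$group == g, , drop = FALSE])
  data.frame(group = g, lambda1 = p$eigenvalues[1],
             ratio_12 = p$ratio_12, ratio_13 = p$ratio_13)
}))
write.csv(pca_rows, "results/group_pca.csv", row.names = FALSE)
print(pca_rows)

# display form of the first loading vector per group (lead-matrix shape)
for (g in c("a", "b")) {
  p <- group_pca(cf$features[cf$meta$group == g, , drop = FALSE])
  lm_disp <- loading_to_matrix(p$loadings[, 1],
                               rownames(cohort$timecourse[[1]]))
  write_leadmatrix(lm_disp, sprintf("results/loading1_group_%s.csv", g))
}
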