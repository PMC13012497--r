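#!/usr/bin/env Rscript
# Step 4 - Report taxonomy, pairwise contrasts and phenomenology PCA.
#
# Compares subjective sleep depth and sleepiness across report types
# (pairwise mixed models with Benjamini-Hochberg correction over the
# four-level family), tests the subtype proportion splits, and reduces
# the six phenomenology ratings of contentful dreams to the perceptual
# immersion / reflective thought components, whose association with
# sleep depth is then estimated.

library(dreamdepth)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

rec <- read_awakening_table(file.path(out_dir, "awakenings.csv"))

cat("-- report-type proportions --\n")
pt <- proportion_tests(rec)
cat(sprintf("Friedman test across CE/CEWR/NCE: chi2 = %.1f, p = %.3g\n",
            pt$friedman_stat, pt$friedman_p))
cat(sprintf("UNC share of NCE: %.1f%% (sign-rank p = %.3f vs CESP)\n",
            100 * pt$mean_unc_share, pt$signrank_unc_cesp_p))
cat(sprintf("sCEWR share of CEWR: %.1f%% (sign-rank p = %.2g vs rCEWR)\n",
            100 * pt$mean_scewr_share, pt$signrank_scewr_rcewr_p))

cat("\n-- pairwise report-type contrasts on sleep depth (BH-corrected) --\n")
ct <- pairwise_contrasts(rec, "sleep_depth")
print(transform(ct, beta = round(beta, 3), p = signif(p, 3),
                q = signif(q, 3))[c("level_a", "level_b", "beta", "p", "q")],
      row.names = FALSE)
write.csv(ct, file.path(out_dir, "contrasts_depth.csv"), row.names = FALSE)

cat("\n-- phenomenology PCA (CE reports) --\n")
ce <- rec[rec$report3 == "CE", , drop = FALSE]
rownames(ce) <- ce$record_id
pca <- phenomenology_pca(ce)
print(pca)
write.csv(data.frame(feature = rownames(pca$loadings),
                     round(pca$loadings[, 1:2], 4)),
          file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)

rec$pc1 <- pca$scores[match(rec$record_id, pca$row_ids), "pc1"]
rec$pc2 <- pca$scores[match(rec$record_id, pca$row_ids), "pc2"]
for (pc in c("pc1", "pc2")) {
  fit <- pc_association(rec, "sleep_depth", pc)
  b <- fit$coefficients[fit$coefficients$term == pc, ]
  cat(sprintf("%s vs sleep depth: beta = %.3f, CI = [%.3f, %.3f], p = %.2g\n",
              pc, b$estimate, b$ci_lo, b$ci_hi, b$p))
}
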