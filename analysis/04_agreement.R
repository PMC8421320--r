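#!/usr/bin/env Rscript
# Stage 4: dual-modality agreement analysis.
#
# Joins the MRI direct-route and PET fit tables per subject/condition/region
# and reports Spearman correlation, paired t test, and Bland-Altman bias and
# limits of agreement at the global, territory and segment level, for rest,
# stress and pooled pairs; then the same comparison for the myocardial flow
# reserve (stress/rest per subject). Writes the paired values, a JSON
# summary and correlation + Bland-Altman SVG plots. Run stages 01-03 first.

suppressPackageStartupMessages({
  library(dualperf)
  library(jsonlite)
})

pet <- read.delim("results/fit_pet.tsv")
mri <- read.delim("results/fit_mri_ps.tsv")
dir.create("results/agreement", showWarnings = FALSE, recursive = TRUE)

reports <- list()
for (lv in c("global", "territory", "segment"))
  for (cond in c("pooled", "rest", "stress")) {
    rep <- compare_modalities(pet, mri, lv, cond)
    reports[[paste(lv, cond, sep = "_")]] <- rep
    message(sprintf(
      "%-9s %-7s n=%3d  bias %+ .3f  LoA [% .2f, % .2f]  rho %.2f (p %.3g)  excl %d",
      lv, cond, rep$n, rep$bias, rep$loa_low, rep$loa_high,
      rep$spearman_r, rep$spearman_p, rep$excluded_count))
  }

pooled <- reports[["global_pooled"]]
write.table(pooled$pairs, "results/agreement/pairs_global_pooled.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

# MFR comparison (per-subject stress/rest before any averaging)
mfr_pet <- mfr_table(pet[pet$region == "global", ])
mfr_mri <- mfr_table(mri[mri$region == "global", ])
mj <- merge(mfr_pet[, c("subject", "mfr")], mfr_mri[, c("subject", "mfr")],
            by = "subject", suffixes = c("_pet", "_mri"))
mfr_rep <- list(n = nrow(mj),
                mean_mri = mean(mj$mfr_mri), mean_pet = mean(mj$mfr_pet),
                spearman = spearman_cor(mj$mfr_mri, mj$mfr_pet),
                bland_altman = bland_altman(mj$mfr_mri, mj$mfr_pet),
                paired_t = paired_t(mj$mfr_mri, mj$mfr_pet))
message(sprintf("MFR: MRI %.2f vs PET %.2f, rho %.2f, bias %+.2f",
                mfr_rep$mean_mri, mfr_rep$mean_pet, mfr_rep$spearman$r,
                mfr_rep$bland_altman$bias))

write_json(c(lapply(reports, function(r)
  r[c("n", "bias", "loa_low", "loa_high", "spearman_r", "spearman_p",
      "t_stat", "t_p", "excluded_count")]),
  list(mfr = mfr_rep)),
  "results/agreement/summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

# scatter + Bland-Altman of the pooled global comparison
svg("results/agreement/global_pooled.svg", width = 9, height = 4.5)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
rng <- range(pooled$pairs$pet, pooled$pairs$mri)
plot(pooled$pairs$pet, pooled$pairs$mri, xlim = rng, ylim = rng,
     xlab = "PET MBF (mL/g/min)", ylab = "MRI MBF (mL/g/min)",
     pch = 19, col = ifelse(pooled$pairs$condition == "rest", "#1b6ca8",
                            "#c23b22"),
     main = "Global MBF, rest + stress")
abline(0, 1, lty = 2)
legend("topleft", c("rest", "stress"), pch = 19,
       col = c("#1b6ca8", "#c23b22"), bty = "n")
avg <- (pooled$pairs$pet + pooled$pairs$mri) / 2
dif <- pooled$pairs$mri - pooled$pairs$pet
plot(avg, dif, pch = 19, xlab = "mean of MRI and PET (mL/g/min)",
     ylab = "MRI - PET (mL/g/min)", main = "Bland-Altman")
abline(h = pooled$bias)
abline(h = c(pooled$loa_low, pooled$loa_high), lty = 2)
dev.off()
message("agreement outputs in results/agreement/")
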