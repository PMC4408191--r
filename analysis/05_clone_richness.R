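#!/usr/bin/env Rscript
# Clone-library richness estimation on synthetic OTU count tables:
# observed richness, Chao1 and ACE with standard errors, and individual
# rarefaction curves per library.

suppressPackageStartupMessages(library(flocrrt))
dir.create("results", showWarnings = FALSE)

otus <- gen_otu_counts(seed = 2)
write_otu_table(otus, "results/otu_counts.csv")

report <- do.call(rbind, lapply(colnames(otus), function(s) {
  x <- otus[, s]
  ch <- chao1(x); ac <- ace(x)
  data.frame(sample = s, n_clones = sum(x), S_obs = ch$S_obs,
             chao1 = ch$estimate, chao1_se = ch$se,
             ACE = ac$estimate, ACE_se = ac$se)
}))
utils::write.csv(report, "results/richness_estimates.csv",
                 row.names = FALSE, quote = FALSE)
print(report, row.names = FALSE, digits = 3)

rare <- do.call(rbind, lapply(colnames(otus), function(s) {
  cbind(sample = s, rarefaction_curve(otus[, s], seq_len(sum(otus[, s]))))
}))
utils::write.csv(rare, "results/rarefaction.csv", row.names = FALSE,
                 quote = FALSE)
cat("\nEstimated richness exceeds observed wherever singletons remain:\n")
cat(sprintf("mean S_obs %.1f vs mean Chao1 %.1f and ACE %.1f - the\n",
            mean(report$S_obs), mean(report$chao1), mean(report$ACE)))
cat("libraries are undersampled, as their still-rising rarefaction curves show.\n")
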