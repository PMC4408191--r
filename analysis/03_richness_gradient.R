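#!/usr/bin/env Rscript
# The central simulation: AOB species richness across a resource
# enrichment gradient with diffusion-sized microhabitats, 50 replicate
# microhabitats of 100 supply points per position. Produces the humped
# richness curve and its replicate-SD profile.

suppressPackageStartupMessages(library(flocrrt))

cfg <- default_config(seed = 1, out_dir = "results/simulation")
curve <- run_simulation_arm(cfg)

peak <- which.max(curve$mean_richness)
cat(sprintf("Peak mean richness %.2f at gradient position %d of %d\n",
            curve$mean_richness[peak], peak, nrow(curve)))
cat(sprintf("Endpoints: %.2f (low supply) and %.2f (high supply) species\n",
            curve$mean_richness[1], curve$mean_richness[nrow(curve)]))
cat(sprintf("Replicate SD: max %.2f on the low-resource half vs %.2f at the top\n",
            max(curve$sd_richness[seq_len(nrow(curve) %/% 2)]),
            curve$sd_richness[nrow(curve)]))
cat(sprintf("Maximum richness in any microhabitat: %d (pool size 23)\n",
            max(attr(curve, "replicates"))))
cat("The curve rises then falls: low supplies support few viable taxa,\n")
cat("intermediate supplies straddle many coexistence wedges, and high\n")
cat("supplies leave microhabitats inside ever fewer wedges.\n")
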