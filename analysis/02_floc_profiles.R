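#!/usr/bin/env Rscript
# Steady-state oxygen and ammonia profiles inside activated-sludge
# flocs, and the non-dimensional variation sigma that sizes resource
# microhabitats. The 100 um floc at high aeration is the benchmark
# regime (oxygen sigma ~ 0.014, ammonia essentially flat); the 200 um
# default used by the richness simulation steepens the oxygen gradient.

suppressPackageStartupMessages(library(flocrrt))
dir.create("results", showWarnings = FALSE)

cases <- list(
  list(name = "O2_100um_highDO",
       spec = floc_spec(100, 1.5e-4, 20000, 0.5, 3.6)),
  list(name = "O2_100um_lowDO",
       spec = floc_spec(100, 1.5e-4, 20000, 0.5, 0.22)),
  list(name = "NH4_100um_lowfeed",
       spec = floc_spec(100, 1.4e-4, 2000, 1.0, 24.2)),
  list(name = "O2_200um_default",
       spec = floc_spec(200, 1.5e-4, 20000, 0.5, 3.6)))

summ <- do.call(rbind, lapply(cases, function(cs) {
  pr <- solve_floc_profile(cs$spec)
  write_floc_profile(pr, file.path("results",
                                   paste0("profile_", cs$name, ".csv")))
  data.frame(case = cs$name, radius_um = cs$spec$radius,
             C_bulk = cs$spec$C_bulk, C_centre = pr$C[1],
             sigma = nondim_variation(pr))
}))
utils::write.csv(summ, "results/floc_sigma.csv", row.names = FALSE,
                 quote = FALSE)
print(summ, row.names = FALSE, digits = 4)
cat("\nOxygen varies through the floc while ammonia is flat on its own\n",
    "supply scale - only oxygen heterogeneity sizes the microhabitats.\n")
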