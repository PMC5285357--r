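#!/usr/bin/env Rscript
# Step 1: simulate an orchard-like dataset with recorded ground truth.
#
# Emulates the field campaign: per-leaf blade measurements for bourse shoots,
# rosettes and vegetative shoots of the three cultivars, cumulative internode
# lengths along 24 spur continua, and an hourly temperature record from full
# bloom. Writes the CSV dialects the fitting steps read.

library(shootallom)

seed <- 20140410L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config()
leaf <- generate_leaf_dataset(cfg, seed = seed)
write.csv(leaf$leaves, file.path(out, "leaves.csv"), row.names = FALSE)
write.csv(leaf$truth$shoots, file.path(out, "truth_shoots.csv"), row.names = FALSE)

spur <- generate_internode_dataset(cfg, seed = seed)
write.csv(spur$internodes, file.path(out, "internodes.csv"), row.names = FALSE)

temps <- generate_temperature_series(60, start = "2014-04-10",
                                     mean_C = 15, amplitude_C = 6,
                                     day_jitter_sd = 2, seed = seed)
write.csv(temps, file.path(out, "temperature.csv"), row.names = FALSE)

sm <- shoot_summaries(leaf$leaves)
cat(sprintf("simulated %d shoots (%d leaves): %s\n",
            nrow(sm), nrow(leaf$leaves),
            paste(sprintf("%s=%d", names(table(sm$shoot_type)),
                          table(sm$shoot_type)), collapse = ", ")))
cat(sprintf("simulated %d spur continua (%d nodes), %d days of hourly temperature\n",
            length(unique(spur$internodes$spur_id)), nrow(spur$internodes),
            nrow(temps) / 24))
cat("generating truth: beta_BS 0.67 (AR,FU) / 0.50 (RB), beta_RO 0.69,",
    "x0 0.63, qi 0.62, si 0.12\n")
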