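#!/usr/bin/env Rscript
# Step 4: the logistic model of cumulative shoot length along the
# bourse/bourse-shoot continuum.

library(shootallom)

rec <- read_internode_table("results/data/internodes.csv")
fit <- fit_internode_model(rec)
print(fit)

# predicted profile for an 18-node continuum of 17 cm (3 cm bourse + 14 cm
# bourse shoot), alongside the per-rank internode lengths it implies
prof <- data.frame(
  rank_continuum = 1:18,
  cum_length_cm = predict_cumulative_length(1:18, 18, 3, 14,
                                            list(qi = fit$qi, si = fit$si))
)
prof$internode_cm <- c(prof$cum_length_cm[1], diff(prof$cum_length_cm))
write.csv(prof, "results/tables/internode_profile.csv", row.names = FALSE)

cat(sprintf("internode lengths: basal %.2f cm, longest %.2f cm at rank %d, apical %.2f cm\n",
            prof$internode_cm[1], max(prof$internode_cm),
            which.max(prof$internode_cm), prof$internode_cm[18]))
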